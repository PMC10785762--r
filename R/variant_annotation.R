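#' Call SNVs from a per-site allele-count pileup
#'
#' A site is called as a single nucleotide variant when, at one or more
#' timepoints, total depth reaches `min_depth` and the alternate-allele
#' frequency reaches `min_freq`. Per-timepoint frequencies are reported only
#' where depth reaches `min_depth`; below that they are missing (`NA`),
#' never zero — non-observation must not masquerade as absence in the
#' trajectory analyses downstream.
#'
#' Sites duplicated at the same (contig, position) with different alternate
#' alleles are reduced to the allele with the highest total alternate count
#' (biallelic treatment); the discarded alleles are reported in a message.
#'
#' @param pileup A `pileup` object (see [simulate_allele_counts()]) or a
#'   compatible list with `alt_counts`, `total_counts`, `site_coords`.
#' @param min_depth Minimum depth for a frequency to be observed (>= 1).
#' @param min_freq Minimum alternate-allele frequency to call a site, in
#'   (0, 1).
#' @return An `snv_set`: list with `sites` (data.frame contig, position,
#'   ref_base, alt_base), and sites x timepoints matrices `alt`, `total`,
#'   `freq` (`NA` below depth).
#' @export
call_snvs <- function(pileup, min_depth = 5, min_freq = 0.05) {
  if (min_depth < 1) stopf("`min_depth` must be >= 1")
  if (min_freq <= 0 || min_freq >= 1) stopf("`min_freq` must be in (0, 1)")
  alt <- as.matrix(pileup$alt_counts)
  tot <- as.matrix(pileup$total_counts)
  coords <- pileup$site_coords
  bad <- which(alt > tot | alt < 0 | tot < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(alt))[1]
    stopf("malformed counts at %s:%d (alt > total or negative)",
          coords$contig[i], coords$position[i])
  }
  key <- paste(coords$contig, coords$position)
  if (anyDuplicated(key)) {
    keep <- rep(TRUE, nrow(coords))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(rowSums(alt[idx, , drop = FALSE]))]
      drop <- setdiff(idx, best)
      keep[drop] <- FALSE
      message(sprintf("multi-allelic site %s: keeping %s>%s, dropping %d allele(s)",
                      k, coords$ref_base[best], coords$alt_base[best],
                      length(drop)))
    }
    alt <- alt[keep, , drop = FALSE]
    tot <- tot[keep, , drop = FALSE]
    coords <- coords[keep, , drop = FALSE]
  }
  freq <- alt / tot
  freq[tot < min_depth] <- NA_real_
  called <- apply(freq >= min_freq, 1, any, na.rm = TRUE)
  structure(list(
    sites = coords[called, , drop = FALSE],
    alt = alt[called, , drop = FALSE],
    total = tot[called, , drop = FALSE],
    freq = freq[called, , drop = FALSE]
  ), class = "snv_set")
}

#' @export
print.snv_set <- function(x, ...) {
  cat(sprintf("snv_set: %d SNVs x %d timepoints\n", nrow(x$sites), ncol(x$freq)))
  invisible(x)
}

#' Annotate SNV coding effects against gene models
#'
#' For each called SNV inside a gene, the spanning codon is reconstructed
#' honoring the gene's strand (reverse-complement on `-`), translated with
#' the genome's genetic code, and classified: `synonymous` (same amino
#' acid), `nonsynonymous` (different), `nonsense` (stop gained) or
#' `intergenic` (outside every gene). Nonsynonymous changes also receive a
#' Grantham distance and impact class; nonsense changes do not (stop has no
#' physicochemical property vector).
#'
#' @param snvs An `snv_set` from [call_snvs()].
#' @param genome A `synthetic_genome` or object read by [read_genome()].
#' @return An `snv_records` object: `records` data.frame (site columns plus
#'   gene_id, effect, codon_position, aa_ref, aa_alt, grantham, impact) and
#'   the `freq` matrix carried through.
#' @export
annotate_effect <- function(snvs, genome) {
  stopifnot(inherits(snvs, "snv_set") || is.list(snvs))
  genes <- genome$genes
  bad_len <- which((genes$end - genes$start + 1L) %% 3L != 0L)
  if (length(bad_len)) {
    stopf("gene model '%s' has length not divisible by 3", genes$gene_id[bad_len[1]])
  }
  code <- Biostrings::getGeneticCode(genome$translation_table %||% "11")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nrow(snvs$sites)
  rec <- data.frame(
    snvs$sites,
    gene_id = NA_character_, effect = "intergenic",
    codon_position = NA_integer_, aa_ref = NA_character_,
    aa_alt = NA_character_, grantham = NA_real_, impact = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ctg <- snvs$sites$contig[i]
    pos <- snvs$sites$position[i]
    if (!ctg %in% names(genome$contigs)) {
      stopf("SNV contig '%s' is not in the annotation", ctg)
    }
    hit <- which(genes$contig == ctg & genes$start <= pos & genes$end >= pos)
    if (!length(hit)) next
    g <- genes[hit[1], ]
    ref <- toupper(snvs$sites$ref_base[i])
    alt <- toupper(snvs$sites$alt_base[i])
    genome_ref <- as.character(Biostrings::subseq(genome$contigs[[ctg]], pos, pos))
    if (genome_ref != ref) {
      stopf("reference mismatch at %s:%d: pileup says %s, genome says %s",
            ctg, pos, ref, genome_ref)
    }
    if (g$strand == "+") {
      cds_pos <- pos - g$start + 1L
      ref_c <- ref; alt_c <- alt
    } else {
      cds_pos <- g$end - pos + 1L
      ref_c <- comp[[ref]]; alt_c <- comp[[alt]]
    }
    codon_i <- (cds_pos - 1L) %/% 3L
    within <- (cds_pos - 1L) %% 3L + 1L
    cds <- coding_sequence(genome, g$gene_id)
    codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt_c
    aa_ref <- unname(code[codon])
    aa_alt <- unname(code[alt_codon])
    rec$gene_id[i] <- g$gene_id
    rec$codon_position[i] <- within
    rec$aa_ref[i] <- aa_ref
    rec$aa_alt[i] <- aa_alt
    if (aa_alt == "*") {
      rec$effect[i] <- "nonsense"
    } else if (aa_alt == aa_ref) {
      rec$effect[i] <- "synonymous"
    } else {
      rec$effect[i] <- "nonsynonymous"
      rec$grantham[i] <- grantham_distance(aa_ref, aa_alt)
      rec$impact[i] <- classify_impact(rec$grantham[i])
    }
  }
  structure(list(records = rec, freq = snvs$freq, alt = snvs$alt,
                 total = snvs$total),
            class = "snv_records")
}

#' @export
print.snv_records <- function(x, ...) {
  tb <- table(x$records$effect)
  cat(sprintf("snv_records: %d SNVs (%s)\n", nrow(x$records),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' SNV frequency matrix with missingness mask
#'
#' Assembles the sites x timepoints frequency matrix used by trajectory
#' clustering and strain deconvolution. Row order follows the input SNV
#' order; rownames are `contig:position:ref>alt`. Entries at timepoints
#' below the calling depth are `NA` (masked), never zero.
#'
#' @param snvs An `snv_set` or `snv_records` object.
#' @return Numeric matrix (possibly 0-row) with entries in `[0, 1]` or `NA`.
#' @export
frequency_matrix <- function(snvs) {
  sites <- if (inherits(snvs, "snv_records")) snvs$records else snvs$sites
  f <- snvs$freq
  if (is.null(f)) stopf("object carries no frequency matrix")
  f <- as.matrix(f)
  if (nrow(sites) == 0) {
    return(matrix(numeric(0), 0, ncol(f), dimnames = list(NULL, colnames(f))))
  }
  rownames(f) <- paste0(sites$contig, ":", sites$position, ":",
                        sites$ref_base, ">", sites$alt_base)
  f
}
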