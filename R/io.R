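# Canonical interchange format: TSV, mandatory header, UTF-8, '.' decimal,
# "NA" for missing. FASTA/GFF3/VCF are supported at the boundary through
# Biostrings / rtracklayer / VariantAnnotation.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a matrix as TSV with an id column
#'
#' @param m Matrix with rownames.
#' @param path File path.
#' @param id_name Header of the rowname column.
#' @return The path (writer) or the matrix (reader).
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, path)
}

#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a pileup as long-format TSV
#'
#' Columns: contig, pos, ref, alt, timepoint, alt_count, total_count.
#'
#' @param pileup A `pileup` object.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  tps <- colnames(pileup$total_counts) %||%
    paste0("t", seq_len(ncol(pileup$total_counts)))
  V <- nrow(pileup$total_counts)
  df <- data.frame(
    contig = rep(pileup$site_coords$contig, times = length(tps)),
    pos = rep(pileup$site_coords$position, times = length(tps)),
    ref = rep(pileup$site_coords$ref_base, times = length(tps)),
    alt = rep(pileup$site_coords$alt_base, times = length(tps)),
    timepoint = rep(tps, each = V),
    alt_count = as.vector(pileup$alt_counts),
    total_count = as.vector(pileup$total_counts),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Read a long-format pileup TSV
#'
#' @param path File path.
#' @return A `pileup` object.
#' @export
read_pileup_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("contig", "pos", "ref", "alt", "timepoint", "alt_count", "total_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("pileup TSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    return(new_pileup(matrix(integer(0), 0, 0), matrix(integer(0), 0, 0),
                      data.frame(contig = character(0), position = integer(0),
                                 ref_base = character(0), alt_base = character(0))))
  }
  bad <- which(df$alt_count > df$total_count | df$alt_count < 0)
  if (length(bad)) {
    stopf("line %d: alt_count exceeds total_count at %s:%d",
          bad[1] + 1L, df$contig[bad[1]], df$pos[bad[1]])
  }
  key <- paste(df$contig, df$pos, df$ref, df$alt, sep = "\r")
  sites <- !duplicated(key)
  site_key <- key[sites]
  tps <- unique(df$timepoint)
  alt <- matrix(NA_integer_, sum(sites), length(tps),
                dimnames = list(NULL, tps))
  tot <- alt
  ri <- match(key, site_key)
  ci <- match(df$timepoint, tps)
  alt[cbind(ri, ci)] <- df$alt_count
  tot[cbind(ri, ci)] <- df$total_count
  if (anyNA(tot)) stopf("pileup TSV has missing site x timepoint combinations")
  coords <- data.frame(
    contig = df$contig[sites], position = df$pos[sites],
    ref_base = df$ref[sites], alt_base = df$alt[sites],
    stringsAsFactors = FALSE
  )
  new_pileup(alt, tot, coords)
}

#' Read allele counts from a VCF subset
#'
#' Consumes a minimal VCF (CHROM, POS, REF, first ALT, per-sample `AD` and
#' `DP`) and maps sample columns to timepoints. `AD` is interpreted as
#' (ref, alt) allele depths; the alternate depth must not exceed `DP`.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sample_order Optional character vector giving the timepoint order
#'   of the VCF sample columns (default: VCF column order).
#' @return A `pileup` object.
#' @export
read_vcf_counts <- function(path, sample_order = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_alleles <- vapply(as.list(rr$ALT), function(a) as.character(a[1]), character(1))
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  if (is.null(ad) || is.null(dp)) stopf("VCF must carry AD and DP genotype fields")
  samples <- colnames(dp)
  if (!is.null(sample_order)) {
    miss <- setdiff(sample_order, samples)
    if (length(miss)) stopf("sample(s) not in VCF: %s", paste(miss, collapse = ", "))
    samples <- sample_order
  }
  nv <- nrow(dp)
  alt_m <- matrix(NA_integer_, nv, length(samples),
                  dimnames = list(NULL, samples))
  tot_m <- alt_m
  for (j in seq_along(samples)) {
    s <- samples[j]
    for (i in seq_len(nv)) {
      adv <- if (is.list(ad)) ad[[i, s]] else ad[i, s, ]
      a <- as.integer(adv[2])
      d <- as.integer(dp[i, s])
      if (is.na(a) || is.na(d)) stopf("record %d sample %s: missing AD/DP", i, s)
      if (a > d) {
        stopf("record %d (%s:%d): AD alt depth %d exceeds DP %d",
              i, as.character(GenomicRanges::seqnames(rr))[i],
              GenomicRanges::start(rr)[i], a, d)
      }
      alt_m[i, j] <- a
      tot_m[i, j] <- d
    }
  }
  coords <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    position = GenomicRanges::start(rr),
    ref_base = as.character(rr$REF),
    alt_base = alt_alleles,
    stringsAsFactors = FALSE
  )
  new_pileup(alt_m, tot_m, coords)
}

#' Read a variant table in either supported dialect
#'
#' @param path File path.
#' @param dialect `"tsv_pileup"` (the package's long TSV) or
#'   `"vcf_subset"`.
#' @param sample_order Timepoint ordering for VCF sample columns.
#' @return A `pileup` object.
#' @export
read_variant_table <- function(path, dialect = c("tsv_pileup", "vcf_subset"),
                               sample_order = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv_pileup = read_pileup_tsv(path),
         vcf_subset = read_vcf_counts(path, sample_order))
}

#' Write genome FASTA and gene-model GFF3
#'
#' Serialized coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param genome A `synthetic_genome`.
#' @param fasta,gff3 Output paths.
#' @rdname genome_io
#' @export
write_genome <- function(genome, fasta, gff3) {
  Biostrings::writeXStringSet(genome$contigs, fasta)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$source <- "strainsweep"
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' @rdname genome_io
#' @param translation_table Genetic code id for the returned genome.
#' @return `read_genome()`: a `synthetic_genome`-shaped object.
#' @export
read_genome <- function(fasta, gff3, translation_table = "11") {
  if (!file.exists(fasta)) stopf("file not found: %s", fasta)
  if (!file.exists(gff3)) stopf("file not found: %s", gff3)
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "gene" | is.na(gr$type)]
  ids <- gr$ID %||% paste0("gene_", seq_along(gr))
  genes <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  structure(list(contigs = contigs, genes = genes,
                 translation_table = translation_table),
            class = "synthetic_genome")
}

#' Write the annotated SNV table
#'
#' Long format (one row per SNV per timepoint) with effect, amino-acid
#' change, Grantham score and impact class; a wide variant (one row per
#' SNV, one frequency column per timepoint) is written alongside when
#' `wide_path` is given.
#'
#' @param snv_records An `snv_records` object.
#' @param path Long-format output path.
#' @param wide_path Optional wide-format output path.
#' @export
write_snv_table <- function(snv_records, path, wide_path = NULL) {
  rec <- snv_records$records
  f <- snv_records$freq
  tps <- colnames(f) %||% paste0("t", seq_len(ncol(f)))
  long <- do.call(rbind, lapply(seq_along(tps), function(j) {
    data.frame(rec, timepoint = tps[j], frequency = f[, j],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write_tsv(long, path)
  if (!is.null(wide_path)) {
    wide <- data.frame(rec, as.data.frame(f), check.names = FALSE,
                       row.names = NULL)
    names(wide)[seq(ncol(rec) + 1, ncol(wide))] <- tps
    write_tsv(wide, wide_path)
  }
  invisible(path)
}

#' Read supporting tables
#'
#' `read_coverage_tsv()`: MAG x sample coverage matrix (first column MAG
#' id). `read_chemistry_csv()`: generation, reactor, tan_mg_per_l, ph,
#' temp_k. `read_pathway_map()`: gene_id, pathway_id.
#'
#' @param path File path.
#' @return Matrix or data.frame.
#' @rdname support_io
#' @export
read_coverage_tsv <- function(path) read_matrix_tsv(path)

#' @rdname support_io
#' @export
read_chemistry_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("generation", "reactor", "tan_mg_per_l", "ph", "temp_k")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("chemistry CSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  df
}

#' @rdname support_io
#' @export
read_pathway_map <- function(path) {
  df <- read_tsv(path)
  miss <- setdiff(c("gene_id", "pathway_id"), names(df))
  if (length(miss)) stopf("pathway map lacks column(s): %s",
                          paste(miss, collapse = ", "))
  df
}
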