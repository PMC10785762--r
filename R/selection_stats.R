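#' Nei-Gojobori (1986) expected site counts
#'
#' Partitions each coding position into fractional nonsynonymous and
#' synonymous "sites" by enumerating the three possible single-base changes
#' at that position and scoring the fraction that changes the encoded amino
#' acid. Changes creating a stop codon are excluded from the enumeration by
#' default (the stated convention here; set `include_stop_mutations = TRUE`
#' to count them as nonsynonymous). Every position contributes exactly one
#' site, so `n_sites + s_sites` equals the sequence length.
#'
#' @param coding_sequence In-frame nucleotide sequence (character scalar),
#'   length divisible by 3, no internal stop codon.
#' @param translation_table Genetic code id (default `"11"`).
#' @param include_stop_mutations Count mutations to stop as nonsynonymous
#'   instead of excluding them.
#' @return Named numeric vector `c(n_sites =, s_sites =)`.
#' @references Nei, M. and Gojobori, T. (1986) Simple methods for
#'   estimating the numbers of synonymous and nonsynonymous nucleotide
#'   substitutions. Mol. Biol. Evol. 3, 418-426.
#' @export
count_ng86_sites <- function(coding_sequence, translation_table = "11",
                             include_stop_mutations = FALSE) {
  seq <- toupper(coding_sequence)
  if (nchar(seq) %% 3 != 0) stopf("coding sequence length must be divisible by 3")
  code <- Biostrings::getGeneticCode(translation_table)
  bases <- c("A", "C", "G", "T")
  n_codons <- nchar(seq) / 3
  n_sites <- 0
  s_sites <- 0
  for (ci in seq_len(n_codons)) {
    codon <- substr(seq, 3 * ci - 2, 3 * ci)
    aa <- unname(code[codon])
    if (is.na(aa)) stopf("unrecognized codon '%s' at codon %d", codon, ci)
    if (aa == "*") stopf("internal stop codon at codon %d", ci)
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      n_ch <- 0L; s_ch <- 0L
      for (alt in setdiff(bases, ref)) {
        mut <- codon
        substr(mut, pos, pos) <- alt
        aa2 <- unname(code[mut])
        if (aa2 == "*") {
          if (include_stop_mutations) n_ch <- n_ch + 1L
          next
        }
        if (aa2 == aa) s_ch <- s_ch + 1L else n_ch <- n_ch + 1L
      }
      tot <- n_ch + s_ch
      if (tot == 0L) {
        # only stop-creating changes at this position: count as nonsynonymous
        n_sites <- n_sites + 1
      } else {
        n_sites <- n_sites + n_ch / tot
        s_sites <- s_sites + s_ch / tot
      }
    }
  }
  c(n_sites = n_sites, s_sites = s_sites)
}

#' Per-gene pN/pS selection statistic
#'
#' The ratio of nonsynonymous to synonymous polymorphism rates, each
#' normalized by its Nei-Gojobori mutational opportunity:
#' `(n_obs / n_sites) / (s_obs / s_sites)`. Values above 1 indicate excess
#' amino-acid-changing variation (candidate positive selection); below 1,
#' purifying selection. Because the variants here are within-population
#' polymorphisms rather than fixed between-species substitutions this is a
#' pN/pS statistic, even though field usage often labels it dN/dS.
#'
#' When no synonymous variants are observed the ratio is undefined
#' (`NA` with `ratio_defined = FALSE`), never infinity; an optional +0.5
#' continuity correction on both observed counts is available.
#'
#' @param coding_sequence The gene's in-frame sequence.
#' @param effects Character vector of SNV effects in the gene
#'   (`"synonymous"`, `"nonsynonymous"`, `"nonsense"`; nonsense is tallied
#'   but excluded from the ratio).
#' @param gene_id Identifier carried into the result.
#' @param continuity Add 0.5 to both observed counts before forming the
#'   ratio.
#' @param translation_table Genetic code id.
#' @return One-row data.frame: gene_id, n_sites, s_sites, n_obs, s_obs,
#'   n_nonsense, ratio, ratio_defined.
#' @export
gene_pnps <- function(coding_sequence, effects, gene_id = "gene",
                      continuity = FALSE, translation_table = "11") {
  sites <- count_ng86_sites(coding_sequence, translation_table)
  known <- c("synonymous", "nonsynonymous", "nonsense")
  if (length(effects) && !all(effects %in% known)) {
    stopf("unknown effect label(s): %s",
          paste(setdiff(effects, known), collapse = ", "))
  }
  n_obs <- sum(effects == "nonsynonymous")
  s_obs <- sum(effects == "synonymous")
  n_use <- n_obs + if (continuity) 0.5 else 0
  s_use <- s_obs + if (continuity) 0.5 else 0
  defined <- s_use > 0 && sites[["s_sites"]] > 0
  ratio <- if (defined) {
    (n_use / sites[["n_sites"]]) / (s_use / sites[["s_sites"]])
  } else NA_real_
  data.frame(
    gene_id = gene_id,
    n_sites = sites[["n_sites"]], s_sites = sites[["s_sites"]],
    n_obs = n_obs, s_obs = s_obs,
    n_nonsense = sum(effects == "nonsense"),
    ratio = ratio, ratio_defined = defined,
    stringsAsFactors = FALSE
  )
}

#' Per-gene pN/pS table for annotated SNVs
#'
#' @param snv_records An `snv_records` object from [annotate_effect()].
#' @param genome The genome the records were annotated against.
#' @param ... Passed to [gene_pnps()].
#' @return data.frame with one row per gene in the genome (genes without
#'   SNVs included, with zero counts).
#' @export
pnps_table <- function(snv_records, genome, ...) {
  rec <- snv_records$records
  rows <- lapply(genome$genes$gene_id, function(gid) {
    eff <- rec$effect[!is.na(rec$gene_id) & rec$gene_id == gid]
    gene_pnps(coding_sequence(genome, gid), eff, gene_id = gid, ...)
  })
  do.call(rbind, rows)
}

#' Flag genes under putative positive selection
#'
#' Genes whose pN/pS ratio is defined and strictly greater than the
#' threshold (default 1, i.e. "above 1"). Undefined ratios are never
#' flagged.
#'
#' @param stats data.frame from [gene_pnps()]/[pnps_table()].
#' @param threshold Ratio threshold (strict inequality).
#' @return Character vector of flagged gene ids.
#' @export
flag_selected <- function(stats, threshold = 1) {
  stats$gene_id[stats$ratio_defined & !is.na(stats$ratio) &
                  stats$ratio > threshold]
}

#' Per-gene nonsynonymous SNV burden
#'
#' Counts nonsynonymous SNVs per gene, optionally normalized per kilobase
#' of coding length (the default burden used by pathway enrichment, since
#' long genes accumulate more variants by chance alone).
#'
#' @param snv_records An `snv_records` object.
#' @param genome The annotated genome.
#' @param per_kb Normalize by coding length in kb.
#' @return Named numeric vector over all genes in the genome.
#' @export
nsnv_burden <- function(snv_records, genome, per_kb = TRUE) {
  rec <- snv_records$records
  counts <- vapply(genome$genes$gene_id, function(gid) {
    sum(!is.na(rec$gene_id) & rec$gene_id == gid &
          rec$effect == "nonsynonymous")
  }, numeric(1))
  if (per_kb) {
    len_kb <- (genome$genes$end - genome$genes$start + 1) / 1000
    counts <- counts / len_kb
  }
  setNames(counts, genome$genes$gene_id)
}

# exact permutation null of the rank-sum statistic with ties: dynamic
# program over doubled midranks counting m-subsets by rank sum
rank_sum_exact_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  r2 <- as.integer(round(2 * r)) # midranks doubled -> integers
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  # f[k+1, s+1] = number of k-subsets with doubled rank sum s
  f <- matrix(0, m + 1, smax + 1)
  f[1, 1] <- 1
  for (ri in r2) {
    # 0/1 knapsack over items: descend k so each rank is used at most once
    for (k in seq(m, 1)) {
      if (ri <= smax) {
        f[k + 1, (ri + 1):(smax + 1)] <- f[k + 1, (ri + 1):(smax + 1)] +
          f[k, seq_len(smax + 1 - ri)]
      }
    }
  }
  total <- choose(m + n, m)
  w2 <- as.integer(round(2 * w_obs))
  counts <- f[m + 1, ]
  if (alternative == "greater") {
    p <- sum(counts[seq(w2 + 1, smax + 1)]) / total
  } else {
    p <- sum(counts[seq_len(w2 + 1)]) / total
  }
  min(max(p, 0), 1)
}

# tie-corrected normal approximation (wilcox.test conventions, with
# continuity correction)
rank_sum_normal_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  ties <- table(r)
  sigma2 <- (m * n / 12) * ((m + n + 1) - sum(ties^3 - ties) /
                              ((m + n) * (m + n - 1)))
  sigma <- sqrt(sigma2)
  if (sigma == 0) return(1)
  z <- if (alternative == "greater") (u - mu - 0.5) / sigma else (u - mu + 0.5) / sigma
  if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
}

#' Rank-sum enrichment of nsSNV burden in a pathway gene set
#'
#' Mann-Whitney U test asking whether genes of a pathway carry a greater
#' nonsynonymous-variant burden than the remaining genes of the same
#' genome (one-sided upper tail by default, matching the directional
#' question "are nsSNVs accumulating in this pathway?"). The comparison
#' groups are disjoint: the background is the gene universe minus the
#' pathway set.
#'
#' The p-value uses the exact tie-aware permutation null (dynamic program
#' over midranks) when `set_size * background_size` is within
#' `exact_budget`, otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param burden Named numeric vector of per-gene burdens over the whole
#'   gene universe (see [nsnv_burden()]).
#' @param pathway_genes Character vector of pathway gene ids (nonempty,
#'   all present in `burden`).
#' @param background Character vector of universe gene ids (default: all
#'   names of `burden`); must strictly contain the pathway set.
#' @param alternative `"greater"` (enrichment) or `"less"`.
#' @param exact_budget Enumeration budget for the exact null.
#' @return One-row data.frame: pathway_size, background_size, statistic
#'   (Mann-Whitney U of the set), p_value, direction (`enriched`,
#'   `depleted` or `none`, by the sign of `U - E[U]`), method.
#' @export
pathway_enrichment <- function(burden, pathway_genes, background = names(burden),
                               alternative = c("greater", "less"),
                               exact_budget = 1e6) {
  alternative <- match.arg(alternative)
  if (!length(pathway_genes)) stopf("pathway gene set is empty")
  if (is.null(names(burden))) stopf("`burden` must be a named vector")
  missing <- setdiff(pathway_genes, names(burden))
  if (length(missing)) {
    stopf("pathway gene(s) not in the burden universe: %s",
          paste(missing, collapse = ", "))
  }
  bg <- setdiff(background, pathway_genes)
  if (!length(bg)) stopf("background must contain genes outside the pathway set")
  if (length(bg) <= length(pathway_genes)) {
    stopf("background size (%d) must exceed set size (%d)",
          length(bg), length(pathway_genes))
  }
  x <- burden[pathway_genes]
  y <- burden[bg]
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  exact <- (m * n) <= exact_budget
  p <- if (exact) rank_sum_exact_p(x, y, alternative)
  else rank_sum_normal_p(x, y, alternative)
  dir <- if (u > m * n / 2) "enriched" else if (u < m * n / 2) "depleted" else "none"
  data.frame(
    pathway_size = m, background_size = n, statistic = u, p_value = p,
    direction = dir, method = if (exact) "exact" else "normal",
    stringsAsFactors = FALSE
  )
}

#' Enrichment across a pathway map
#'
#' @param burden Named per-gene burden vector.
#' @param pathway_map data.frame with columns `gene_id`, `pathway_id`.
#' @param p_adjust Optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (default `"none"`, reporting raw p-values).
#' @param ... Passed to [pathway_enrichment()].
#' @return data.frame, one row per pathway, plus `p_adjusted` when
#'   requested.
#' @export
enrichment_table <- function(burden, pathway_map, p_adjust = "none", ...) {
  stopifnot(all(c("gene_id", "pathway_id") %in% names(pathway_map)))
  ids <- unique(pathway_map$pathway_id)
  rows <- lapply(ids, function(pid) {
    genes <- intersect(pathway_map$gene_id[pathway_map$pathway_id == pid],
                       names(burden))
    if (!length(genes)) return(NULL)
    cbind(pathway_id = pid, pathway_enrichment(burden, genes, ...),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && p_adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}
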