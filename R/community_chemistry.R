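#' MAG relative abundance from coverage
#'
#' Column-normalizes a MAG x sample mean-coverage matrix into relative
#' abundances (each sample sums to 1; zero-coverage MAGs get 0).
#'
#' @param coverage MAG x sample matrix of nonnegative mean depths.
#' @return Matrix of the same shape with columns summing to 1.
#' @export
relative_abundance <- function(coverage) {
  cov <- as.matrix(coverage)
  if (any(cov < 0)) stopf("coverages must be nonnegative")
  cs <- colSums(cov)
  zero <- which(cs == 0)
  if (length(zero)) {
    nm <- colnames(cov)[zero[1]] %||% as.character(zero[1])
    stopf("sample '%s' has zero total coverage", nm)
  }
  sweep(cov, 2, cs, "/")
}

#' Filter MAGs by relative abundance
#'
#' Keeps a MAG when its relative abundance reaches `threshold` in at least
#' one sample (the "X% or higher in at least one generation" rule used to
#' restrict analyses to well-covered genomes).
#'
#' @param ra_table MAG x sample relative-abundance matrix.
#' @param threshold Fraction in (0, 1); the comparison is `>=`.
#' @return Character vector of retained MAG names (or row indices when
#'   unnamed).
#' @export
filter_by_ra <- function(ra_table, threshold) {
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0, 1)")
  ra <- as.matrix(ra_table)
  keep <- apply(ra, 1, max) >= threshold
  if (is.null(rownames(ra))) which(keep) else rownames(ra)[keep]
}

#' Shannon diversity of a composition
#'
#' `H = -sum(p * log(p))` over nonzero components, in nats by default.
#'
#' @param p Nonnegative composition vector summing to 1 (within 1e-6).
#' @param base Logarithm base (default `exp(1)`; recorded by writers in
#'   output headers).
#' @return Scalar diversity, >= 0.
#' @export
shannon <- function(p, base = exp(1)) {
  if (any(p < 0)) stopf("composition entries must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6) stopf("composition must sum to 1 (got %.6f)", sum(p))
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1`/`F2` are the
#' numbers of taxa observed exactly once/twice. Requires integer detection
#' counts; fractional relative abundances must first be integerized (see
#' [ra_to_counts()]).
#'
#' @param counts Nonnegative integer detection counts per taxon.
#' @return Estimated richness (>= observed richness; 0 for all-zero input).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("Chao1 requires nonnegative integer counts")
  }
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Integerize relative abundances into pseudo-counts
#'
#' Chao1 needs count data; when only fractional relative abundances exist,
#' counts are obtained by scaling to a pseudo-count depth and flooring.
#' The depth is an explicit analysis choice recorded in outputs.
#'
#' @param ra Relative-abundance vector.
#' @param depth Pseudo-count depth (default 1000).
#' @return Integer vector.
#' @export
ra_to_counts <- function(ra, depth = 1000) {
  as.integer(floor(ra * depth))
}

#' Alpha diversity per sample
#'
#' @param ra_table MAG x sample relative-abundance matrix.
#' @param depth Pseudo-count depth for Chao1 (see [ra_to_counts()]).
#' @param base Log base for Shannon.
#' @return data.frame: sample, shannon, chao1, observed_richness.
#' @export
diversity_table <- function(ra_table, depth = 1000, base = exp(1)) {
  ra <- as.matrix(ra_table)
  samples <- colnames(ra) %||% paste0("sample", seq_len(ncol(ra)))
  rows <- lapply(seq_len(ncol(ra)), function(j) {
    counts <- ra_to_counts(ra[, j], depth)
    data.frame(
      sample = samples[j],
      shannon = shannon(ra[, j], base = base),
      chao1 = chao1(counts),
      observed_richness = sum(ra[, j] > 0),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Gene-set pathway completeness
#'
#' Fraction of a module's required genes present in a genome:
#' `|present & required| / |required|`, the gene-set analogue of KEGG
#' module completeness.
#'
#' @param genes_present Character vector of genes detected in the genome.
#' @param module_definition Nonempty character vector of required genes.
#' @return Fraction in `[0, 1]`.
#' @export
pathway_completeness <- function(genes_present, module_definition) {
  if (!length(module_definition)) stopf("module definition is empty")
  length(intersect(unique(genes_present), unique(module_definition))) /
    length(unique(module_definition))
}

#' Temperature-dependent ammonia dissociation pKa
#'
#' The NH4+/NH3 acid dissociation constant parameterized as
#' `pKa(T) = a + b / T` with the Emerson-type constants `a = 0.09018`,
#' `b = 2729.92` K (T in kelvin), the standard form used for free-ammonia
#' calculations in water and digester chemistry. Both constants are
#' arguments so an alternative parameterization can be swapped in without
#' code changes.
#'
#' @param temperature_k Temperature in kelvin (> 0).
#' @param a,b Parameterization constants.
#' @return pKa (unitless).
#' @export
ammonia_pka <- function(temperature_k, a = 0.09018, b = 2729.92) {
  if (any(temperature_k <= 0)) stopf("temperature must be > 0 K")
  a + b / temperature_k
}

#' Free ammonia nitrogen from TAN, pH and temperature
#'
#' Free ammonia (NH3-N) is the undissociated, membrane-permeant — and
#' therefore toxic — fraction of total ammonia nitrogen. From the NH4+/NH3
#' equilibrium,
#' \deqn{FAN = TAN \left(1 + \frac{10^{-pH}}{K_a(T)}\right)^{-1}}
#' with the dissociation constant `Ka(T)` from [ammonia_pka()]. FAN never
#' exceeds TAN; it increases monotonically with pH and temperature, and at
#' `pH = pKa(T)` exactly half of TAN is free.
#'
#' @param tan Total ammonia nitrogen, mg N/L (>= 0).
#' @param ph pH (unitless).
#' @param temperature_k Temperature in kelvin.
#' @param ... Passed to [ammonia_pka()] (alternative constants).
#' @return Free ammonia nitrogen, mg N/L, same length as the inputs
#'   (recycled).
#' @examples
#' compute_fan(tan = 20000, ph = 6.8, temperature_k = 315.15)
#' @export
compute_fan <- function(tan, ph, temperature_k, ...) {
  if (any(tan < 0)) stopf("TAN must be >= 0")
  pka <- ammonia_pka(temperature_k, ...)
  tan / (1 + 10^(pka - ph))
}

#' Chemistry table with computed FAN
#'
#' @param chem data.frame with columns `generation`, `reactor`,
#'   `tan_mg_per_l`, `ph`, `temp_k`.
#' @param ... Passed to [compute_fan()].
#' @return The input with a `fan_mg_per_l` column appended.
#' @export
chemistry_with_fan <- function(chem, ...) {
  need <- c("generation", "reactor", "tan_mg_per_l", "ph", "temp_k")
  miss <- setdiff(need, names(chem))
  if (length(miss)) stopf("chemistry table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  chem$fan_mg_per_l <- compute_fan(chem$tan_mg_per_l, chem$ph, chem$temp_k, ...)
  chem
}

#' Cumulative chloride from salt supplementation
#'
#' Bookkeeping helper: converts per-generation NH4Cl doses into cumulative
#' chloride-ion concentration (mass fraction of Cl in NH4Cl = 35.453 /
#' 53.491).
#'
#' @param nh4cl_mg_per_l Per-generation NH4Cl dose, mg/L.
#' @return Cumulative Cl- concentration, mg/L, per generation.
#' @export
estimate_chloride <- function(nh4cl_mg_per_l) {
  if (any(nh4cl_mg_per_l < 0)) stopf("doses must be >= 0")
  cumsum(nh4cl_mg_per_l) * 35.453 / 53.491
}
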