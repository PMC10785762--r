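#' Simulate strain abundance trajectories
#'
#' Generates a strains x timepoints abundance matrix with columns on the
#' probability simplex. Three regimes are available: `stable` (fixed
#' proportions), `single_sweep` (one logistic takeover) and
#' `serial_replacement` (a cascade of logistic sweeps so the dominant strain
#' changes repeatedly over the time course, the pattern seen when fitter
#' strains successively replace the resident under increasing environmental
#' pressure).
#'
#' Sweeps are logistic replacement curves: strain s switches on as
#' `1 / (1 + exp(-steepness * (t - midpoint_s)))` and suppresses all earlier
#' strains, after which columns are renormalized to the simplex. Optional
#' zero-mean Gaussian noise (sd `noise_sd`) is added entrywise, truncated at
#' zero and renormalized.
#'
#' @param n_strains Number of strains (>= 1).
#' @param n_timepoints Number of timepoints (>= 2).
#' @param sweep_pattern One of `"stable"`, `"single_sweep"`,
#'   `"serial_replacement"`.
#' @param noise_sd Standard deviation of additive abundance noise (fraction).
#' @param seed Integer seed; all randomness is derived from it.
#' @param midpoints Optional sweep midpoints (timepoint units) for the
#'   sweeping strains; defaults to evenly spaced.
#' @param steepness Logistic steepness per timepoint unit.
#' @return A `n_strains x n_timepoints` matrix, columns summing to 1, with
#'   dimnames `strain1..` / `t1..`.
#' @examples
#' a <- simulate_abundance_trajectories(3, 8, "serial_replacement", 0, seed = 1)
#' colSums(a)
#' @export
simulate_abundance_trajectories <- function(n_strains, n_timepoints,
                                            sweep_pattern = c("stable", "single_sweep", "serial_replacement"),
                                            noise_sd = 0, seed = 1,
                                            midpoints = NULL, steepness = 1.5) {
  n_strains <- check_count(n_strains, "n_strains", min = 1)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2)
  sweep_pattern <- match.arg(sweep_pattern)
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")

  tt <- seq_len(n_timepoints)
  with_seed(derive_seed(seed, "abundance", sweep_pattern), {
    if (n_strains == 1) {
      a <- matrix(1, 1, n_timepoints)
    } else if (sweep_pattern == "stable") {
      base <- rgamma(n_strains, shape = 5, rate = 1)
      a <- matrix(base / sum(base), n_strains, n_timepoints)
    } else {
      n_sweeps <- if (sweep_pattern == "single_sweep") 1L else n_strains - 1L
      if (is.null(midpoints)) {
        midpoints <- seq(1, n_timepoints, length.out = n_sweeps + 2)[-c(1, n_sweeps + 2)]
      }
      if (length(midpoints) != n_sweeps) {
        stopf("need %d sweep midpoints, got %d", n_sweeps, length(midpoints))
      }
      # strain 1 is resident; strain s (s > 1) switches on at midpoints[s-1]
      # and suppresses all earlier strains
      on <- matrix(1, n_strains, n_timepoints)
      for (s in seq_len(n_sweeps)) {
        on[s + 1L, ] <- 1 / (1 + exp(-steepness * (tt - midpoints[s])))
      }
      if (sweep_pattern == "single_sweep" && n_strains > 2) {
        # remaining strains stay rare background
        on[seq(3, n_strains), ] <- 0.05
      }
      u <- on
      active <- if (sweep_pattern == "single_sweep") 2L else seq(2L, n_strains)
      for (s in seq_len(n_strains)) {
        later <- active[active > s]
        for (j in later) u[s, ] <- u[s, ] * (1 - on[j, ])
      }
      u <- pmax(u, 0.01) # keep every strain detectable at low level
      a <- sweep(u, 2, colSums(u), "/")
    }
    if (noise_sd > 0) {
      a <- a + matrix(rnorm(length(a), 0, noise_sd), nrow(a))
      a <- pmax(a, 0)
      cs <- colSums(a)
      bad <- cs <= 0
      if (any(bad)) a[, bad] <- 1 / n_strains
      cs[bad] <- 1
      a <- sweep(a, 2, colSums(a), "/")
    }
    dimnames(a) <- list(paste0("strain", seq_len(n_strains)),
                        paste0("t", seq_len(n_timepoints)))
    a
  })
}

#' Simulate binary strain genotypes
#'
#' Draws a sites x strains 0/1 genotype matrix (1 = alternate allele) whose
#' strain columns are pairwise separated by at least `min_hamming`
#' differences, so simulated strains are genuinely distinct haplotypes.
#'
#' @param n_sites Number of variant sites.
#' @param n_strains Number of strains.
#' @param min_hamming Minimum pairwise Hamming distance between strain
#'   columns (>= 1).
#' @param seed Integer seed.
#' @return Binary matrix with dimnames `site1..` / `strain1..`.
#' @export
simulate_genotypes <- function(n_sites, n_strains, min_hamming = 1, seed = 1) {
  n_sites <- check_count(n_sites, "n_sites", min = 1)
  n_strains <- check_count(n_strains, "n_strains", min = 1)
  min_hamming <- check_count(min_hamming, "min_hamming", min = 1)
  if (min_hamming > n_sites) {
    stopf("min_hamming (%d) cannot exceed n_sites (%d)", min_hamming, n_sites)
  }
  if (n_sites < 60 && 2^n_sites < n_strains) {
    stopf("infeasible: only %d distinct binary columns exist for %d sites",
          2^n_sites, n_sites)
  }
  with_seed(derive_seed(seed, "genotypes"), {
    g <- matrix(NA_integer_, n_sites, n_strains)
    max_tries <- 5000L
    k <- 0L
    tries <- 0L
    while (k < n_strains) {
      cand <- as.integer(runif(n_sites) < 0.5)
      ok <- TRUE
      if (k > 0) {
        for (j in seq_len(k)) {
          if (sum(cand != g[, j]) < min_hamming) { ok <- FALSE; break }
        }
      }
      if (ok) {
        k <- k + 1L
        g[, k] <- cand
      }
      tries <- tries + 1L
      if (tries > max_tries) {
        stopf("infeasible: could not place %d strains at pairwise Hamming >= %d over %d sites",
              n_strains, min_hamming, n_sites)
      }
    }
    if (n_strains > 1 && all(apply(g, 1, function(r) length(unique(r))) == 1)) {
      # guaranteed not to happen when min_hamming >= 1, but keep the contract explicit
      stopf("no polymorphic site across strains")
    }
    dimnames(g) <- list(paste0("site", seq_len(n_sites)),
                        paste0("strain", seq_len(n_strains)))
    g
  })
}

#' Assemble a ground-truth strain community
#'
#' Bundles a binary genotype matrix and a simplex abundance matrix into the
#' latent object the deconvolution stage tries to recover, together with the
#' expected read depth per site and timepoint.
#'
#' @param genotypes Binary sites x strains matrix.
#' @param abundances Strains x timepoints matrix, columns summing to 1.
#' @param depth Scalar expected depth, or a sites x timepoints matrix.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `strain_truth`.
#' @export
strain_truth <- function(genotypes, abundances, depth = 50, seed = 1) {
  genotypes <- as.matrix(genotypes)
  abundances <- as.matrix(abundances)
  if (!all(genotypes %in% c(0, 1))) stopf("genotypes must be 0/1")
  if (ncol(genotypes) != nrow(abundances)) {
    stopf("genotypes has %d strains but abundances has %d",
          ncol(genotypes), nrow(abundances))
  }
  if (ncol(genotypes) > 1 && anyDuplicated(t(genotypes))) {
    stopf("two strain genotype columns are identical")
  }
  cs <- colSums(abundances)
  if (any(abundances < 0) || any(abs(cs - 1) > 1e-9)) {
    stopf("abundance columns must be nonnegative and sum to 1 within 1e-9")
  }
  dp <- if (length(depth) == 1) {
    matrix(depth, nrow(genotypes), ncol(abundances))
  } else as.matrix(depth)
  if (!all(dim(dp) == c(nrow(genotypes), ncol(abundances)))) {
    stopf("depth_profile must be sites x timepoints")
  }
  structure(list(genotypes = genotypes, abundances = abundances,
                 depth_profile = dp, seed = as.integer(seed)),
            class = "strain_truth")
}

#' @rdname strain_truth
#' @param truth A `strain_truth` object.
#' @return `expected_frequencies()`: the sites x timepoints matrix of
#'   expected alternate-allele frequencies `G %*% A` (entries in `[0, 1]`).
#' @export
expected_frequencies <- function(truth) {
  stopifnot(inherits(truth, "strain_truth"))
  f <- truth$genotypes %*% truth$abundances
  dimnames(f) <- list(rownames(truth$genotypes), colnames(truth$abundances))
  f
}

#' @export
print.strain_truth <- function(x, ...) {
  cat(sprintf("strain_truth: %d sites x %d strains x %d timepoints (seed %d)\n",
              nrow(x$genotypes), ncol(x$genotypes), ncol(x$abundances), x$seed))
  invisible(x)
}

#' Simulate a read-count pileup from a strain community
#'
#' Draws per-site per-timepoint total depths (Poisson, or negative binomial
#' when `dispersion > 0`) and alternate-allele counts (binomial with success
#' probability equal to the community allele frequency `G %*% A`, plus an
#' optional symmetric error rate). This is the pileup-level stand-in for
#' mapped-read output consumed by downstream SNV calling.
#'
#' @param truth A [strain_truth()] object.
#' @param mean_depth Expected depth; overrides `truth$depth_profile` when
#'   given (default uses the profile).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial overdispersion (0 = Poisson). The NB
#'   variance is `mu + dispersion * mu^2`.
#' @param error_rate Per-read probability that an allele is misread as its
#'   complement class (alters the binomial success probability to
#'   `p (1 - e) + (1 - p) e`). Default 0.
#' @param site_coords Optional data.frame (contig, position, ref_base,
#'   alt_base) for the sites; synthesized deterministically when absent.
#' @return A `pileup` object: list with integer matrices `alt_counts`,
#'   `total_counts` (sites x timepoints) and data.frame `site_coords`.
#' @export
simulate_allele_counts <- function(truth, mean_depth = NULL, seed = 1,
                                   dispersion = 0, error_rate = 0,
                                   site_coords = NULL) {
  stopifnot(inherits(truth, "strain_truth"))
  p <- expected_frequencies(truth)
  dp <- truth$depth_profile
  if (!is.null(mean_depth)) {
    if (mean_depth <= 0) stopf("`mean_depth` must be > 0")
    dp <- matrix(mean_depth, nrow(p), ncol(p))
  }
  if (error_rate < 0 || error_rate > 0.5) stopf("`error_rate` must be in [0, 0.5]")
  p_obs <- p * (1 - error_rate) + (1 - p) * error_rate
  # guard against 1 + eps from the matrix product
  p_obs <- pmin(pmax(p_obs, 0), 1)
  with_seed(derive_seed(seed, "counts"), {
    n <- length(p)
    tot <- if (dispersion > 0) {
      rnbinom(n, size = 1 / dispersion, mu = as.vector(dp))
    } else {
      rpois(n, as.vector(dp))
    }
    alt <- rbinom(n, size = tot, prob = as.vector(p_obs))
    alt_m <- matrix(as.integer(alt), nrow(p), dimnames = dimnames(p))
    tot_m <- matrix(as.integer(tot), nrow(p), dimnames = dimnames(p))
    if (is.null(site_coords)) {
      site_coords <- data.frame(
        contig = "sim_contig",
        position = 10L * seq_len(nrow(p)),
        ref_base = "A", alt_base = "G",
        stringsAsFactors = FALSE
      )
    }
    new_pileup(alt_m, tot_m, site_coords)
  })
}

new_pileup <- function(alt_counts, total_counts, site_coords) {
  if (any(alt_counts < 0) || any(alt_counts > total_counts)) {
    stopf("pileup invariant violated: need 0 <= alt_counts <= total_counts")
  }
  if (anyDuplicated(site_coords[, c("contig", "position")])) {
    stopf("pileup positions must be unique per contig")
  }
  structure(list(alt_counts = alt_counts, total_counts = total_counts,
                 site_coords = site_coords),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d sites x %d timepoints, mean depth %.1f\n",
              nrow(x$total_counts), ncol(x$total_counts),
              mean(x$total_counts)))
  invisible(x)
}

#' Simulate a genome of protein-coding genes
#'
#' Builds one contig carrying `n_genes` stop-free coding genes with the
#' requested GC content, alternating between the + and - strands and
#' separated by random intergenic spacers. Codons are drawn
#' nucleotide-by-nucleotide with `P(G) = P(C) = gc_fraction / 2`, rejecting
#' stop codons, so translations never contain an internal stop.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length Gene length in bases, divisible by 3.
#' @param gc_fraction Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param translation_table Genetic code identifier as used by
#'   [Biostrings::getGeneticCode()]; default `"11"` (bacteria/archaea).
#' @param intergenic Spacer length between genes.
#' @return A `synthetic_genome`: list with `contigs`
#'   ([Biostrings::DNAStringSet]), `genes` data.frame (gene_id, contig,
#'   start, end, strand; 1-based inclusive) and `translation_table`.
#' @export
simulate_coding_genes <- function(n_genes, gene_length, gc_fraction, seed = 1,
                                  translation_table = "11", intergenic = 60L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  if (gene_length %% 3 != 0 || gene_length < 3) {
    stopf("`gene_length` must be a positive multiple of 3 (got %s)", gene_length)
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) stopf("`gc_fraction` must be in (0, 1)")
  code <- Biostrings::getGeneticCode(translation_table)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
             (1 - gc_fraction) / 2)
  stops <- names(code)[code == "*"]
  with_seed(derive_seed(seed, "genome"), {
    draw_codons <- function(n) {
      m <- matrix(sample(bases, 3 * n, replace = TRUE, prob = probs), 3, n)
      cods <- paste0(m[1, ], m[2, ], m[3, ])
      repeat {
        bad <- which(cods %in% stops)
        if (!length(bad)) return(cods)
        m2 <- matrix(sample(bases, 3 * length(bad), replace = TRUE,
                            prob = probs), 3)
        cods[bad] <- paste0(m2[1, ], m2[2, ], m2[3, ])
      }
    }
    spacer <- function(n) paste(sample(bases, n, replace = TRUE, prob = probs),
                                collapse = "")
    pieces <- character(0)
    genes <- vector("list", n_genes)
    pos <- 0L
    for (g in seq_len(n_genes)) {
      sp <- spacer(intergenic)
      pieces <- c(pieces, sp)
      pos <- pos + intergenic
      cds <- paste(draw_codons(gene_length / 3), collapse = "")
      strand <- if (g %% 2 == 1) "+" else "-"
      genomic <- if (strand == "+") cds else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      }
      pieces <- c(pieces, genomic)
      genes[[g]] <- data.frame(
        gene_id = sprintf("gene_%03d", g), contig = "ctg1",
        start = pos + 1L, end = pos + gene_length, strand = strand,
        stringsAsFactors = FALSE
      )
      pos <- pos + gene_length
    }
    pieces <- c(pieces, spacer(intergenic))
    contigs <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(contigs) <- "ctg1"
    structure(list(contigs = contigs, genes = do.call(rbind, genes),
                   translation_table = translation_table),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d contig(s), %d gene(s), code %s\n",
              length(x$contigs), nrow(x$genes), x$translation_table))
  invisible(x)
}

#' Extract a gene's coding sequence (5'->3')
#'
#' @param genome A `synthetic_genome` (or compatible list with `contigs`,
#'   `genes`, `translation_table`).
#' @param gene_id Gene identifier.
#' @return Character scalar, the in-frame coding sequence.
#' @export
coding_sequence <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stopf("unknown gene '%s'", gene_id)
  s <- Biostrings::subseq(genome$contigs[[g$contig]], g$start, g$end)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Inject variants with known coding effects
#'
#' Plants `n_variants` single-base substitutions at distinct coding
#' positions of a synthetic genome, choosing synonymous and nonsynonymous
#' changes so that the realized nonsynonymous fraction matches
#' `target_nonsyn_fraction` within one-variant rounding. Changes creating a
#' stop codon are never injected (nonsense effects are a separate category
#' downstream). Every variant carries its true effect by construction,
#' giving downstream annotation an exact oracle.
#'
#' @param genome A [simulate_coding_genes()] genome.
#' @param n_variants Number of variants.
#' @param target_nonsyn_fraction Fraction of nonsynonymous variants in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return data.frame: contig, position, ref_base, alt_base, gene_id,
#'   effect, aa_ref, aa_alt, codon_position.
#' @export
inject_variants <- function(genome, n_variants, target_nonsyn_fraction, seed = 1) {
  n_variants <- check_count(n_variants, "n_variants", min = 1)
  if (target_nonsyn_fraction < 0 || target_nonsyn_fraction > 1) {
    stopf("`target_nonsyn_fraction` must be in [0, 1]")
  }
  cand <- enumerate_coding_changes(genome)
  cand <- cand[cand$effect != "nonsense", , drop = FALSE]
  n_ns <- round(n_variants * target_nonsyn_fraction)
  with_seed(derive_seed(seed, "variants"), {
    # one random candidate change per genomic position, then fill the two
    # effect quotas in shuffled order
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$contig, cand$position)), , drop = FALSE]
    ns_pool <- which(cand$effect == "nonsynonymous")
    s_pool <- which(cand$effect == "synonymous")
    n_s <- n_variants - n_ns
    if (length(ns_pool) < n_ns || length(s_pool) < n_s) {
      stopf("insufficient eligible positions: needed %d nonsynonymous and %d synonymous, found %d and %d",
            n_ns, n_s, length(ns_pool), length(s_pool))
    }
    out <- cand[c(ns_pool[seq_len(n_ns)], s_pool[seq_len(n_s)]), , drop = FALSE]
    out <- out[order(out$contig, out$position), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# every possible single-base change in every codon of every gene, with its
# true effect under the genome's genetic code (vectorized per gene)
enumerate_coding_changes <- function(genome) {
  code <- Biostrings::getGeneticCode(genome$translation_table)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  res <- vector("list", nrow(genome$genes))
  for (gi in seq_len(nrow(genome$genes))) {
    g <- genome$genes[gi, ]
    cds <- coding_sequence(genome, g$gene_id)
    len <- nchar(cds)
    cds_v <- strsplit(cds, "")[[1]]
    pos0 <- seq_len(len) - 1L
    within <- pos0 %% 3L + 1L
    codon_start <- pos0 %/% 3L * 3L + 1L
    codons <- substring(cds, codon_start, codon_start + 2L)
    aa_ref <- unname(code[codons])
    genome_pos <- if (g$strand == "+") g$start + pos0 else g$end - pos0
    per_base <- lapply(bases, function(b) {
      keep <- cds_v != b
      mut <- paste0(substr(codons[keep], 1, within[keep] - 1L), b,
                    substr(codons[keep], within[keep] + 1L, 3L))
      aa_alt <- unname(code[mut])
      data.frame(
        contig = g$contig,
        position = genome_pos[keep],
        ref_base = if (g$strand == "+") cds_v[keep] else unname(comp[cds_v[keep]]),
        alt_base = if (g$strand == "+") b else unname(comp[[b]]),
        gene_id = g$gene_id,
        effect = ifelse(aa_alt == "*", "nonsense",
                        ifelse(aa_alt == aa_ref[keep], "synonymous",
                               "nonsynonymous")),
        aa_ref = aa_ref[keep], aa_alt = aa_alt,
        codon_position = within[keep],
        stringsAsFactors = FALSE
      )
    })
    res[[gi]] <- do.call(rbind, per_base)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a complete synthetic study
#'
#' Convenience wrapper tying the generators together: a coding genome,
#' injected variant sites, strain genotypes over those sites, abundance
#' sweeps and the resulting pileup. This is the one-call entry point used by
#' the pipeline's simulate stage and by end-to-end tests.
#'
#' @param n_strains,n_timepoints,sweep_pattern,noise_sd Passed to
#'   [simulate_abundance_trajectories()].
#' @param n_sites Number of variant sites.
#' @param n_genes,gene_length,gc_fraction Passed to
#'   [simulate_coding_genes()].
#' @param target_nonsyn_fraction Passed to [inject_variants()].
#' @param mean_depth,dispersion,error_rate Passed to
#'   [simulate_allele_counts()].
#' @param min_hamming Passed to [simulate_genotypes()].
#' @param seed Top-level seed.
#' @return List: `genome`, `variants`, `truth`, `pileup`.
#' @export
simulate_study <- function(n_strains = 3, n_timepoints = 8,
                           sweep_pattern = "serial_replacement",
                           n_sites = 100, n_genes = 10, gene_length = 900,
                           gc_fraction = 0.5, target_nonsyn_fraction = 0.5,
                           mean_depth = 50, noise_sd = 0, dispersion = 0,
                           error_rate = 0, min_hamming = 2, seed = 1) {
  genome <- simulate_coding_genes(n_genes, gene_length, gc_fraction,
                                  seed = derive_seed(seed, "study", "genome"))
  variants <- inject_variants(genome, n_sites, target_nonsyn_fraction,
                              seed = derive_seed(seed, "study", "variants"))
  genotypes <- simulate_genotypes(n_sites, n_strains, min_hamming = min_hamming,
                                  seed = derive_seed(seed, "study", "geno"))
  abundances <- simulate_abundance_trajectories(
    n_strains, n_timepoints, sweep_pattern, noise_sd = noise_sd,
    seed = derive_seed(seed, "study", "abund"))
  truth <- strain_truth(genotypes, abundances, depth = mean_depth, seed = seed)
  pileup <- simulate_allele_counts(
    truth, seed = derive_seed(seed, "study", "pileup"),
    dispersion = dispersion, error_rate = error_rate,
    site_coords = variants[, c("contig", "position", "ref_base", "alt_base")])
  list(genome = genome, variants = variants, truth = truth, pileup = pileup)
}
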