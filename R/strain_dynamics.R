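#' Cluster SNV frequency trajectories
#'
#' Groups SNVs whose alternate-allele frequencies move coherently over time
#' — the signature of variants riding on the same strain background —
#' using hierarchical clustering cut at a fixed height. The default
#' distance is `1 - Pearson correlation` between trajectories (computed on
#' pairwise-complete timepoints), so rising and falling variants separate
#' regardless of their absolute frequency level; Euclidean distance is
#' available as an alternative.
#'
#' SNVs with fewer than two non-missing timepoints, or with zero temporal
#' variance under correlation distance (fixed variants carry no temporal
#' signal and have undefined correlation), are routed to the unassigned
#' group, as are members of clusters smaller than `min_cluster_size`.
#'
#' @param freq_matrix Sites x timepoints matrix from [frequency_matrix()],
#'   `NA` = missing.
#' @param linkage Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param cut_threshold Tree cut height (correlation-distance units by
#'   default).
#' @param min_cluster_size Clusters smaller than this are unassigned.
#' @return A `trajectory_clustering`: list with `assignment` (named integer
#'   vector, `0` = unassigned), `clusters` (list of member-id character
#'   vectors), `mean_profiles` (clusters x timepoints), `cohesion` (mean
#'   within-cluster similarity per cluster).
#' @export
cluster_trajectories <- function(freq_matrix, linkage = "average",
                                 distance = c("correlation", "euclidean"),
                                 cut_threshold = 0.25, min_cluster_size = 2) {
  distance <- match.arg(distance)
  f <- as.matrix(freq_matrix)
  if (is.null(rownames(f))) rownames(f) <- paste0("snv", seq_len(nrow(f)))
  ids <- rownames(f)
  assignment <- setNames(integer(nrow(f)), ids)
  n_obs <- rowSums(!is.na(f))
  usable <- n_obs >= 2
  if (distance == "correlation") {
    vr <- apply(f, 1, function(r) stats::var(r[!is.na(r)]))
    usable <- usable & !is.na(vr) & vr > 0
  }
  if (!any(usable)) {
    warnf("no SNV trajectory has enough observed, varying timepoints; all unassigned")
    return(new_trajectory_clustering(assignment, f))
  }
  fu <- f[usable, , drop = FALSE]
  if (nrow(fu) == 1) {
    assignment[rownames(fu)] <- 1L
    return(new_trajectory_clustering(assignment, f))
  }
  if (distance == "correlation") {
    cc <- suppressWarnings(cor(t(fu), use = "pairwise.complete.obs"))
    d <- 1 - cc
    d[is.na(d)] <- 2 # disjoint observation patterns: maximally distant
  } else {
    d <- as.matrix(stats::dist(fu))
    d[is.na(d)] <- max(d, na.rm = TRUE) + 1
  }
  hc <- hclust(as.dist(d), method = linkage)
  cl <- cutree(hc, h = cut_threshold)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  cl[cl %in% small] <- 0L
  # renumber surviving clusters by size (largest first)
  kept <- sort(table(cl[cl > 0]), decreasing = TRUE)
  remap <- setNames(seq_along(kept), names(kept))
  cl <- ifelse(cl > 0, remap[as.character(cl)], 0L)
  assignment[rownames(fu)] <- as.integer(cl)
  new_trajectory_clustering(assignment, f, d)
}

new_trajectory_clustering <- function(assignment, f, d = NULL) {
  ks <- sort(unique(assignment[assignment > 0]))
  clusters <- lapply(ks, function(k) names(assignment)[assignment == k])
  if (length(ks)) names(clusters) <- paste0("cluster", ks)
  mean_profiles <- if (length(ks)) {
    t(vapply(clusters, function(m) colMeans(f[m, , drop = FALSE], na.rm = TRUE),
             numeric(ncol(f))))
  } else matrix(numeric(0), 0, ncol(f))
  mean_profiles[is.nan(mean_profiles)] <- NA_real_
  colnames(mean_profiles) <- colnames(f)
  cohesion <- vapply(clusters, function(m) {
    if (length(m) < 2 || is.null(d)) return(NA_real_)
    dd <- d[m, m, drop = FALSE]
    1 - mean(dd[upper.tri(dd)])
  }, numeric(1))
  structure(list(assignment = assignment, clusters = clusters,
                 mean_profiles = mean_profiles, cohesion = cohesion),
            class = "trajectory_clustering")
}

#' @export
print.trajectory_clustering <- function(x, ...) {
  cat(sprintf("trajectory_clustering: %d clusters, %d SNVs (%d unassigned)\n",
              length(x$clusters), length(x$assignment),
              sum(x$assignment == 0)))
  invisible(x)
}

#' Mean frequency profiles of trajectory clusters
#'
#' The per-cluster arithmetic mean trajectory over member SNVs, ignoring
#' missing entries (the bold summary lines of a cluster plot). Timepoints
#' where every member is missing are `NA`; empty clusters are dropped with
#' a warning.
#'
#' @param clustering A `trajectory_clustering`, or a list of member-id
#'   vectors together with `freq_matrix`.
#' @param freq_matrix Required when `clustering` is a plain list of member
#'   vectors.
#' @return Clusters x timepoints matrix.
#' @export
cluster_mean_profiles <- function(clustering, freq_matrix = NULL) {
  if (inherits(clustering, "trajectory_clustering")) {
    return(clustering$mean_profiles)
  }
  if (is.null(freq_matrix)) stopf("`freq_matrix` is required for a plain cluster list")
  keep <- lengths(clustering) > 0
  if (!all(keep)) {
    warnf("dropping %d empty cluster(s)", sum(!keep))
    clustering <- clustering[keep]
  }
  if (!length(clustering)) return(matrix(numeric(0), 0, ncol(freq_matrix)))
  out <- t(vapply(clustering,
                  function(m) colMeans(freq_matrix[m, , drop = FALSE], na.rm = TRUE),
                  numeric(ncol(freq_matrix))))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- colnames(freq_matrix)
  out
}

# exact simplex-constrained weighted least squares:
# minimize ||sqrt(w) * (G a - f)||^2 s.t. a >= 0, sum(a) = 1,
# by enumerating active sets (nonzero-support subsets) and solving each
# equality-constrained system; exact for the small strain counts used here
simplex_lsq <- function(G, f, w = NULL) {
  S <- ncol(G)
  if (is.null(w)) w <- rep(1, length(f))
  ok <- w > 0 & !is.na(f)
  if (!any(ok)) return(rep(1 / S, S))
  G <- G[ok, , drop = FALSE]
  fv <- f[ok]
  wv <- w[ok]
  GtWG <- crossprod(G * wv, G)
  GtWf <- crossprod(G * wv, fv)
  best <- NULL
  best_obj <- Inf
  wf2 <- sum(wv * fv^2)
  # singleton supports have the closed form a = e_s
  for (s in seq_len(S)) {
    obj <- wf2 - 2 * GtWf[s] + GtWG[s, s]
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- replace(rep(0, S), s, 1)
    }
  }
  if (S > 1) {
    for (mask in seq_len(2^S - 1)) {
      sub <- which(bitwAnd(mask, 2^(seq_len(S) - 1)) > 0)
      k <- length(sub)
      if (k < 2) next
      M <- rbind(cbind(GtWG[sub, sub, drop = FALSE] +
                         diag(1e-10, k), rep(1, k)),
                 c(rep(1, k), 0))
      rhs <- c(GtWf[sub], 1)
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a_sub <- sol[seq_len(k)]
      if (any(a_sub < -1e-9)) next
      a <- rep(0, S)
      a[sub] <- pmax(a_sub, 0)
      a <- a / sum(a)
      r <- fv - G %*% a
      obj <- sum(wv * r^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- a
      }
    }
  }
  if (is.null(best)) rep(1 / S, S) else best
}

# best binary genotype row per site given A: enumerate all 2^S candidates;
# ties broken toward the previous iterate, then lexicographically
gstep_binary <- function(F, W, A, G_prev = NULL) {
  S <- nrow(A)
  cand <- as.matrix(expand.grid(rep(list(c(0, 1)), S)))[, S:1, drop = FALSE]
  # lexicographic candidate order: row 1 = (0,..,0), then counting up
  P <- cand %*% A                       # K x T predicted frequencies
  WF <- W * F
  c0 <- rowSums(WF * F)                 # site-wise constant term
  cross <- WF %*% t(P)                  # V x K
  quad <- W %*% t(P^2)                  # V x K
  err <- matrix(c0, nrow(F), nrow(cand)) - 2 * cross + quad
  V <- nrow(F)
  # first minimum = lexicographically smallest row (cand is in binary order)
  pick <- max.col(-err, ties.method = "first")
  if (!is.null(G_prev)) {
    # tie-break toward the previous iterate for stability
    prev_k <- 1L + as.integer(G_prev %*% 2^(S - seq_len(S)))
    emin <- err[cbind(seq_len(V), pick)]
    eprev <- err[cbind(seq_len(V), prev_k)]
    stay <- eprev <= emin + 1e-12
    pick[stay] <- prev_k[stay]
  }
  G <- cand[pick, , drop = FALSE]
  storage.mode(G) <- "integer"
  dimnames(G) <- NULL
  G
}

#' Deconvolve allele frequencies into strain genotypes and abundances
#'
#' Factorizes a sites x timepoints SNV frequency matrix `F` into a binary
#' genotype matrix `G` (sites x strains) and an abundance matrix `A`
#' (strains x timepoints, columns on the probability simplex) by locally
#' minimizing the depth-weighted squared error `||F - G A||^2`. The model
#' is the mixture identity of pooled sequencing: the community frequency of
#' an allele is the abundance-weighted sum of the strains that carry it.
#'
#' Optimization alternates an exact simplex-constrained least-squares
#' A-step (per timepoint) with an exhaustive per-site binary G-step (all
#' `2^n_strains` candidate rows; ties broken toward the previous iterate,
#' then lexicographically), from multiple restarts with deterministically
#' derived seeds. Restart initialization uses trajectory-cluster mean
#' profiles when supplied, otherwise random simplex draws. This is an
#' allele-frequency factorization in the spirit of assembly-graph strain
#' deconvolvers, not a re-implementation of any of them: no read linkage or
#' graph structure is used.
#'
#' Missing frequencies get weight 0. `n_strains > 10` is refused (the
#' G-step is exponential in strain count); split the site set
#' hierarchically instead.
#'
#' @param freq_matrix Sites x timepoints matrix, entries in `[0,1]` or `NA`.
#' @param weights Optional per-entry nonnegative weights (e.g. read depth).
#' @param n_strains Number of strains to fit (>= 1).
#' @param n_restarts Number of random restarts (default 20).
#' @param max_iter Maximum alternations per restart.
#' @param seed Integer seed for restart initializations.
#' @param init_profiles Optional strains x timepoints matrix (for example
#'   cluster mean profiles) used to initialize the first restart.
#' @return A `strain_model`: list with `genotypes`, `abundances`,
#'   `n_strains`, `rss` (weighted residual sum of squares), `score` (BIC),
#'   `n_obs`, `converged`.
#' @export
deconvolve_strains <- function(freq_matrix, weights = NULL, n_strains,
                               n_restarts = 20, max_iter = 100, seed = 1,
                               init_profiles = NULL) {
  n_strains <- check_count(n_strains, "n_strains", min = 1)
  if (n_strains > 10) {
    stopf("n_strains > 10 refused: the exhaustive genotype step is exponential; split the site set hierarchically")
  }
  F <- as.matrix(freq_matrix)
  V <- nrow(F); TT <- ncol(F)
  if (TT < 2) stopf("need >= 2 timepoints")
  W <- if (is.null(weights)) matrix(1, V, TT) else as.matrix(weights)
  if (any(W < 0)) stopf("weights must be nonnegative")
  W[is.na(F)] <- 0
  F[is.na(F)] <- 0
  if (V < n_strains) {
    warnf("fewer sites (%d) than strains (%d): the factorization is weakly identifiable",
          V, n_strains)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    A0 <- if (r == 1 && !is.null(init_profiles) &&
              nrow(init_profiles) >= n_strains) {
      # turn cluster mean profiles into simplex columns
      P <- init_profiles[seq_len(n_strains), , drop = FALSE]
      P[is.na(P)] <- 0.5
      P <- pmax(P, 1e-3)
      sweep(P, 2, colSums(P), "/")
    } else {
      with_seed(derive_seed(seed, "deconv", n_strains, r), {
        draws <- matrix(rgamma(n_strains * TT, 1), n_strains, TT)
        sweep(draws, 2, colSums(draws), "/")
      })
    }
    fit <- alternate_fit(F, W, A0, max_iter)
    if (is.null(best) || fit$rss < best$rss - 1e-12) best <- fit
  }
  G <- best$G
  A <- best$A
  dimnames(G) <- list(rownames(freq_matrix), paste0("strain", seq_len(n_strains)))
  dimnames(A) <- list(paste0("strain", seq_len(n_strains)), colnames(freq_matrix))
  n_obs <- sum(W > 0)
  structure(list(genotypes = G, abundances = A, n_strains = n_strains,
                 rss = best$rss, n_obs = n_obs,
                 score = strain_model_score(best$rss, G, A, n_obs),
                 converged = best$converged),
            class = "strain_model")
}

alternate_fit <- function(F, W, A, max_iter) {
  G <- NULL
  rss <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G_new <- gstep_binary(F, W, A, G)
    A_new <- A
    for (t in seq_len(ncol(F))) {
      A_new[, t] <- simplex_lsq(G_new, F[, t], W[, t])
    }
    r <- F - G_new %*% A_new
    rss_new <- sum(W * r^2)
    if (!is.null(G) && identical(G_new, G) && rss - rss_new < 1e-10) {
      converged <- TRUE
      G <- G_new; A <- A_new; rss <- rss_new
      break
    }
    G <- G_new; A <- A_new; rss <- rss_new
  }
  list(G = G, A = A, rss = rss, converged = converged)
}

# BIC-style model-selection score under a Gaussian pseudo-likelihood;
# parameter count = V * S_distinct + S * (T - 1)
strain_model_score <- function(rss, G, A, n_obs) {
  S_eff <- nrow(unique(t(G)))
  k <- nrow(G) * S_eff + nrow(A) * (ncol(A) - 1)
  n_obs * log(max(rss, 1e-12) / n_obs) + k * log(n_obs)
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf("strain_model: %d strains, %d sites x %d timepoints, RSS %.4g (BIC %.1f)\n",
              x$n_strains, nrow(x$genotypes), ncol(x$abundances), x$rss, x$score))
  invisible(x)
}

#' Choose the number of strains by penalized model selection
#'
#' Fits 1..`s_max` strains with [deconvolve_strains()] and returns the model
#' minimizing a BIC-style score (Gaussian pseudo-likelihood of the weighted
#' residual plus `log(n)` times the parameter count `V * S_distinct +
#' S * (T-1)`). The full score path is attached so the selection is
#' auditable.
#'
#' @inheritParams deconvolve_strains
#' @param s_max Largest strain count to try.
#' @param ... Passed to [deconvolve_strains()].
#' @return The selected `strain_model` with an extra `score_path`
#'   data.frame (n_strains, rss, score).
#' @export
select_strain_number <- function(freq_matrix, weights = NULL, s_max = 5, ...) {
  s_max <- check_count(s_max, "s_max", min = 1)
  fits <- lapply(seq_len(s_max), function(s) {
    deconvolve_strains(freq_matrix, weights, n_strains = s, ...)
  })
  path <- data.frame(
    n_strains = seq_len(s_max),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    score = vapply(fits, `[[`, numeric(1), "score")
  )
  best <- fits[[which.min(path$score)]]
  best$score_path <- path
  best
}

#' Weight strain abundances by the species' community abundance
#'
#' Within-species strain fractions multiplied by the MAG's relative
#' abundance per timepoint give community-scale strain abundances; column
#' sums then equal the MAG relative-abundance trajectory.
#'
#' @param model A `strain_model` (or a strains x timepoints matrix).
#' @param mag_ra Numeric vector of MAG relative abundances, one per
#'   timepoint, entries in `[0, 1]`.
#' @return Strains x timepoints matrix of community-scale abundances.
#' @export
weight_by_mag_abundance <- function(model, mag_ra) {
  A <- if (inherits(model, "strain_model")) model$abundances else as.matrix(model)
  if (length(mag_ra) != ncol(A)) {
    stopf("mag_ra has %d entries but the model has %d timepoints",
          length(mag_ra), ncol(A))
  }
  if (any(mag_ra < 0 | mag_ra > 1)) stopf("mag_ra entries must be in [0, 1]")
  sweep(A, 2, mag_ra, "*")
}

#' Match inferred strains to a ground truth and score recovery
#'
#' Strain labels are arbitrary under the factorization (any relabeling has
#' the same residual), so recovery is scored after the optimal one-to-one
#' strain matching: the label permutation minimizing abundance RMSE is
#' found by enumeration and applied before comparing genotypes.
#'
#' @param model A `strain_model`.
#' @param truth A [strain_truth()] with the same strain count.
#' @return List: `genotype_accuracy` (fraction of correct G entries),
#'   `abundance_rmse`, `permutation` (truth strain order applied to the
#'   model).
#' @export
match_strains <- function(model, truth) {
  stopifnot(inherits(truth, "strain_truth"))
  A <- model$abundances
  G <- model$genotypes
  S <- nrow(A)
  if (S != nrow(truth$abundances)) {
    stopf("model has %d strains, truth has %d", S, nrow(truth$abundances))
  }
  perms <- all_permutations(S)
  rmse <- vapply(perms, function(p) {
    sqrt(mean((A[p, , drop = FALSE] - truth$abundances)^2))
  }, numeric(1))
  p <- perms[[which.min(rmse)]]
  list(
    genotype_accuracy = mean(G[, p, drop = FALSE] == truth$genotypes),
    abundance_rmse = min(rmse),
    permutation = p
  )
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
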