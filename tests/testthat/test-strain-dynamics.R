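test_that("identical trajectories form one cluster; opposite ones split", {
  up <- seq(0.1, 0.9, length.out = 5)
  f1 <- matrix(rep(up, each = 10), 10, byrow = FALSE)
  rownames(f1) <- paste0("s", 1:10)
  cl1 <- cluster_trajectories(f1, min_cluster_size = 2)
  expect_equal(length(cl1$clusters), 1)
  expect_equal(length(cl1$clusters[[1]]), 10)

  f2 <- rbind(matrix(rep(up, each = 5), 5),
              matrix(rep(rev(up), each = 5), 5))
  rownames(f2) <- paste0("s", 1:10)
  cl2 <- cluster_trajectories(f2, min_cluster_size = 2)
  expect_equal(length(cl2$clusters), 2)
  a <- cl2$assignment
  expect_equal(length(unique(a[1:5])), 1)
  expect_equal(length(unique(a[6:10])), 1)
  expect_false(a[1] == a[6])
})

test_that("zero-variance trajectories go to unassigned without errors", {
  up <- seq(0.1, 0.9, length.out = 5)
  f <- rbind(matrix(rep(up, each = 3), 3), rep(1, 5))
  rownames(f) <- c("a", "b", "c", "fixed")
  cl <- cluster_trajectories(f, distance = "correlation")
  expect_equal(unname(cl$assignment["fixed"]), 0L)
  # an all-missing matrix warns and returns an empty clustering
  fm <- matrix(NA_real_, 3, 4, dimnames = list(letters[1:3], NULL))
  expect_warning(cl0 <- cluster_trajectories(fm), "unassigned")
  expect_equal(length(cl0$clusters), 0)
})

test_that("cluster mean profiles average members with mask semantics", {
  f <- rbind(a = c(0.2, 0.4), b = c(0.4, 0.6), c = c(0.5, NA))
  prof <- cluster_mean_profiles(list(g1 = c("a", "b"), g2 = "c"), f)
  expect_equal(unname(prof["g1", ]), c(0.3, 0.5))
  # single-member cluster: profile equals the trajectory
  expect_equal(unname(prof["g2", 1]), 0.5)
  expect_true(is.na(prof["g2", 2]))
  # member missing at t2: mean over remaining members only
  prof2 <- cluster_mean_profiles(list(g = c("a", "c")), f)
  expect_equal(unname(prof2[1, ]), c(0.35, 0.4))
  expect_warning(cluster_mean_profiles(list(g = "a", empty = character(0)), f),
                 "empty")
})

test_that("one-strain deconvolution reduces to rounded means", {
  f <- rbind(c(0.9, 0.85, 0.95), c(0.1, 0.05, 0.02))
  m <- deconvolve_strains(f, n_strains = 1, n_restarts = 2, seed = 1)
  expect_equal(unname(m$genotypes[, 1]), c(1, 0))
  expect_equal(unname(m$abundances[1, ]), c(1, 1, 1))
  # residual equals total within-site deviation from the binary consensus
  expect_equal(m$rss, sum((f - c(1, 0))^2))
})

test_that("noiseless two-strain mixtures are recovered exactly", {
  set.seed(42)
  g <- simulate_genotypes(20, 2, 4, seed = 5)
  a <- simulate_abundance_trajectories(2, 6, "single_sweep", 0, seed = 5)
  f <- g %*% a
  m <- deconvolve_strains(f, n_strains = 2, n_restarts = 10, seed = 6)
  expect_lt(m$rss, 1e-12)
  tr <- strain_truth(g, a, seed = 1)
  sc <- match_strains(m, tr)
  expect_equal(sc$genotype_accuracy, 1)
  expect_lt(sc$abundance_rmse, 1e-6)
})

test_that("reconstructed frequencies stay in [0, 1] and labels are exchangeable", {
  st <- simulate_study(seed = 23, n_sites = 40, n_timepoints = 6)
  f <- frequency_matrix(call_snvs(st$pileup, 1, 0.01))
  m <- deconvolve_strains(f, n_strains = 3, n_restarts = 5, seed = 2)
  pred <- m$genotypes %*% m$abundances
  expect_true(all(pred >= -1e-9 & pred <= 1 + 1e-9))
  # any strain relabeling leaves the residual unchanged
  perm <- c(2, 3, 1)
  f0 <- f; f0[is.na(f0)] <- 0
  w <- !is.na(f)
  rss_perm <- sum(w * (f0 - m$genotypes[, perm] %*% m$abundances[perm, ])^2)
  expect_equal(rss_perm, m$rss, tolerance = 1e-9)
})

test_that("the refusal and degenerate paths of deconvolution hold", {
  f <- matrix(runif(20), 5, 4)
  expect_error(deconvolve_strains(f, n_strains = 11), "refused")
  expect_error(deconvolve_strains(f[, 1, drop = FALSE], n_strains = 1),
               "timepoints")
  # s_max = 1 degenerates to the one-strain fit
  sel <- select_strain_number(f, s_max = 1, n_restarts = 2, seed = 1)
  expect_equal(sel$n_strains, 1)
  expect_equal(nrow(sel$score_path), 1)
})

test_that("model selection prefers the true strain count", {
  # 1 strain, no noise: zero residual already at S = 1
  g1 <- matrix(c(1, 1, 0, 0, 1, 0), 6, 1)
  a1 <- matrix(1, 1, 5)
  f1 <- g1 %*% a1
  sel1 <- select_strain_number(f1, s_max = 3, n_restarts = 3, seed = 1)
  expect_equal(sel1$n_strains, 1)
  # 3 well-separated strains at depth 100
  st <- simulate_study(seed = 29, n_sites = 80, mean_depth = 100)
  full <- call_snvs(st$pileup, 1, 0.01)
  sel3 <- select_strain_number(frequency_matrix(full), weights = full$total,
                               s_max = 5, n_restarts = 10, seed = 3)
  expect_equal(sel3$n_strains, 3)
  expect_equal(which.min(sel3$score_path$score), 3)
})

test_that("MAG-abundance weighting rescales columns exactly", {
  A <- rbind(c(0.5, 0.25), c(0.5, 0.75))
  w <- weight_by_mag_abundance(A, c(0.04, 0))
  expect_equal(unname(w[, 1]), c(0.02, 0.02))
  expect_true(all(w[, 2] == 0))
  expect_equal(colSums(w), c(0.04, 0))
  # one strain: weighted row equals the MAG trajectory
  w1 <- weight_by_mag_abundance(matrix(1, 1, 3), c(0.1, 0.2, 0.3))
  expect_equal(unname(w1[1, ]), c(0.1, 0.2, 0.3))
  expect_error(weight_by_mag_abundance(A, c(0.1, 0.2, 0.3)), "timepoints")
})

test_that("genotype accuracy does not degrade as depth grows", {
  depths <- c(10, 25, 50, 100)
  acc <- sapply(depths, function(d) {
    mean(sapply(1:20, function(s) {
      st <- simulate_study(seed = derive_seed(s, "depthcurve"), n_sites = 60,
                           n_genes = 4, gene_length = 300,
                           n_timepoints = 8, mean_depth = d)
      full <- call_snvs(st$pileup, 1, 0.01)
      f <- frequency_matrix(full)
      m <- deconvolve_strains(f, weights = full$total, n_strains = 3,
                              n_restarts = 6, seed = derive_seed(s, "fit", d))
      keep <- match(paste(full$sites$contig, full$sites$position),
                    paste(st$pileup$site_coords$contig,
                          st$pileup$site_coords$position))
      tr <- strain_truth(st$truth$genotypes[keep, , drop = FALSE],
                         st$truth$abundances, seed = 1)
      match_strains(m, tr)$genotype_accuracy
    }))
  })
  expect_true(all(diff(acc) >= -0.01))
  expect_gt(acc[4], acc[1] - 1e-9)
})

test_that("SNVs private to one strain co-cluster at realistic depth", {
  st <- simulate_study(seed = 37, n_sites = 100, mean_depth = 50)
  snv <- call_snvs(st$pileup, 5, 0.05)
  f <- frequency_matrix(snv)
  cl <- cluster_trajectories(f, cut_threshold = 0.5, min_cluster_size = 2)
  keep <- match(paste(snv$sites$contig, snv$sites$position),
                paste(st$pileup$site_coords$contig,
                      st$pileup$site_coords$position))
  g <- st$truth$genotypes[keep, , drop = FALSE]
  rates <- sapply(1:3, function(s) {
    private <- g[, s] == 1 & rowSums(g) == 1
    a <- cl$assignment[private]
    a <- a[a > 0]
    if (length(a) < 2) return(NA_real_)
    max(table(a)) / length(a)
  })
  expect_gte(mean(rates, na.rm = TRUE), 0.9)
})
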