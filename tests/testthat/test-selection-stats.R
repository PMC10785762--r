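test_that("NG86 site counts match hand enumeration for landmark codons", {
  # TGG (Trp): every non-stop single-base change is nonsynonymous
  expect_equal(count_ng86_sites("TGG"),
               c(n_sites = 3, s_sites = 0))
  # GGG (Gly): third position fully synonymous
  s <- count_ng86_sites("GGG")
  expect_gte(s[["s_sites"]], 1)
  expect_equal(sum(s), 3)
  # conservation over a 9-codon gene
  g <- simulate_coding_genes(1, 27, 0.5, seed = 1)
  expect_equal(sum(count_ng86_sites(coding_sequence(g, "gene_001"))), 27)
  expect_error(count_ng86_sites("ATGTAAAAA"), "stop codon at codon 2")
  expect_error(count_ng86_sites("ATGA"))
})

test_that("site-count conservation holds across random synthetic genes", {
  for (s in 1:5) {
    g <- simulate_coding_genes(1, 300, runif(1, 0.3, 0.7), seed = s)
    counts <- count_ng86_sites(coding_sequence(g, "gene_001"))
    expect_equal(sum(counts), 300, tolerance = 1e-6)
    expect_true(all(counts >= 0))
  }
})

test_that("pN/pS handles zero and undefined cases by contract", {
  g <- tiny_genome()
  cds <- coding_sequence(g, "gene_plus")
  r0 <- gene_pnps(cds, c("synonymous", "synonymous", "synonymous"))
  expect_equal(r0$ratio, 0)
  r_undef <- gene_pnps(cds, c("nonsynonymous", "nonsynonymous"))
  expect_false(r_undef$ratio_defined)
  expect_true(is.na(r_undef$ratio))
  # continuity flag yields a finite ratio instead
  r_cont <- gene_pnps(cds, c("nonsynonymous", "nonsynonymous"),
                      continuity = TRUE)
  expect_true(r_cont$ratio_defined)
  expect_true(is.finite(r_cont$ratio))
  # nonsense tallied separately, excluded from the ratio
  r_non <- gene_pnps(cds, c("synonymous", "nonsense"))
  expect_equal(r_non$n_nonsense, 1)
  expect_equal(r_non$n_obs, 0)
})

test_that("selection flagging is strictly above threshold, never undefined", {
  stats <- data.frame(
    gene_id = c("a", "b", "c"),
    ratio = c(1.0, 1.01, NA),
    ratio_defined = c(TRUE, TRUE, FALSE)
  )
  expect_equal(flag_selected(stats), "b")
  expect_equal(flag_selected(stats, threshold = 0.5), c("a", "b"))
})

test_that("neutral injection calibrates pooled pN/pS near one", {
  g <- simulate_coding_genes(6, 600, 0.5, seed = 44)
  total <- Reduce(`+`, lapply(g$genes$gene_id, function(id) {
    count_ng86_sites(coding_sequence(g, id))
  }))
  target <- total[["n_sites"]] / sum(total)
  v <- inject_variants(g, 200, target, seed = 44)
  n <- nrow(v)
  pu <- strainsweep:::new_pileup(
    matrix(50L, n, 2), matrix(100L, n, 2),
    data.frame(contig = v$contig, position = v$position,
               ref_base = v$ref_base, alt_base = v$alt_base,
               stringsAsFactors = FALSE))
  ann <- annotate_effect(call_snvs(pu, 1, 0.01), g)
  tab <- pnps_table(ann, g)
  pooled <- (sum(tab$n_obs) / sum(tab$n_sites)) /
    (sum(tab$s_obs) / sum(tab$s_sites))
  expect_gt(pooled, 0.8)
  expect_lt(pooled, 1.25)
})

# brute-force oracle: enumerate all m-subsets of the pooled values
brute_force_ranksum_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  obs <- sum(r[seq_len(m)])
  sums <- combn(r, m, sum)
  if (alternative == "greater") mean(sums >= obs - 1e-9)
  else mean(sums <= obs + 1e-9)
}

test_that("exact rank-sum p equals brute-force enumeration, with and without ties", {
  set.seed(7)
  for (i in 1:5) {
    x <- round(runif(4, 0, 10), 1)
    y <- round(runif(7, 0, 10), 1)
    expect_equal(strainsweep:::rank_sum_exact_p(x, y, "greater"),
                 brute_force_ranksum_p(x, y, "greater"), tolerance = 1e-12)
  }
  # heavy ties (integer burdens with many zeros, the realistic case)
  x <- c(0, 0, 2, 3)
  y <- c(0, 0, 0, 1, 1, 2, 0)
  expect_equal(strainsweep:::rank_sum_exact_p(x, y, "greater"),
               brute_force_ranksum_p(x, y, "greater"), tolerance = 1e-12)
  expect_equal(strainsweep:::rank_sum_exact_p(x, y, "less"),
               brute_force_ranksum_p(x, y, "less"), tolerance = 1e-12)
})

test_that("a fully separated pathway attains the minimal exact p", {
  burden <- setNames(c(rep(10, 5) + (1:5) / 10, rep(1, 20) + (1:20) / 100),
                     paste0("g", 1:25))
  res <- pathway_enrichment(burden, paste0("g", 1:5))
  expect_equal(res$p_value, 1 / choose(25, 5), tolerance = 1e-12)
  expect_equal(res$direction, "enriched")
  expect_equal(res$method, "exact")
})

test_that("an upward-shifted pathway is called enriched; input errors are loud", {
  set.seed(3)
  bg <- rnorm(30, 5)
  burden <- setNames(c(bg[1:5] + 100, bg[6:30]), paste0("g", 1:30))
  res <- pathway_enrichment(burden, paste0("g", 1:5))
  expect_equal(res$direction, "enriched")
  expect_lt(res$p_value, 0.01)
  expect_error(pathway_enrichment(burden, character(0)), "empty")
  expect_error(pathway_enrichment(burden, "absent_gene"), "not in the burden")
})

test_that("adding an nsSNV to a pathway gene never increases the p-value", {
  set.seed(11)
  burden <- setNames(rpois(30, 2), paste0("g", 1:30))
  set_genes <- paste0("g", 1:6)
  p_before <- pathway_enrichment(burden, set_genes)$p_value
  for (gene in set_genes[1:3]) {
    b2 <- burden
    b2[gene] <- b2[gene] + 1
    p_after <- pathway_enrichment(b2, set_genes)$p_value
    expect_lte(p_after, p_before + 1e-12)
  }
})

test_that("enrichment tables cover a pathway map with optional adjustment", {
  set.seed(5)
  burden <- setNames(rpois(40, 2), paste0("g", 1:40))
  pm <- data.frame(gene_id = paste0("g", c(1:5, 6:12)),
                   pathway_id = rep(c("WL", "GSR"), c(5, 7)))
  tab <- enrichment_table(burden, pm, p_adjust = "BH")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
})
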