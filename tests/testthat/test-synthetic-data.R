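test_that("abundance trajectories live on the simplex for every pattern", {
  for (pat in c("stable", "single_sweep", "serial_replacement")) {
    a <- simulate_abundance_trajectories(3, 8, pat, noise_sd = 0, seed = 4)
    expect_equal(colSums(a), rep(1, 8), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(a >= 0))
  }
  # one strain: trivially the all-ones row
  a1 <- simulate_abundance_trajectories(1, 5, "stable", 0, seed = 1)
  expect_equal(unname(a1), matrix(1, 1, 5))
  # noisy columns still renormalize exactly
  an <- simulate_abundance_trajectories(2, 5, "stable", noise_sd = 0.05, seed = 2)
  expect_equal(colSums(an), rep(1, 5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("serial replacement changes the dominant strain at least twice", {
  a <- simulate_abundance_trajectories(3, 8, "serial_replacement", 0, seed = 1)
  dom <- apply(a, 2, which.max)
  expect_gte(sum(diff(dom) != 0), 2)
  # and each dominance window is contiguous (a sweep, not flicker)
  expect_equal(dom, sort(dom))
})

test_that("degenerate trajectory arguments are rejected", {
  expect_error(simulate_abundance_trajectories(0, 5, "stable", 0, 1))
  expect_error(simulate_abundance_trajectories(2, 1, "stable", 0, 1))
  expect_error(simulate_abundance_trajectories(2, 5, "stable", -0.1, 1))
})

test_that("simulated genotypes respect the Hamming separation contract", {
  g <- simulate_genotypes(50, 3, min_hamming = 10, seed = 7)
  expect_true(all(g %in% c(0, 1)))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(sum(g[, i] != g[, j]), 10)
  }
  # single strain: a single binary column
  g1 <- simulate_genotypes(10, 1, 1, seed = 1)
  expect_equal(dim(g1), c(10, 1))
  # pigeonhole: 3 distinct strains cannot exist over 1 site
  expect_error(simulate_genotypes(1, 3, 1, seed = 1), "infeasible")
  expect_error(simulate_genotypes(5, 2, 6, seed = 1))
})

test_that("allele counts follow the strain-mixture forward model", {
  g <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 4, 2)
  a <- rbind(c(0.3, 0.7), c(0.7, 0.3))
  tr <- strain_truth(g, a, depth = 50, seed = 1)
  p <- expected_frequencies(tr)
  expect_equal(p, g %*% a, ignore_attr = TRUE)
  pu <- simulate_allele_counts(tr, seed = 5)
  # site 1 (both strains carry alt): expected frequency 1 -> alt == total
  expect_equal(pu$alt_counts[1, ], pu$total_counts[1, ], ignore_attr = TRUE)
  # site 3 (no strain carries alt): expected frequency 0 -> alt == 0
  expect_true(all(pu$alt_counts[3, ] == 0))
  expect_true(all(pu$alt_counts <= pu$total_counts))
})

test_that("empirical allele frequencies concentrate on the expected matrix", {
  g <- simulate_genotypes(100, 3, 2, seed = 3)
  a <- simulate_abundance_trajectories(3, 6, "serial_replacement", 0, seed = 3)
  tr <- strain_truth(g, a, depth = 50, seed = 3)
  pu <- simulate_allele_counts(tr, seed = 9)
  p <- expected_frequencies(tr)
  obs <- pu$alt_counts / pmax(pu$total_counts, 1)
  se <- sqrt(p * (1 - p) / pmax(pu$total_counts, 1))
  inside <- abs(obs - p) <= 3 * se + 1e-12
  # law of large numbers: ~99.7% of entries within 3 SE
  expect_gte(mean(inside), 0.98)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a1 <- simulate_abundance_trajectories(3, 8, "serial_replacement", 0.02, seed = 11)
  a2 <- simulate_abundance_trajectories(3, 8, "serial_replacement", 0.02, seed = 11)
  expect_identical(a1, a2)
  s1 <- simulate_study(seed = 13, n_sites = 20, n_genes = 2, gene_length = 300)
  s2 <- simulate_study(seed = 13, n_sites = 20, n_genes = 2, gene_length = 300)
  expect_identical(s1$pileup$alt_counts, s2$pileup$alt_counts)
  expect_identical(as.character(s1$genome$contigs), as.character(s2$genome$contigs))
})

test_that("synthetic genes are stop-free, in-frame, on both strands", {
  g <- simulate_coding_genes(10, 999, 0.6, seed = 21)
  expect_equal(nrow(g$genes), 10)
  expect_true(all((g$genes$end - g$genes$start + 1) %% 3 == 0))
  expect_setequal(unique(g$genes$strand), c("+", "-"))
  code <- Biostrings::getGeneticCode("11")
  for (gid in g$genes$gene_id) {
    cds <- coding_sequence(g, gid)
    aas <- Biostrings::translate(Biostrings::DNAString(cds),
                                 genetic.code = code)
    expect_false(grepl("\\*", as.character(aas)), info = gid)
  }
  # observed GC close to target
  gc <- Biostrings::letterFrequency(g$contigs, "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.6), 0.05)
  expect_error(simulate_coding_genes(2, 100, 0.5, seed = 1), "multiple of 3")
  # a two-gene genome has one gene per strand, both stop-free
  g2 <- simulate_coding_genes(2, 30, 0.5, seed = 2)
  expect_setequal(g2$genes$strand, c("+", "-"))
})

test_that("injected variants hit the target nonsynonymous fraction", {
  g <- simulate_coding_genes(4, 300, 0.5, seed = 8)
  v0 <- inject_variants(g, 30, 0, seed = 1)
  expect_true(all(v0$effect == "synonymous"))
  v1 <- inject_variants(g, 30, 1, seed = 1)
  expect_true(all(v1$effect == "nonsynonymous"))
  v5 <- inject_variants(g, 100, 0.5, seed = 1)
  expect_lte(abs(sum(v5$effect == "nonsynonymous") - 50), 1)
  expect_false(any(duplicated(paste(v5$contig, v5$position))))
})

test_that("round-trip: independent annotation reproduces injected effects", {
  g <- simulate_coding_genes(6, 300, 0.5, seed = 31)
  v <- inject_variants(g, 100, 0.5, seed = 31)
  # build a pileup at the injected sites with every variant clearly visible
  n <- nrow(v)
  pu <- strainsweep:::new_pileup(
    matrix(50L, n, 2), matrix(100L, n, 2),
    data.frame(contig = v$contig, position = v$position,
               ref_base = v$ref_base, alt_base = v$alt_base,
               stringsAsFactors = FALSE))
  ann <- annotate_effect(call_snvs(pu, 1, 0.01), g)
  rec <- ann$records[match(paste(v$contig, v$position),
                           paste(ann$records$contig, ann$records$position)), ]
  expect_equal(rec$effect, v$effect)
  expect_equal(rec$aa_ref, v$aa_ref)
  expect_equal(rec$aa_alt, v$aa_alt)
  expect_equal(rec$codon_position, v$codon_position)
})
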