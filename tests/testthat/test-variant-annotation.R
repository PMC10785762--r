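test_that("SNV calling applies depth and frequency thresholds per contract", {
  # site 1: 10/100 -> called with frequency 0.10
  # site 2: depth 4 everywhere -> not called (below depth)
  # site 3: 2/100 = 0.02 -> not called (below frequency)
  alt <- rbind(c(10L, 12L), c(1L, 1L), c(2L, 2L))
  tot <- rbind(c(100L, 100L), c(4L, 4L), c(100L, 100L))
  pu <- make_pileup(alt, tot, positions = c(5L, 9L, 14L))
  snv <- call_snvs(pu, min_depth = 5, min_freq = 0.05)
  expect_equal(snv$sites$position, 5L)
  expect_equal(unname(snv$freq[1, 1]), 0.10)
})

test_that("frequencies below the depth threshold are missing, never zero", {
  alt <- rbind(c(10L, 0L))
  tot <- rbind(c(100L, 3L))
  pu <- make_pileup(alt, tot)
  snv <- call_snvs(pu, min_depth = 5, min_freq = 0.05)
  expect_true(is.na(snv$freq[1, 2]))
  expect_equal(unname(snv$freq[1, 1]), 0.10)
})

test_that("malformed counts raise a data error naming the site", {
  alt <- rbind(c(10L, 5L))
  tot <- rbind(c(4L, 5L))
  expect_error(call_snvs(make_pileup(alt, tot, positions = 42L), 1, 0.01),
               "ctg1:42")
})

test_that("multi-allelic sites are reduced to the dominant alternate allele", {
  alt <- rbind(c(30L, 30L), c(5L, 5L))
  tot <- rbind(c(100L, 100L), c(100L, 100L))
  coords <- data.frame(contig = "ctg1", position = c(7L, 7L),
                       ref_base = "A", alt_base = c("G", "T"),
                       stringsAsFactors = FALSE)
  pu <- list(alt_counts = alt, total_counts = tot, site_coords = coords)
  expect_message(snv <- call_snvs(pu, 5, 0.01), "multi-allelic")
  expect_equal(nrow(snv$sites), 1)
  expect_equal(snv$sites$alt_base, "G")
})

test_that("effect annotation translates codons honoring the genetic code", {
  g <- tiny_genome()
  # gene_plus codon 2 is GGA (Gly) at ctg1:10-12
  alt <- matrix(c(50L, 50L), 2, 1)
  tot <- matrix(c(100L, 100L), 2, 1)
  pu <- make_pileup(alt, tot, positions = c(12L, 10L),
                    ref = c("A", "G"), alt_base = c("G", "A"))
  ann <- annotate_effect(call_snvs(pu, 1, 0.01), g)
  rec <- ann$records[order(ann$records$position), ]
  # GGA -> AGA at codon position 1: Gly -> Arg, nonsynonymous
  expect_equal(rec$effect[1], "nonsynonymous")
  expect_equal(rec$aa_ref[1], "G")
  expect_equal(rec$aa_alt[1], "R")
  expect_equal(rec$codon_position[1], 1L)
  expect_equal(rec$grantham[1], grantham_distance("G", "R"))
  # GGA -> GGG at codon position 3: Gly -> Gly, synonymous
  expect_equal(rec$effect[2], "synonymous")
  expect_true(is.na(rec$grantham[2]))
})

test_that("minus-strand codons are reconstructed by reverse complement", {
  g <- tiny_genome()
  # gene_minus codes ATG CCA GAA; genomic 19..27 = TTCTGGCAT (revcomp)
  # position 19 is the 3rd base of the GAA codon: genomic T>C reads as
  # coding A>G, GAA->GAG, Glu->Glu: synonymous
  # position 21 is the 1st base of GAA: genomic C>T reads as coding G>A,
  # GAA->AAA, Glu->Lys: nonsynonymous
  alt <- matrix(50L, 2, 1)
  tot <- matrix(100L, 2, 1)
  pu <- make_pileup(alt, tot, positions = c(19L, 21L),
                    ref = c("T", "C"), alt_base = c("C", "T"))
  ann <- annotate_effect(call_snvs(pu, 1, 0.01), g)
  rec <- ann$records[order(ann$records$position), ]
  expect_equal(rec$effect[1], "synonymous")
  expect_equal(rec$codon_position[1], 3L)
  expect_equal(rec$effect[2], "nonsynonymous")
  expect_equal(rec$aa_ref[2], "E")
  expect_equal(rec$aa_alt[2], "K")
})

test_that("sites outside genes are intergenic; nonsense has no Grantham", {
  g <- tiny_genome()
  # position 2 is intergenic spacer (C); gene_plus codon 3 AAA at 13..15:
  # A>T at 13 gives TAA = stop (nonsense)
  alt <- matrix(50L, 2, 1)
  tot <- matrix(100L, 2, 1)
  pu <- make_pileup(alt, tot, positions = c(2L, 13L),
                    ref = c("C", "A"), alt_base = c("G", "T"))
  ann <- annotate_effect(call_snvs(pu, 1, 0.01), g)
  rec <- ann$records[order(ann$records$position), ]
  expect_equal(rec$effect[1], "intergenic")
  expect_equal(rec$effect[2], "nonsense")
  expect_true(is.na(rec$grantham[2]))
})

test_that("gene models with broken reading frames are rejected by name", {
  g <- tiny_genome()
  g$genes$end[1] <- g$genes$end[1] + 1L
  pu <- make_pileup(matrix(5L, 1, 1), matrix(10L, 1, 1), positions = 10L,
                    ref = "G", alt_base = "A")
  expect_error(annotate_effect(call_snvs(pu, 1, 0.01), g), "gene_plus")
})

test_that("frequency matrix preserves order, mask and degenerate inputs", {
  alt <- rbind(c(10L, 50L, 90L), c(10L, 0L, 10L))
  tot <- rbind(c(100L, 100L, 100L), c(100L, 3L, 100L))
  pu <- make_pileup(alt, tot)
  snv <- call_snvs(pu, 5, 0.05)
  f <- frequency_matrix(snv)
  expect_equal(unname(f[1, ]), c(0.1, 0.5, 0.9))
  expect_true(is.na(f[2, 2])) # masked, not zero
  expect_equal(rownames(f), c("ctg1:1:A>G", "ctg1:2:A>G"))
  # empty call set: 0-row matrix, no error
  none <- call_snvs(make_pileup(matrix(0L, 1, 2), matrix(100L, 1, 2)), 5, 0.05)
  expect_equal(nrow(frequency_matrix(none)), 0)
})

test_that("permissive calling recovers exactly the injected polymorphic sites", {
  st <- simulate_study(seed = 17, n_sites = 60, mean_depth = 100,
                       n_timepoints = 6)
  p <- expected_frequencies(st$truth)
  polymorphic <- apply(p, 1, function(r) any(r > 0.02))
  snv <- call_snvs(st$pileup, min_depth = 1, min_freq = 0.005)
  called <- paste(snv$sites$contig, snv$sites$position)
  truth_keys <- paste(st$pileup$site_coords$contig,
                      st$pileup$site_coords$position)
  # no false negatives among truly polymorphic sites
  expect_true(all(truth_keys[polymorphic] %in% called))
  # no false positives: every called site carries alternate alleles in truth
  has_alt <- apply(p, 1, max) > 0
  expect_true(all(called %in% truth_keys[has_alt]))
})
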