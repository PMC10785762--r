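# strainsweep

Strain-resolved analysis of longitudinal shotgun metagenomes.

Microbial communities under slowly increasing environmental pressure — the
motivating system is anaerobic digestion adapting to extreme ammonia
(20 g NH4+-N/L) — often evolve *within* species: a fitter strain sweeps
through a population, dragging its private alleles from low to high
frequency across the time series. `strainsweep` implements the analysis
layer for detecting and quantifying this:

* **SNV calling** from per-site allele-count pileups (TSV or VCF subset),
  with depth/frequency thresholds and missing-not-zero frequency masks;
* **effect annotation** against gene models (GFF3 + FASTA), strand-aware
  codon reconstruction, synonymous/nonsynonymous/nonsense classification,
  and **Grantham (1974) distance** with the `>70` medium–high impact rule;
* **trajectory clustering** of SNV frequencies (average-linkage,
  correlation distance) to find groups of variants moving together;
* **strain deconvolution**: factorization of the frequency matrix
  `F ≈ G·A` into binary genotypes `G` (sites × strains) and simplex
  abundance trajectories `A` (strains × timepoints), by alternating exact
  simplex-constrained least squares with an exhaustive binary genotype
  step, multi-restart, with BIC-style selection of the strain count and
  MAG-relative-abundance re-weighting;
* **selection statistics**: per-gene pN/pS with Nei–Gojobori (1986) site
  counting, strict `>1` flagging, and a Mann–Whitney rank-sum test (exact,
  tie-aware) for nsSNV enrichment in pathway gene sets;
* **community & chemistry metrics**: relative abundance from coverage, RA
  filters ("≥X% in at least one sample"), Shannon and bias-corrected Chao1
  diversity, gene-set pathway completeness, and free ammonia nitrogen
  `FAN = TAN / (1 + 10^(pKa(T) − pH))` with `pKa(T) = 0.09018 + 2729.92/T`;
* a **synthetic-data generator** producing ground-truthed strain
  communities (known genotypes, logistic replacement sweeps, Poisson
  depth, binomial allele sampling, coding genes with injected variants of
  known effect) so that every stage is validated against known answers.

## Worked example

```r
library(strainsweep)

# a ground-truthed community: 3 strains, 8 timepoints, serial replacement,
# 100 variant sites at 50x depth
st <- simulate_study(seed = 1)

# call and annotate SNVs
snv <- annotate_effect(call_snvs(st$pileup, min_depth = 5, min_freq = 0.05), st$genome)
print(snv)
#> snv_records: 92 SNVs (nonsynonymous=44, synonymous=48)

# cluster frequency trajectories and deconvolve strains
f  <- frequency_matrix(snv)
cl <- cluster_trajectories(f)
print(cl)
#> trajectory_clustering: 4 clusters, 92 SNVs (14 unassigned)

full <- call_snvs(st$pileup, 1, 0.01)
fit  <- select_strain_number(frequency_matrix(full), weights = full$total,
                             s_max = 5, seed = 1)
print(fit)
#> strain_model: 3 strains, 92 sites x 8 timepoints, RSS 61.79 (BIC 137.2)

# compare against the simulated truth after optimal strain matching
keep <- match(paste(full$sites$contig, full$sites$position),
              paste(st$pileup$site_coords$contig, st$pileup$site_coords$position))
truth <- strain_truth(st$truth$genotypes[keep, ], st$truth$abundances, seed = 1)
match_strains(fit, truth)[c("genotype_accuracy", "abundance_rmse")]
#> $genotype_accuracy
#> [1] 1
#> $abundance_rmse
#> [1] 0.007324638
```

The fitted model recovers every genotype entry and tracks the strain
abundance sweeps to within ~0.7% despite binomial sampling noise at 50×.
(RSS is depth-weighted; printed values come from the code above.)

Free ammonia from digester chemistry:

```r
compute_fan(tan = 20000, ph = 6.8, temperature_k = 315.15)
#> [1] 220.6702
```

## Documentation

The methods vignette (`vignettes/strain-resolved-metagenomics.Rmd`)
describes the mixture model and optimization, the statistical conventions
(NG86 site counting, exact rank-sum null, missing-data semantics), what
the synthetic generator does and does not emulate, and known limitations.
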