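---
title: "Strain-resolved longitudinal metagenomics with strainsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved longitudinal metagenomics with strainsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsweep)
```

## The scientific problem

When a microbial community is pushed along an environmental gradient — the
motivating case is an anaerobic digester slowly adapted to extreme ammonia
levels — the species list often changes less than the *strains* inside each
species. Shotgun metagenomes sequenced along the time course record this as
shifting allele frequencies at single-nucleotide variant (SNV) sites: a
fitter strain sweeping through a population drags all of its private
alleles from low to high frequency together. `strainsweep` provides the
analysis layer for this situation: it calls SNVs from per-site allele
counts, annotates their coding consequences, clusters their frequency
trajectories, deconvolves the pooled frequencies into discrete strains with
abundance trajectories, and scores genes and pathways for selection.

Because real read sets are large and their ground truth unknowable, the
package also ships a first-class synthetic-data generator that produces
communities with *known* strain genotypes, abundance sweeps and selection
regimes. Every quantitative guarantee the package makes is demonstrated
against that ground truth in the test suite.

## The strain mixture model

Let `G` be a binary sites-by-strains genotype matrix (1 = strain carries
the alternate allele) and `A` a strains-by-timepoints abundance matrix
whose columns lie on the probability simplex. Pooled sequencing then
observes, at site v and timepoint t, alternate reads distributed
binomially with success probability

    F[v, t] = (G A)[v, t],

the abundance-weighted fraction of strains carrying the allele. The
deconvolution task inverts this: given noisy `F` (and read depths), recover
`G` and `A`.

`deconvolve_strains()` minimizes the depth-weighted squared error
`sum(W * (F - G A)^2)` by alternating two exact conditional steps:

* **A-step** — for each timepoint, a simplex-constrained least-squares
  problem, solved exactly by enumerating the `2^S - 1` possible support
  sets and solving each equality-constrained system (S is small, so this
  beats iterative QP both in speed and in determinism);
* **G-step** — for each site, the best binary row among all `2^S`
  candidates, computed for all sites at once by matrix algebra. Ties are
  broken toward the previous iterate (stability across iterations), then
  lexicographically (determinism across runs).

Each alternation weakly decreases the objective, so the iteration
converges; because the problem is combinatorial, the fit restarts from 20
initializations by default (the first seeded from trajectory-cluster mean
profiles when available, the rest from random simplex draws), each restart
seeded deterministically from the top-level seed. Missing frequencies
(below-depth timepoints) enter with weight zero. Strain counts above 10
are refused outright rather than silently attempted — the G-step is
exponential in S — with the advice to split the site set hierarchically.

This is deliberately an *allele-frequency factorization*, in the spirit of
assembly-graph strain deconvolvers but not a re-implementation of one: no
read linkage, unitig graph or co-assembly information is used, and no
claim is made to reproduce any specific tool's output on real reads.

**Choosing the number of strains.** `select_strain_number()` fits
S = 1..s_max and minimizes a BIC-style score: the Gaussian
pseudo-log-likelihood of the weighted residual plus `log(n)` times the
parameter count `V * S_distinct + S * (T - 1)` (duplicate genotype columns
do not add parameters, which stops the score from rewarding cosmetic extra
strains). The full score path is returned so the selection is auditable
rather than oracular.

**Label exchangeability.** Any permutation of strain labels leaves the
residual unchanged, so comparisons against ground truth go through
`match_strains()`, which finds the label permutation minimizing abundance
RMSE by enumeration (S is small) before scoring genotype accuracy.

## SNV calling and effect annotation

`call_snvs()` is a caller-independent representation of the usual
pileup-thresholding contract: a site is an SNV if at one or more
timepoints depth reaches `min_depth` (default 5) and alternate frequency
reaches `min_freq` (default 0.05). Both defaults are explicit arguments
because published workflows rarely print them. Two conventions matter
downstream:

* frequencies at below-depth timepoints are **missing, never zero** —
  treating non-observation as absence would fabricate "crashes" in
  trajectories and corrupt clustering;
* multi-allelic sites are reduced to the highest-count alternate allele
  (biallelic treatment), with a message naming the discarded alleles.

`annotate_effect()` reconstructs the codon spanning each SNV, honoring
strand (reverse-complement on `-`) and the configured genetic code
(bacterial/archaeal table 11 by default), and classifies the change as
synonymous, nonsynonymous, nonsense or intergenic. Nonsynonymous changes
receive a Grantham (1974) distance; nonsense changes do not — the stop
codon has no physicochemical property vector — and are tallied separately.

The Grantham engine computes distances from the published composition,
polarity and volume properties with mean-100 scaling, then snaps to the
reference integer matrix; a load-time self-check fails if formula and
reference disagree by more than one unit anywhere. One cell deserves a
note: the Trp–Asp entry is stored as 191, the value the formula yields
from the published property table, where the original print shows 181 —
inconsistent with its own formula by ten units and treated here as a
typographical error. Substitutions with distance strictly above 70 are
classified `medium_high` impact; 70 itself is conservative.

## Trajectory clustering

`cluster_trajectories()` uses average-linkage hierarchical clustering on
`1 - Pearson correlation` between SNV trajectories (pairwise-complete over
observed timepoints), cut at a fixed height (default 0.25). Correlation
distance groups variants by the *shape* of their trajectory regardless of
level, which is what strain-hitchhiking predicts; Euclidean distance is
available when absolute frequencies matter. The cut height and linkage
are explicit parameters because the upstream literature describes this
step only loosely. Three degenerate cases are routed to an unassigned
group rather than forced into clusters: trajectories with fewer than two
observed timepoints, zero-variance (fixed) trajectories whose correlation
is undefined, and members of clusters smaller than `min_cluster_size`.
Cluster mean profiles average members' non-missing entries per timepoint.

## Selection statistics

`count_ng86_sites()` implements Nei–Gojobori (1986) site counting: each
coding position contributes fractionally to nonsynonymous and synonymous
"sites" according to the fraction of its possible single-base changes that
alter the amino acid, so each position contributes exactly one site and
`n_sites + s_sites` equals the gene length. Mutations *to* stop codons are
excluded from the enumeration by default (available behind
`include_stop_mutations`); observed nonsense variants are likewise kept
out of the ratio.

The per-gene statistic is a within-population **pN/pS** — the variants are
polymorphisms segregating in one population, not fixed substitutions
between species — even though field usage often writes dN/dS:

    pN/pS = (n_obs / n_sites) / (s_obs / s_sites).

With no synonymous observations the ratio is *undefined*, flagged rather
than reported as infinity; an optional +0.5 continuity correction is
available. `flag_selected()` marks genes with a defined ratio strictly
above 1.

**Pathway enrichment.** `pathway_enrichment()` asks whether pathway genes
carry a higher nonsynonymous burden than the rest of the genome's genes
(one-sided upper tail; the background excludes the pathway set so the
groups are disjoint). The burden is nsSNV count per kilobase of coding
sequence by default — length normalization is an explicit choice, with raw
counts available — and the test is the Mann–Whitney rank sum. The p-value
comes from the exact tie-aware permutation null, computed by a dynamic
program over doubled midranks, whenever `set_size * background_size` is
within the enumeration budget (1e6); beyond that, the tie-corrected normal
approximation with continuity correction. Raw p-values are reported by
default, with Benjamini–Hochberg adjustment available, since small numbers
of directed hypotheses are the common use.

## Community metrics and ammonia chemistry

Relative abundance is column-normalized mean coverage. The RA filter
("X% or higher in at least one sample", `>=` comparison) reproduces the
usual prioritization of well-covered genomes; the 1% filter provably keeps
a superset of the 3% filter. Shannon diversity is `-sum(p log p)` in nats
(base configurable); Chao1 uses the bias-corrected estimator
`S_obs + F1(F1-1) / (2(F2+1))` and, because it needs counts, fractional
abundances are first scaled to a pseudo-count depth (default 1000) and
floored — a declared convention, not a claim about how any particular
study computed it. Pathway completeness is the fraction of a module's
required genes present.

Free ammonia nitrogen follows the NH4+/NH3 equilibrium,
`FAN = TAN / (1 + 10^(pKa(T) - pH))` with the Emerson-type
parameterization `pKa(T) = 0.09018 + 2729.92 / T`; both constants are
arguments so an alternative parameterization can be swapped without code
changes. Useful identities — FAN = TAN/2 exactly at pH = pKa, FAN bounded
by TAN, monotone in pH and temperature, FAN/TAN independent of TAN — are
asserted in the test suite.

## What the synthetic generator emulates, and what it does not

`simulate_study()` builds: stop-free coding genes on both strands at a
target GC content; injected variants with exact known effects (the
annotation module must reproduce them 100%, which the tests enforce);
binary strain genotypes with a minimum pairwise Hamming separation;
abundance trajectories as logistic replacement cascades (`stable`,
`single_sweep`, `serial_replacement`) mimicking successive strain
takeovers; and pileups with Poisson depth (negative binomial behind a
dispersion flag) and binomial allele sampling, plus an optional symmetric
error rate. Defaults — 3 strains, 8 timepoints, 100 sites, depth 50,
serial replacement — are the regime the downstream guarantees are stated
for: strain turnover across a medium-length time series at moderate
coverage.

The generator deliberately does *not* simulate reads (no FASTQ, mapping
or mapping bias), recombination, gene gain/loss between strains, or
within-strain microdiversity. Passing tests therefore demonstrate
correctness of the algorithms under the stated sampling model, not
robustness to alignment artifacts or reference bias in real data. The
error-rate knob exists because real pileups contain sequencing error, but
no literature value is matched.

Coordinates are 1-based inclusive in all serialized files (GFF3
convention); all internal arithmetic converts at the boundary. One
top-level seed drives everything; substreams are derived deterministically
(`derive_seed()`), so whole analyses are bit-reproducible.

## Numerical choices and degenerate inputs

* Simplex least squares adds a 1e-10 ridge before each small solve;
  supports whose solution goes negative are discarded (exact active-set
  logic), and the uniform simplex point is the fallback for pathological
  all-zero-weight columns.
* Alternation stops when the genotype matrix is stable and the residual
  improvement falls below 1e-10, or at 100 iterations.
* The model-selection likelihood floors the residual at 1e-12 so exact
  fits do not produce `-Inf`; at equal (zero) residual the penalty then
  selects the smaller strain count.
* Zero-variance trajectories, all-missing matrices, empty SNV sets and
  empty clusters all return well-defined empty results or unassigned
  routings with warnings — never errors — because they occur routinely on
  small or heavily filtered datasets.

## Problem sizes in the shipped validation

The test suite and the acceptance script exercise: parameter recovery at
100 sites x 3 strains x 8 timepoints x depth 50 over 20 seeds (genotype
accuracy, abundance RMSE, strain-count selection rate); global-optimum
agreement against exhaustive enumeration on 100 noiseless instances with
up to 6 sites and 2 strains; pN/pS neutrality over 50 seeds of 200
injected variants; enrichment type-I error over 1000 null simulations;
and a depth curve (10-100x) over 20 seeds. These sizes were chosen as the
smallest at which the estimates of interest are stable, keeping the whole
validation comfortably desk-scale.

## Known limitations

* The deconvolution has no read-linkage information, so strains that are
  nearly collinear in abundance over the sampled timepoints are only
  weakly identifiable; the score path makes such cases visible.
* pN/pS on polymorphism data is conservative with respect to classic
  divergence dN/dS, and undefined for genes without synonymous variants;
  a codon-model likelihood method is out of scope.
* Chao1 on pseudo-counts inherits the arbitrariness of the chosen depth;
  it is reported for trend comparison, not absolute richness.
* The pipeline treats each reactor/site series independently; no joint
  multi-series model is attempted.
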