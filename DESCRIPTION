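Package: strainsweep
Title: Strain-Resolved Longitudinal Metagenomics of Adapting Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking strain-level evolution in longitudinal shotgun
    metagenomes of microbial communities under environmental pressure (for
    example anaerobic digesters adapting to ammonia stress). Calls single
    nucleotide variants from per-site allele counts, annotates coding effects
    and Grantham physicochemical impact, clusters SNV frequency trajectories,
    deconvolves pooled allele frequencies into binary strain genotypes with
    simplex abundance trajectories, computes per-gene pN/pS selection
    statistics with Nei-Gojobori (1986) site counting, tests pathway gene
    sets for nonsynonymous-variant enrichment with a rank-sum test, and
    provides community metrics (relative abundance, Shannon and Chao1
    diversity, pathway completeness) and free-ammonia-nitrogen chemistry.
    A ground-truthed synthetic-data generator emulates multi-strain species
    with replacement sweeps so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
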