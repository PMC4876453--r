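Package: clonekin
Title: Clonal Growth Kinetics from Serial Tumour Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal subclonal reconstruction and growth-kinetic analysis
    for leukaemias sampled serially in peripheral blood. Converts somatic
    mutation read counts to cancer cell fraction (CCF) posteriors given sample
    purity and local copy number, clusters mutations across serial samples
    into subclones, infers the rooted clone phylogeny under lineage
    (pigeonhole) constraints, converts clone fractions to absolute circulating
    cell counts using absolute lymphocyte counts, fits per-clone constant-rate
    exponential growth or decline with posterior-propagated confidence
    intervals, and back-extrapolates resistant-clone sizes to treatment
    initiation. Also implements the quantification statistics of droplet
    digital rare-cell assays (Poisson loading, standard curves, exact binomial
    frequency intervals) and allele-specific single-cell genotype calling, and
    ships a fully specified synthetic-cohort simulator so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
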