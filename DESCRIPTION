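Package: edgefront
Title: Range-Expansion Population Genomics for Invasion SNP Data
Version: 0.1.0
Authors@R: person("edgefront", "maintainers", email = "edgefront@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing range expansions from biallelic SNP data:
    locus-retention filters in the style of the Stacks populations program,
    per-locus and per-population diversity statistics (heterozygosities, pi,
    F_IS, rarefied allelic richness, private alleles), Weir-Cockerham F_ST
    with permutation tests, PCA with iterative outlier removal, constrained
    least-cost ocean distances, diversity-versus-distance regressions, the
    directionality index (psi) for expansion-origin inference, bespoke locus
    classifiers (flip-flop and min-max frequency filters), F_ST-outlier and
    environmental-correlation outlier scans, and a forward-time serial
    founder-event simulator for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    VariantAnnotation,
    BiocGenerics,
    SummarizedExperiment,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
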