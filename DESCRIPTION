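Package: panelsmith
Title: Design and Evaluation of Targeted Liquid-Chip SNP Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for designing targeted-capture ("liquid chip") SNP panels
    from population variant data and for evaluating the resulting assays.
    Covers per-site quality statistics and inclusion filtering; probe-flank
    GC and genome-wide homology-specificity screening; uniformly spaced
    panel selection with characterization metrics; population-genetic
    evaluation (windowed nucleotide diversity, Weir-Cockerham Fst, Tajima's
    D); distillation of a compact fingerprint locus set with QR-style
    genotype profiles and method-of-moments identity-by-descent kinship and
    clone detection; F1 recombination bin maps and segregation-distortion
    scans; and seeded simulators for genomes, structured populations and
    biparental crosses so every step is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
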