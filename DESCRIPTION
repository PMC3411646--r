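Package: plastdiverge
Title: Comparative Divergence Analysis of Plastid Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of complete chloroplast
    (plastid) genomes in closely related plant groups. Provides pairwise
    substitution and indel accounting on whole-genome alignments,
    staged outgroup-based polarization of indels with assignment to
    branches of a fixed species tree, perfect-microsatellite (cpSSR)
    detection and polymorphism analysis, region-wise (LSC/SSC/IR)
    divergence rates, Nei-Gojobori Ka/Ks estimation with clock-based
    divergence dating, and Tajima's relative rate test. Includes a
    quadripartite plastome evolution simulator with a complete
    ground-truth event log for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
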