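Package: foulscan
Title: Marine Biofouling Metabarcoding and Panel-Monitoring Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for port biofouling surveys that combine DNA metabarcoding
    with image-based panel monitoring. Implements read quality filtering and
    greedy 97% OTU clustering, a rule-based adjudication cascade for tabular
    homology (BLAST outfmt 6) hits, translation-validated screening of COI
    assignments against non-indigenous-species checklists, community
    statistics (alpha diversity, rarefaction, Bray-Curtis with a dummy
    pseudo-taxon, PERMANOVA and multivariate dispersion homogeneity, both
    written from first principles), and quantification of percent fouling
    cover and biomass per panel area from photograph stacks. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
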