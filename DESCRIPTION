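Package: hoxphys
Title: Biophysical Force Model of Hox Gene Cluster Collinearity
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models Hox gene cluster collinearity as the outcome of a physical
    pulling force F = P * N that extrudes the chromatin fiber from the
    chromosome territory into the interchromosome domain, activating genes in
    chromosomal order. Provides S4 containers for Hox clusters described by
    ordered gene lists and intergenic distances (Kbp), descriptive distance
    statistics for compact (vertebrate) versus loose (invertebrate) clusters,
    a Monte-Carlo experiment perturbing factors of phenotypic realization with
    Gaussian white noise to compare how cluster geometry buffers developmental
    noise, a morphogen-gradient/elastic-spring expression simulator with
    spatial, temporal and quantitative collinearity checks, and a qualitative
    classifier predicting mutant expression outcomes of cluster deletions,
    duplications and splittings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, rtracklayer, GenomicRanges, IRanges, S4Vectors
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SystemsBiology, GeneExpression, Transcription
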