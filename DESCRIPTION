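Package: epiland
Title: Environment-Dependent Epistasis on Empirical Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing combinatorially complete fitness landscapes
    (all 2^L combinations of L mutations) measured in multiple external
    environments. Implements epistasis decomposition against a multiplicative
    null model with propagated measurement error and t-tests, net higher-order
    epistasis by inclusion-exclusion over mutation subsets, diminishing-returns
    regression (Pearson correlation and standard major axis fits),
    focal-mutation stratified analyses, enumeration and classification of
    selectively accessible mutational paths on the genotype hypercube,
    full-factorial genotype-by-environment ANOVA with variance partitioning
    into G, GxG, E, GxE and GxGxE components, and the underlying assay
    computations: serial-transfer competition fitness, growth-curve area under
    the curve, and phenotype-microarray differential-respiration calls. A
    synthetic-data generator with known ground truth supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
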