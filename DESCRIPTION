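Package: gd2sig
Title: GD2 Phenotype Prediction from Ganglioside-Synthesis Gene Expression
Version: 0.1.0
Authors@R:
    person("Maintainer", "Unknown", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to predict the GD2-positive cancer phenotype from bulk
    RNA-seq read counts. Implements median-of-ratios count normalization,
    additive log10 gene-signature scoring over the six-gene ganglioside
    biosynthesis panel (flagship signature ST8SIA1 + B4GALNT1),
    equal-error-rate thresholding with Matthews Correlation Coefficient
    evaluation, permutation and random-gene-pair null distributions,
    relative-fluorescence-intensity (RFI) phenotyping of cell lines, a
    negative-binomial cohort simulator, and an end-to-end reporting
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
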