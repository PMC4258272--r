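Package: ccatx
Title: Canonical Correspondence Analysis of Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained ordination of gene-by-sample expression matrices in
    the chi-square metric. Projects a standardized expression matrix onto
    differentiation-programme explanatory profiles, decomposes the
    constrained space by singular value decomposition, and reports gene,
    sample and biplot scores together with an inertia decomposition.
    Includes one-dimensional differentiation-variable scoring for
    classifying undefined samples against reference differentiation
    programmes, deterministic two-group partitioning of sample scores,
    jackknife confidence intervals for sensitivity and accuracy,
    cross-platform rank normalization, a synthetic transcriptome generator
    with class-specific marker genes, and triplot/score visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    grid,
    ggplot2,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
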