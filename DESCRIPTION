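Package: pdfftexture
Title: Texture Analysis of Proton Density Fat Fraction Maps in Muscle
Version: 0.1.0
Authors@R: person("Paraspinal", "Imaging Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: ROI-based texture analysis of quantitative proton density fat
    fraction (PDFF) maps of paraspinal musculature. Computes mean PDFF,
    global intensity-histogram features (variance, skewness, kurtosis with
    a median-of-Sturges/Scott/Freedman-Diaconis bin rule), and
    second-order features from a 13-direction three-dimensional gray-level
    co-occurrence matrix with discretization-length correction, aggregated
    bilaterally by muscle volume. Includes a synthetic PDFF-phantom cohort
    generator with programmed sex, age and BMI effects, rank-based group
    statistics (Wilcoxon-Mann-Whitney, Wilcoxon signed-rank) and
    age/BMI-adjusted partial correlations, plus a reproducible
    simulate/extract/stats pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
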