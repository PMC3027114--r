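Package: jointGWAS
Title: Robust Joint Analysis for Two-Stage Case-Control Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis of two-stage case-control genome-wide
    association studies with joint statistics that combine both stages.
    Implements the allele-frequency-difference test, Cochran-Armitage
    trend tests under recessive, additive and dominant scores, the
    maximin efficiency robust test (MERT) and MAX3, together with exact
    bivariate-normal threshold equations, Monte-Carlo critical values for
    the MAX3 joint analysis, analytic and empirical power, family-wise
    error simulation, and an analysis path for per-SNP genotype count
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
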