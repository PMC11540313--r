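Package: xwaymsv
Title: Analytical Prediction of Genetic Variance and Mendelian Sampling
    Variance in Multiparent Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the additive genetic variance among double-haploid
    (DH) lines and intermediate F1 generations descending from an
    arbitrary power-of-two number of phased founder haplotypes, from
    phased genotypes, a genetic map and additive allele-substitution
    effects. The DH variance is decomposed into per-generation gametic
    Mendelian sampling variances (MSVs) along a balanced MAGIC-style
    crossing plan, with infinitesimal-model (coancestry-based)
    counterparts, a multi-generation selection criterion
    (ExpBVSelGrGrGrOff), and a forward Monte-Carlo crossing-plan
    simulator used to validate the analytical predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
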