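Package: vwmprecision
Title: Precision Analysis of Continuous-Report Visual Working Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing delayed-reproduction (continuous-report)
    visual working memory experiments on circular feature spaces. Implements
    chance-corrected precision based on Fisher's circular standard deviation,
    sensorimotor correction by subtraction of error variances, the
    three-component von Mises mixture model of response error (target,
    non-target/misbinding, uniform guessing) fitted by maximum-likelihood
    expectation-maximization, a synthetic cohort generator emulating an
    age-structured developmental study design, and a staged statistical
    pipeline (outlier handling, age regressions, partial correlations,
    serial-position ANOVA with Greenhouse-Geisser correction, response
    histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
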