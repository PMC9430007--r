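Package: rwerepro
Title: Concordance Metrics for Reproductions of Real-World Evidence Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for meta-research on the reproducibility of database
    studies (real-world evidence). Computes per-study concordance between an
    original published result and an independent reproduction (relative
    magnitude of effect, absolute log-difference, closer-to-null and
    side-of-null agreement, confidence-interval overlap, significance
    discordance), portfolio-level agreement statistics (unweighted and
    inverse-variance-weighted Pearson and Spearman correlation, one-way
    intraclass correlation with confidence interval, Bland-Altman limits of
    agreement, outlier ranking), cohort-construction concordance (sample-size
    ratios, baseline-covariate prevalence differences, outcome risk and rate
    differences), and scoring of a 54-item reporting-clarity checklist. A
    synthetic generator produces paired original/reproduction study
    portfolios with known truth so the whole pipeline is testable without
    restricted healthcare data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
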