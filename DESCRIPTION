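Package: killicog
Title: Pose-Track Analysis of Associative Learning, Lifespan and Diet in the
    African Turquoise Killifish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and quantification tools for automated-feeder
    experiments in the African turquoise killifish (Nothobranchius furzeri).
    Reads DeepLabCut-style keypoint tracks, applies likelihood gating,
    pooled jump-anomaly removal and natural cubic-spline interpolation,
    derives upward-velocity kinematics and compass statistics, and extracts
    the latency of the first surface-bound trajectory (t1) together with
    trial success calls and a per-fish learning index. Companion modules
    cover feeder fidelity and bootstrap precision, nonparametric tests and
    Wilcoxon-Mann-Whitney a-priori sample sizes, Kaplan-Meier and censored
    Gompertz survival fits ("rate of aging"), and an expression-matched
    bootstrap enrichment test for differentially expressed genes. A
    synthetic-data module generates every input with ground truth so the
    whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    flexsurv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
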