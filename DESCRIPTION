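Package: metarelapse
Title: Branching-Process Models of Metastasis Seeding and Cancer Recurrence Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for a stochastic model of cancer
    recurrence in which a deterministically growing primary tumor seeds
    metastases as a non-homogeneous Poisson process, each metastasis evolving
    as a supercritical birth-death branching process. Provides closed-form and
    semi-analytic relapse-time distributions (including Gumbel extreme-value
    limits and defective cure-model variants after primary resection),
    estimation of model parameters from clinical tumor doubling times,
    classification of synchronous versus metachronous metastases, high-risk
    resection windows, surgery-delay risk, and an exact/hybrid Gillespie
    simulator used to validate the analytic results. Clinical input tables
    for breast, colorectal, head and neck, lung and prostate cancers are
    bundled.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
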