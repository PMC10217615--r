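Package: entrotest
Title: Asymptotic Inference for Plug-In Entropies of Multinomial Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Plug-in Shannon, Tsallis, and Renyi entropies and the discrete
    Fisher information measure computed from multinomial count samples,
    together with their closed-form asymptotic (large-n) distributions
    obtained by the multivariate delta method. Includes a two-sample z-test
    for comparing entropies of possibly different types and different
    numbers of categories, a chi-squared homogeneity baseline, synthetic
    probability models (linear, one-almost-zero, half-and-half) with exact
    multinomial sampling, and a simulation harness that validates the limit
    laws with Anderson-Darling normality sweeps, Kolmogorov-Smirnov
    goodness-of-fit sweeps, and Monte-Carlo variance calibration. Count
    tables are tidy data frames throughout; fitted laws and tests provide
    broom-style tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
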