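Package: volnorm
Title: Size-Effect Normalization for Metabolomics Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates unknown sample volumes (size effects) in metabolomics
    time-series measurements and normalizes measured abundances to
    concentrations. Implements probabilistic quotient normalization (PQN),
    pharmacokinetic-model normalization (PKM) based on a modified Bateman
    function fitted by bounded robust nonlinear least squares with
    Monte-Carlo multistart, and a combined MIX model whose fitted volumes
    are biased towards the PQN quotients. Ships a synthetic-data benchmark
    framework (kinetic, random, and resampled concentration profiles,
    truncated log-normal volumes, multiplicative error, noise-fraction
    masking), goodness-of-normalization metrics (RMSE, rRMSE, scaled
    errors, paired Wilcoxon comparison), and LC-MS feature-table
    pre-filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
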