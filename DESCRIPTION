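Package: mastnao
Title: Continental Masting Synchrony and North Atlantic Oscillation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to link continental-scale tree masting synchrony to
    inter-annual and decadal components of seasonal North Atlantic
    Oscillation (NAO) indices. Builds an annual masting synchrony index
    from ordinal seed-crop records aggregated to regional modal
    chronologies; aggregates monthly teleconnection tables to seasonal,
    lag-aligned predictors; computes Morlet wavelet coherence with
    Monte Carlo significance against AR(1) surrogates; decomposes
    seasonal series into low- and high-frequency components with a
    fixed-span running-line smoother; fits maximum-likelihood beta
    regressions with collinearity gating, interaction screening,
    AIC-based predictor importance and leave-one-out cross-validation;
    and correlates seasonal indices with gridded climate anomalies.
    Includes a synthetic-data generator with known truth so the whole
    pipeline can be exercised and calibrated without external downloads.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
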