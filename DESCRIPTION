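Package: mcml
Title: Maximum-Correlation Analog Forecasting and Time-Lagged Analytics for
    Epidemic-Like Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free tools for daily, non-negative, epidemic-like time
    series (normalized new cases, stock indices, population counts). Implements
    maximum-correlation machine learning (MCML): principal-lag selection by BIC
    over lagged linear models of the one-day log-scale change, followed by
    analog forecasting that reuses the historical increment whose principal-lag
    vector is most Pearson-correlated with the current one, iterated over a
    held-out test horizon and scored by MAE/RMSE/MAPE. Also provides the
    accompanying time-lagged analytics: autocorrelation, binned average mutual
    information (AMI) with lag profiles and sum-of-absolute-AMI summaries,
    sliding-window feature spaces with dynamic half-maximum scaling, local
    Lyapunov exponents and their pairwise maximum (MLE), and peak/spike
    alignment diagnostics for anticipating epidemic wave peaks. Seeded
    synthetic generators (multi-wave epidemic curves, lagged linear difference
    models, periodic and chaotic logistic-map series, delayed-feedback
    oscillations) make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
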