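Package: mortalitynowcast
Title: Nowcasting Weekly Mortality Counts from Heterogeneous Proxy Data Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase stacked-generalization pipeline for near-real-time
    estimation ("nowcasting") of weekly national fatality counts from multiple
    heterogeneous proxy time series (health-service utilisation, online search
    and social-media activity, economic indicators). Phase one trains a zoo of
    regression models (OLS, lasso, ridge, elastic net, random forest, support
    vector regression) on lagged sliding-window features per data stream and
    selects the best model per stream on a held-out validation year; phase two
    combines the per-stream weekly predictions through a small feed-forward
    neural network meta-learner, in the spirit of the super learner. Includes a
    seasonality-aware Holt-Winters historical baseline, a surveillance metric
    battery (Pearson r, RMSE, MAPE, SMAPE, annual rate error per 100 000), an
    ISO-week calendar layer with monthly-to-weekly alignment, and a seeded
    synthetic-data generator that emulates the statistical structure of
    restricted surveillance inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    e1071,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
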