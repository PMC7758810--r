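# mortalitynowcast

Nowcasting weekly national mortality counts from heterogeneous real-time
proxy data streams.

## The problem

Official statistics on some causes of death — suicide in particular — are
published a year or more after the fact, which rules out timely public
health response. Several secondary signals track the same underlying
phenomenon and are available in near real time: the proportion of emergency
department visits for self-harm, crisis-hotline call volumes, poison-control
call proportions, search-engine trend scores, and social-media posting
activity. This package is for surveillance modellers who want to combine
such streams into a weekly estimate of the current national count, and to
quantify how much each stream and their ensemble contribute.

## The method

A two-phase stacked-generalization ("super learner") pipeline:

**Phase 1 — per-source models.** For each stream *s*, lagged sliding-window
features `x_{t-l-w+1}, ..., x_{t-l}` (default window w = 8 weeks; lead l = 0
for real-time streams, l = 52 for the delayed historical stream) are mapped
to the weekly count `y_t` by a zoo of regressors — OLS, lasso, ridge,
elastic net, random forest, RBF support vector regression — on a
year-blocked split (train through 2015, validate on 2016, test on 2017).
The best candidate per stream is chosen by validation-year Pearson
correlation (trend tracking is what surveillance consumers act on), refit on
train + validation, and produces test-year predictions `ŷ_t^(s)`.

**Phase 2 — stacking ensemble.** The per-stream predictions become the
inputs of a one-hidden-layer neural network (8 rectifier units, linear
output, full-batch Adam, L2 weight decay) trained on validation-year
predictions against validation-year truth, then evaluated on the held-out
test year. Six canonical source combinations are reported: health services,
online, baseline + each, health + online, and all sources. A historical
baseline (lag-52 regression on the target itself, or additive Holt-Winters
with period 52) represents practice without real-time data.

Metrics per prediction series: Pearson *r*, RMSE, MAPE,
SMAPE `= 100 · mean(|a−e|/(a+e))`, and the annual estimated rate per
100 000 with its percentage error `100·|Σe − Σa|/Σa`.

Because the real inputs are restricted, the package ships a seeded
synthetic-data generator (`generate_bundle()`) reproducing their statistical
structure — trend + seasonality + a faster-growing test year in the truth;
per-stream coupling, noise, lag, bounded scales, late starts, monthly
economic indicators — so the entire pipeline runs, and is tested, offline.

## Worked example

The `analysis/` scripts run the full study on the synthetic panel and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_base_models.R
Rscript analysis/03_ensemble.R
Rscript analysis/04_published_table_statistics.R
```

Stage 2 prints the per-source (phase 1) table, e.g.:

```
label          category               family         pearson rmse   mape_pct annual_error_pct
historical     historical_fatalities  ols            0.557   31.009 2.511    1.42
poison_like    health_services        elastic_net    0.612   42.491 3.775    3.70
google_like    online                 ridge          0.489   28.752 2.497    0.74
reddit_like    online                 elastic_net    0.293   48.629 4.451    4.12
...
```

Each row is one proxy stream's best model evaluated on the held-out test
year: no single stream is both a good trend tracker and a good annual
estimator. Stage 3 prints the ensemble (phase 2) table and the headline
comparison:

```
label                                  pearson rmse   mape_pct annual_error_pct
Health services data sources           0.684   24.001 2.010    0.55
Online data sources                    0.549   26.398 2.328    0.43
All data sources                       0.668   24.374 2.055    0.78

all-sources ensemble: r=0.668, annual error=0.78% (baseline: r=0.557, 1.42%)
```

The stacked ensembles beat every individual stream on weekly error, and the
all-sources ensemble tracks trends better than the historical baseline
(r 0.668 vs 0.557) while roughly halving its annual error (0.78% vs 1.42%)
— the baseline misses the test year's accelerated growth, which the
real-time streams see. Stage 4 verifies, by exact arithmetic on the bundled
published performance tables (`inst/extdata/table1.csv`, `table2.csv`),
every in-text comparison statistic those tables imply, e.g. the largest
correlation gap among individual models (0.372) and the all-sources
ensemble's gains over the baseline (+0.05 correlation, −35.351 RMSE,
−7.25 points of annual error).

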