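test_that("degenerate truth configuration yields a constant series", {
  cfg <- truth_config(base_level = 800, trend_per_week = 0,
                      seasonal_amplitude = 0, noise_sd = 0,
                      surge_per_week = 0)
  s <- generate_truth(cfg, seed = 99)
  expect_true(all(s$value == 800))
  expect_length(s, 209L)  # 2014-2017 = 52+53+52+52 ISO weeks
})

test_that("noise-free weekly increments follow the closed-form mean function", {
  cfg <- truth_config(trend_per_week = 1, seasonal_amplitude = 40,
                      noise_sd = 0, surge_per_week = 0)
  s <- generate_truth(cfg, seed = 1)
  t0 <- seq_along(s$value) - 1
  mu <- 830 + t0 + 40 * cos(2 * pi * (t0 - 16) / 52)
  expect_equal(s$value, round(mu))
  # increments stay within rounding of trend plus the seasonal derivative
  d <- diff(s$value)
  d_mu <- diff(mu)
  expect_true(all(abs(d - d_mu) <= 1))
})

test_that("truth generation is deterministic and respects n_years >= 3", {
  expect_identical(generate_truth(seed = 5), generate_truth(seed = 5))
  expect_false(identical(generate_truth(seed = 5), generate_truth(seed = 6)))
  expect_error(truth_config(n_years = 2), "n_years")
})

test_that("first-year totals land at a plausible national scale", {
  # Monte Carlo over 100 seeds: year-1 total within [40k, 50k] in >= 95
  totals <- vapply(1:100, function(s) {
    tr <- generate_truth(truth_config(), seed = s)
    sum(tr$value[tr$iso_year == 2014])
  }, 0)
  expect_gte(sum(totals >= 40000 & totals <= 50000), 95)
})

test_that("an exact copy stream reproduces truth with correlation 1", {
  truth <- smooth_truth(noise_sd = 10)
  st <- generate_stream(truth, stream_config("copy", "online", coupling = 1),
                        seed = 3)
  expect_equal(st$series$value, truth$value)
  expect_equal(pearson(truth, st$series), 1)
})

test_that("a pure-seasonality stream correlates with truth exactly as the
           seasonal component does", {
  truth <- generate_truth(truth_config(noise_sd = 20), seed = 11)
  st <- generate_stream(truth,
                        stream_config("seasonal", "online", coupling = 0,
                                      season_leak = 1, noise_sd = 0),
                        seed = 11)
  t0 <- seq_along(truth$value) - 1
  seasonal <- cos(2 * pi * t0 / 52)
  expect_equal(pearson(truth, st$series),
               stats::cor(truth$value, seasonal))
})

test_that("overwhelming noise destroys the stream-truth correlation", {
  truth <- generate_truth(truth_config(), seed = 2)
  big <- 10 * stats::sd(truth$value)
  weak <- vapply(1:100, function(s) {
    st <- generate_stream(truth,
                          stream_config("noisy", "online", coupling = 1,
                                        noise_sd = big), seed = s)
    abs(pearson(truth, st$series))
  }, 0)
  expect_gte(sum(weak < 0.3), 90)
})

test_that("scale contracts hold: 0-100 attains endpoints, proportions stay in (0,1)", {
  truth <- generate_truth(truth_config(), seed = 7)
  sc <- generate_stream(truth, stream_config("g", "online", noise_sd = 30,
                                             scale = "zero_one_hundred"),
                        seed = 7)
  expect_equal(range(sc$series$value), c(0, 100))
  pr <- generate_stream(truth, stream_config("p", "online", noise_sd = 30,
                                             scale = "proportion"), seed = 7)
  expect_true(all(pr$series$value > 0 & pr$series$value < 1))
  # monotone: ranks preserved under both transforms
  raw <- generate_stream(truth, stream_config("r", "online", noise_sd = 30),
                         seed = 7)
  expect_equal(order(sc$series$value), order(raw$series$value))
  expect_equal(order(pr$series$value), order(raw$series$value))
  # degenerate: constant raw series cannot be min-max scaled
  flat <- toy_series(rep(5, 60))
  expect_error(generate_stream(flat, stream_config("f", "online", coupling = 1,
                                                   scale = "zero_one_hundred"),
                               seed = 1),
               "constant")
})

test_that("raising noise never raises the expected stream-truth correlation", {
  truth <- generate_truth(truth_config(), seed = 4)
  levels <- c(10, 40, 120, 400)
  mean_r <- vapply(levels, function(ns) {
    mean(vapply(1:30, function(s) {
      st <- generate_stream(truth, stream_config("x", "online", noise_sd = ns),
                            seed = s)
      pearson(truth, st$series)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_r) < 0.02))  # one-sided tolerance for MC noise
})

test_that("bundles are seed-deterministic with per-stream seed isolation", {
  b1 <- generate_bundle(seed = 21)
  b2 <- generate_bundle(seed = 21)
  expect_identical(b1, b2)
  # dropping one stream leaves the others' values untouched
  preset <- default_stream_preset()
  b3 <- generate_bundle(stream_configs = preset[-1], seed = 21)
  expect_identical(b3$streams$google_like, b1$streams$google_like)
  expect_error(generate_bundle(stream_configs = c(preset, preset[1])),
               "duplicate stream name")
})

test_that("default preset: late-start stream is 52 weeks short; monthly stream
           carries a monthly table; search-trend stream beats the noisiest", {
  b <- generate_bundle(seed = 8)
  expect_equal(length(b$truth) - length(b$streams$twitter_like$series), 52L)
  expect_s3_class(b$streams$economic_like$monthly, "data.frame")
  expect_equal(b$streams$economic_like$frequency, "monthly")
  wins <- vapply(1:100, function(s) {
    bb <- generate_bundle(seed = s)
    g <- bb$streams$google_like$series
    r <- bb$streams$reddit_like$series
    tr <- bb$truth
    g_r <- pearson(weekly_series(g$iso_year, g$iso_week,
                                 ws_value_at(tr, g$iso_year, g$iso_week)), g)
    r_r <- pearson(weekly_series(r$iso_year, r$iso_week,
                                 ws_value_at(tr, r$iso_year, r$iso_week)), r)
    g_r > r_r
  }, TRUE)
  expect_gte(sum(wins), 95)
})

test_that("bundle CSVs round-trip byte-identically under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(generate_bundle(seed = 33), d1)
  write_bundle(generate_bundle(seed = 33), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  back <- read_bundle(d1)
  expect_equal(back$truth$value, generate_bundle(seed = 33)$truth$value)
  expect_equal(back$population, 325700000)
})
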