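#' Synthetic surveillance panel generator
#'
#' The real inputs to a weekly mortality nowcast — vital-statistics death
#' counts, syndromic ED-visit proportions, crisis-line call volumes, poison
#' control call proportions, search-trend scores, social-media post counts and
#' monthly economic indicators — are restricted or require scraping. This
#' module generates a ground-truth weekly count series plus a configurable
#' panel of proxy streams that reproduce the *statistical structure* those
#' analyses assume: linear coupling to truth with stream-specific noise, lag,
#' independent seasonal leakage, bounded scales (0-100 trend scores,
#' proportions), late stream starts and monthly-frequency economic indicators.
#' Everything is seeded and bit-reproducible.
#'
#' @name synthetic_data
NULL

#' Configuration for the ground-truth weekly count series
#'
#' Defaults emulate a national weekly fatality count: level ~830/week with a
#' slow upward trend and annual seasonality, so annual totals land around
#' 44,000-47,000 and annual rates around 13-15 per 100,000 at a national
#' population denominator.
#'
#' @param n_years number of whole calendar years (>= 3: train + validation +
#'   test)
#' @param base_level mean weekly count at the start week
#' @param trend_per_week linear drift, counts per week
#' @param seasonal_amplitude amplitude of the annual cosine, counts
#' @param seasonal_phase week of the seasonal peak (default 16, a spring peak)
#' @param noise_sd SD of the additive Gaussian week noise, counts
#' @param surge_per_week additional slope, counts/week, that switches on at
#'   `surge_start_week` — emulates the documented feature of recent US suicide
#'   mortality that the final (test) year grew faster than the historical
#'   trend (roughly +5% in 2017 after ~2-3%/year before), which is precisely
#'   what a purely historical baseline cannot anticipate. Default 0.6
#'   (~+1.8% extra growth over the final year of the default bundle).
#' @param surge_start_week 0-based week index at which the surge begins;
#'   `NULL` (default) means the start of the final year
#' @param start c(iso_year, iso_week) of the first week
#' @return list of class `truth_config`
#' @export
truth_config <- function(n_years = 4L, base_level = 830, trend_per_week = 0.5,
                         seasonal_amplitude = 40, seasonal_phase = 16,
                         noise_sd = 25, surge_per_week = 0.6,
                         surge_start_week = NULL, start = c(2014L, 1L)) {
  if (n_years < 3L) stop("n_years must be >= 3 (train + validation + test)")
  stopifnot(base_level > 0, noise_sd >= 0, seasonal_amplitude >= 0)
  structure(list(n_years = as.integer(n_years), base_level = base_level,
                 trend_per_week = trend_per_week,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_phase = seasonal_phase, noise_sd = noise_sd,
                 surge_per_week = surge_per_week,
                 surge_start_week = surge_start_week,
                 start = as.integer(start)),
            class = "truth_config")
}

#' Generate the ground-truth weekly count series
#'
#' `value(t) = max(0, round(base + trend * t + surge * max(0, t - t_surge) +
#' A * cos(2 * pi * (t - phase) / 52) + e_t))` with `e_t ~ N(0, noise_sd^2)`
#' and `t` the 0-based week index. The generative seasonal period is fixed at
#' 52 weeks; the calendar layer still carries 53-week years (the phase error
#' this introduces is < 2%).
#'
#' @param config a [truth_config()]
#' @param seed integer RNG seed
#' @return a [weekly_series()] of non-negative integer counts covering
#'   `n_years` whole calendar years
#' @export
generate_truth <- function(config = truth_config(), seed = 1L) {
  stopifnot(inherits(config, "truth_config"))
  years <- config$start[1L] + seq_len(config$n_years) - 1L
  n <- sum(weeks_in_iso_year(years)) - (config$start[2L] - 1L)
  weeks <- week_seq(config$start[1L], config$start[2L], n)
  t0 <- seq_len(n) - 1
  t_surge <- config$surge_start_week %||%
    (n - weeks_in_iso_year(years[length(years)]))
  mu <- config$base_level + config$trend_per_week * t0 +
    config$surge_per_week * pmax(0, t0 - t_surge) +
    config$seasonal_amplitude * cos(2 * pi * (t0 - config$seasonal_phase) / 52)
  set.seed(as.integer(seed))
  eps <- stats::rnorm(n, 0, config$noise_sd)
  weekly_series(weeks$iso_year, weeks$iso_week, pmax(0, round(mu + eps)))
}

#' Configuration for one synthetic proxy stream
#'
#' @param name stream name
#' @param category provenance category as in [source_stream()]
#' @param coupling slope linking the stream to the truth series
#' @param lag_weeks how many weeks the stream trails the truth signal (>= 0)
#' @param season_leak amplitude of an independent annual cosine picked up by
#'   the stream (seasonal confounding not mediated by truth)
#' @param noise_sd SD of the stream's own Gaussian noise, raw scale
#' @param scale `raw` (counts), `zero_one_hundred` (min-max to 0-100, like
#'   search-trend popularity scores) or `proportion` (logistic squash into
#'   (0,1), like ED-visit or poison-call proportions)
#' @param frequency `weekly`, or `monthly` for economic-style indicators (the
#'   weekly signal is averaged within calendar months, then re-aligned to the
#'   weekly grid by month repetition)
#' @param start_offset_weeks weeks after the truth start at which the stream
#'   begins (emulates sources whose collection started later)
#' @return list of class `stream_config`
#' @export
stream_config <- function(name, category = "online", coupling = 1,
                          lag_weeks = 0L, season_leak = 0, noise_sd = 0,
                          scale = c("raw", "zero_one_hundred", "proportion"),
                          frequency = c("weekly", "monthly"),
                          start_offset_weeks = 0L) {
  scale <- match.arg(scale)
  frequency <- match.arg(frequency)
  stopifnot(lag_weeks >= 0L, start_offset_weeks >= 0L, noise_sd >= 0)
  structure(list(name = name, category = category, coupling = coupling,
                 lag_weeks = as.integer(lag_weeks), season_leak = season_leak,
                 noise_sd = noise_sd, scale = scale, frequency = frequency,
                 start_offset_weeks = as.integer(start_offset_weeks)),
            class = "stream_config")
}

#' Generate one proxy stream coupled to a truth series
#'
#' `raw(t) = coupling * truth(t - lag) + season_leak * cos(2 * pi * t / 52) +
#' e_t`, then the configured scale transform (always monotone). The stream
#' starts `start_offset_weeks` after the truth series (and never before its
#' lag allows).
#'
#' @param truth a [weekly_series()]
#' @param config a [stream_config()]
#' @param seed integer RNG seed
#' @return a [source_stream()]
#' @export
generate_stream <- function(truth, config, seed = 1L) {
  stopifnot(inherits(truth, "weekly_series"), inherits(config, "stream_config"))
  n <- length(truth)
  if (config$lag_weeks >= n) stop("lag_weeks must be < length(truth)")
  first <- max(config$lag_weeks, config$start_offset_weeks) + 1L
  if (first > n) stop("start_offset_weeks leaves no coverage")
  idx <- first:n
  t0 <- idx - 1
  set.seed(as.integer(seed))
  raw <- config$coupling * truth$value[idx - config$lag_weeks] +
    config$season_leak * cos(2 * pi * t0 / 52) +
    stats::rnorm(length(idx), 0, config$noise_sd)
  vals <- switch(config$scale,
    raw = raw,
    zero_one_hundred = {
      rng <- range(raw)
      if (rng[1] == rng[2]) {
        stop(sprintf("stream '%s': constant raw values cannot be min-max scaled",
                     config$name))
      }
      100 * (raw - rng[1]) / (rng[2] - rng[1])
    },
    proportion = {
      s <- stats::sd(raw)
      if (s == 0) stop(sprintf("stream '%s': constant raw values cannot be squashed",
                               config$name))
      stats::plogis((raw - mean(raw)) / s)
    })
  series <- weekly_series(truth$iso_year[idx], truth$iso_week[idx], vals)
  monthly <- NULL
  if (config$frequency == "monthly") {
    mo <- week_month(series$iso_year, series$iso_week)
    key <- sprintf("%04d-%02d", mo$year, mo$month)
    agg <- tapply(series$value, key, mean)
    monthly <- data.frame(
      year = as.integer(substr(names(agg), 1, 4)),
      month = as.integer(substr(names(agg), 6, 7)),
      value = as.numeric(agg))
    monthly <- monthly[order(monthly$year, monthly$month), , drop = FALSE]
    rownames(monthly) <- NULL
    # re-aligned weekly series: each week carries its month's mean
    series <- weekly_series(series$iso_year, series$iso_week,
                            as.numeric(agg[key]))
  }
  source_stream(config$name, config$category, config$frequency, series,
                monthly = monthly)
}

#' Default 8-stream panel mirroring a multi-source surveillance study
#'
#' Three health-services streams (poison-control-like and ED-visit-like
#' proportions, a crisis-line-like count), four online streams
#' (search-trend-like 0-100 scores, a noisy social-forum-like proportion, a
#' count stream that starts a year late) and one monthly economic-style
#' indicator. The coupled signal has SD roughly `coupling * 48` on the raw
#' scale; per-stream noise SDs are set so the stream-truth correlations span
#' roughly 0.4-0.75 — the range real proxy sources achieve — with the
#' search-trend-like stream the most informative and the late-start count
#' stream the least, so no single stream dominates and combining them is
#' genuinely informative.
#'
#' @return list of [stream_config()]
#' @export
default_stream_preset <- function() {
  list(
    stream_config("poison_like", "health_services", coupling = 1,
                  season_leak = 5, noise_sd = 50, scale = "proportion"),
    stream_config("lifeline_like", "health_services", coupling = 15,
                  season_leak = 100, noise_sd = 1250, scale = "raw"),
    stream_config("ed_like", "health_services", coupling = 1,
                  season_leak = 0, noise_sd = 80, scale = "proportion"),
    stream_config("google_like", "online", coupling = 1,
                  season_leak = 8, noise_sd = 45, scale = "zero_one_hundred"),
    stream_config("youtube_like", "online", coupling = 1,
                  season_leak = 10, noise_sd = 67, scale = "zero_one_hundred"),
    stream_config("reddit_like", "online", coupling = 1,
                  season_leak = 0, noise_sd = 85, scale = "proportion"),
    stream_config("twitter_like", "online", coupling = 8,
                  season_leak = 0, noise_sd = 900, scale = "raw",
                  start_offset_weeks = 52L),
    stream_config("economic_like", "economic", coupling = 1, lag_weeks = 4L,
                  season_leak = 0, noise_sd = 48, scale = "raw",
                  frequency = "monthly")
  )
}

#' Generate a full synthetic bundle (truth + proxy panel)
#'
#' Per-stream noise is seeded by a stable hash of `(seed, name)`, so adding or
#' reordering streams never perturbs the others, and regeneration with the
#' same seed is bit-identical.
#'
#' @param truth_config a [truth_config()]
#' @param stream_configs list of [stream_config()]; defaults to
#'   [default_stream_preset()]
#' @param population denominator for annual rates per 100,000
#' @param seed integer master seed
#' @return list of class `synthetic_bundle` with elements `truth`, `streams`
#'   (named list of [source_stream()]), `population`, `seed`
#' @export
generate_bundle <- function(truth_config = mortalitynowcast::truth_config(),
                            stream_configs = default_stream_preset(),
                            population = 325700000, seed = 1L) {
  nm <- vapply(stream_configs, function(cfg) cfg$name, "")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate stream name '%s'", nm[duplicated(nm)][1L]))
  }
  truth <- generate_truth(truth_config, seed = derive_seed(seed, "truth"))
  streams <- lapply(stream_configs, function(cfg) {
    generate_stream(truth, cfg, seed = derive_seed(seed, cfg$name))
  })
  names(streams) <- nm
  structure(list(truth = truth, streams = streams,
                 population = population, seed = as.integer(seed)),
            class = "synthetic_bundle")
}

#' Write a bundle to a directory of CSVs plus a manifest
#'
#' Writes `truth.csv`, one `<name>.csv` per stream (aligned weekly values),
#' `<name>_monthly.csv` for monthly streams (raw monthly table), and
#' `manifest.json` recording names, categories, frequencies, spans and the
#' population denominator.
#'
#' @param bundle a [generate_bundle()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_csv(bundle$truth, file.path(dir, "truth.csv"))
  manifest <- list(population = bundle$population, seed = bundle$seed,
                   streams = lapply(bundle$streams, function(s) {
    list(name = s$name, category = s$category, frequency = s$frequency,
         start = week_label(s$span$start[1], s$span$start[2]),
         end = week_label(s$span$end[1], s$span$end[2]))
  }))
  for (s in bundle$streams) {
    write_series_csv(s$series, file.path(dir, paste0(s$name, ".csv")))
    if (!is.null(s$monthly)) {
      utils::write.csv(s$monthly,
                       file.path(dir, paste0(s$name, "_monthly.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle back from a directory written by [write_bundle()]
#' @param dir directory containing `truth.csv`, stream CSVs and `manifest.json`
#' @return a `synthetic_bundle`-shaped list
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  truth <- read_series_csv(file.path(dir, "truth.csv"))
  streams <- lapply(manifest$streams, function(m) {
    series <- read_series_csv(file.path(dir, paste0(m$name, ".csv")))
    monthly_path <- file.path(dir, paste0(m$name, "_monthly.csv"))
    monthly <- if (file.exists(monthly_path)) {
      utils::read.csv(monthly_path)
    }
    source_stream(m$name, m$category, m$frequency, series, monthly = monthly)
  })
  names(streams) <- vapply(streams, function(s) s$name, "")
  structure(list(truth = truth, streams = streams,
                 population = manifest$population,
                 seed = manifest$seed),
            class = "synthetic_bundle")
}
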