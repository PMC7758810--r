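# Shared fixtures, all built in code at test time.

# a short deterministic weekly series starting at 2016-W01
toy_series <- function(values, year = 2016L, week = 1L) {
  wk <- week_seq(year, week, length(values))
  weekly_series(wk$iso_year, wk$iso_week, values)
}

# noise-free seasonal + trend truth over 2014-2017 (no final-year surge)
smooth_truth <- function(noise_sd = 0, surge = 0) {
  generate_truth(truth_config(noise_sd = noise_sd, surge_per_week = surge),
                 seed = 1L)
}

default_split <- function() split_spec(2015L, 2016L, 2017L)

# reduced model zoo for fast unit tests
small_specs <- function(seed = 1L) {
  list(model_spec("ols", seed = seed),
       model_spec("ridge", list(lambda = c(0.1, 1)), seed = seed))
}

# a stream that is truth plus iid Gaussian noise on the raw scale
oracle_stream <- function(truth, sigma, seed = 1L, name = "oracle") {
  generate_stream(truth,
                  stream_config(name, "health_services", coupling = 1,
                                noise_sd = sigma, scale = "raw"),
                  seed = seed)
}

published_table1 <- function() {
  utils::read.csv(system.file("extdata", "table1.csv",
                              package = "mortalitynowcast"))
}

published_table2 <- function() {
  utils::read.csv(system.file("extdata", "table2.csv",
                              package = "mortalitynowcast"))
}
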