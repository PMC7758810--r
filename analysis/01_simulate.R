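#!/usr/bin/env Rscript
# Stage 1: generate the synthetic surveillance panel.
#
# The real inputs (vital-statistics weekly death counts, ED-visit and
# poison-call proportions, crisis-line volumes, search-trend scores,
# social-media counts, monthly economic indicators) are restricted, so the
# whole analysis runs on a seeded synthetic bundle that reproduces their
# statistical structure: a trending, seasonal weekly count series and eight
# proxy streams with stream-specific coupling, noise, scale, lag and
# coverage.

suppressMessages(library(mortalitynowcast))

seed <- 1L
data_dir <- file.path("results", "data")

bundle <- generate_bundle(seed = derive_seed(seed, "simulate"))
write_bundle(bundle, data_dir)

cat(sprintf("truth: %d weeks (%s .. %s), annual totals:\n",
            length(bundle$truth),
            week_label(bundle$truth$iso_year[1], bundle$truth$iso_week[1]),
            week_label(rev(bundle$truth$iso_year)[1],
                       rev(bundle$truth$iso_week)[1])))
print(tapply(bundle$truth$value, bundle$truth$iso_year, sum))
cat("\nstreams written to", data_dir, "\n")
for (s in bundle$streams) {
  sub <- ws_value_at(bundle$truth, s$series$iso_year, s$series$iso_week)
  r <- stats::cor(sub, s$series$value)
  cat(sprintf("  %-14s %-16s %-7s %3d weeks  cor(truth)=%+.2f\n",
              s$name, s$category, s$frequency, length(s$series), r))
}
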