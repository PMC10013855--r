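#!/usr/bin/env Rscript
# Correlation structure of domain motions: pooled per-run window averages
# (the scatter summary behind pairwise r tables), and the time-lagged
# cross-correlation that localizes which coordinate leads. Outputs:
# results/window_scatter.csv, results/lag_correlation.csv.

suppressMessages(library(ternarymd))
seed <- 42
dir.create("results", showWarnings = FALSE)

# an ensemble of synthetic runs whose per-run means are anti-correlated,
# emulating the helix-stacking vs receptor-separation relationship
set.seed(seed)
n_runs <- 8
runs <- lapply(seq_len(n_runs), function(i) {
  base <- runif(1, 10, 20)
  list(x = cv_series("a1_a5_distance", base + rnorm(2000, sd = 0.8), "A"),
       y = cv_series("b2ar_a5_distance",
                     30 - 0.9 * base + rnorm(2000, sd = 0.8), "A"))
})
ws <- window_scatter(runs, last_ns = 1000)
write.csv(ws$means, "results/window_scatter.csv", row.names = FALSE)
message(sprintf("pooled r across %d run averages: %.2f", n_runs, ws$r))

# lag correlation on an OU pair with a planted 50 ns lead
pair <- correlated_cv_pair(0.8, 2e4, "ou", lag = 50, timestep = 1,
                           tau_ns = 10, seed = seed)
lc <- lag_correlation(pair$x, pair$y, max_lag = 500)
write.csv(as.data.frame(lc), "results/lag_correlation.csv",
          row.names = FALSE)
message(sprintf("lag profile peaks at %g ns with r = %.2f (planted 50 ns)",
                lag_peak(lc), max(abs(lc$r))))
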