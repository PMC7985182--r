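# Shared fixtures, built in code.

# Reference adult gold-standard parameter set.
ref_params <- function() csf_params(294.33, 3.62, 5.13, 0.90)

# The seven gold-standard test frequencies (cycles per degree).
paper_sfs <- function() c(0.5, 0.99, 1.96, 3.87, 7.66, 15.16, 30)

# Run one QUEST track against a simulated Weibull observer and return the
# final posterior-mean estimate.
quest_track <- function(true_threshold, seed, n_trials = 48,
                        prior_mean = -1.5, ...) {
  withr::with_seed(seed, {
    st <- quest_init(prior_mean, ...)
    for (i in seq_len(n_trials)) {
      x <- min(max(quest_next(st), -4), log10(0.5))
      ok <- stats::runif(1) < weibull_prob(x, true_threshold)
      st <- quest_update(st, x, ok)
    }
    quest_estimate(st)
  })
}

# Toy parameter table: one quest row and `runs` chart rows per observer, with
# values supplied as functions of the observer index.
toy_table <- function(n, group = "adult", runs = 3,
                      quest_fun = function(i) csf_params(200 + i, 3 + 0.1 * i,
                                                         5 + 0.05 * i,
                                                         0.5 + 0.02 * i),
                      chart_fun = function(i, r) csf_params(400 + 10 * i + r,
                                                            2 + 0.1 * i,
                                                            3 + 0.05 * i,
                                                            0.8 + 0.02 * i),
                      r_squared = function(i) 0.95) {
  rows <- list()
  for (i in seq_len(n)) {
    id <- sprintf("%s_%03d", group, i)
    rows[[length(rows) + 1]] <- parameter_row(id, group, "quest",
                                              quest_fun(i), r_squared(i))
    for (r in seq_len(runs)) {
      rows[[length(rows) + 1]] <- parameter_row(id, group,
                                                sprintf("chart_run%d", r),
                                                chart_fun(i, r))
    }
  }
  do.call(rbind, rows)
}

# Sub-pixel zero-crossing positions (in degrees) of a rendered chart row.
crossing_positions <- function(row, chart) {
  x <- (seq_along(row) - 0.5) / length(row) * chart$width_deg
  d <- row - chart$mean_level
  i <- which(d[-1] * d[-length(d)] < 0)
  x[i] - d[i] * (x[i + 1] - x[i]) / (d[i + 1] - d[i])
}
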