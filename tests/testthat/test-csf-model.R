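test_that("the truncated log-parabola evaluates to its analytic spot values", {
  p <- csf_params(100, 2, 2, 0.5)
  expect_equal(log_sensitivity(p, 2), 2)      # peak: log10(y_max)
  expect_equal(log_sensitivity(p, 4), 1)      # one octave above the peak
  expect_equal(log_sensitivity(p, 0.5), 1.5)  # low-SF plateau
  expect_equal(sensitivity(p, 2), 100)
  expect_equal(sensitivity(p, 4), 10)
  # the peak always returns y_max
  for (pars in list(ref_params(), csf_params(10, 0.7, 3, 0))) {
    expect_equal(sensitivity(pars, pars$f_max), pars$y_max)
  }
  # truncation never applies above f_max, however deep the parabola falls
  expect_lt(log_sensitivity(p, 32), 2 - 0.5)
})

test_that("the two branches meet continuously and the plateau is flat", {
  p <- ref_params()
  # crossover frequency where the parabola equals the plateau, left of peak
  half_width <- p$beta * log10(2) / 2
  sf_cross <- 10^(log10(p$f_max) - half_width * sqrt(p$delta))
  eps <- 1e-9
  expect_equal(log_sensitivity(p, sf_cross * (1 - eps)),
               log_sensitivity(p, sf_cross * (1 + eps)), tolerance = 1e-6)
  grid <- 10^seq(log10(0.05), log10(60), length.out = 4000)
  vals <- log_sensitivity(p, grid)
  expect_lt(max(abs(diff(vals))), 0.01)                 # no jumps
  expect_equal(max(vals), log10(p$y_max), tolerance = 1e-6)  # maximum at peak
  expect_equal(which.max(vals),
               which.min(abs(grid - p$f_max)))
  low <- log_sensitivity(p, c(1e-4, 1e-3, 0.01))
  expect_true(all(low == log10(p$y_max) - p$delta))     # constant plateau
})

test_that("invalid inputs to the model are rejected", {
  expect_error(csf_params(-1, 2, 2, 0.5), "y_max")
  expect_error(csf_params(100, 2, 2, -0.1), "delta")
  expect_error(log_sensitivity(ref_params(), 0), "positive")
  expect_error(log_sensitivity(ref_params(), c(1, -2)), "positive")
})

test_that("clicks map to parameters through the chart's log axes", {
  ch <- chart_spec()
  # first click: axis endpoints and log midpoint
  p <- params_from_clicks(c(0, 0.3), c(0.5, 0.1), c(0, 0.2), ch)
  expect_equal(p$f_max, 0.16)
  expect_equal(p$y_max, 1 / contrast_at(ch, 0.3))
  p <- params_from_clicks(c(0.5, 0.5), c(0.9, 0.2), c(0, 0.3), ch)
  expect_equal(p$f_max, 0.16 * (40 / 0.16)^0.5, tolerance = 1e-12)
  # second click: beta solves the right half-parabola through the cursor
  u2 <- 0.9; v2 <- 0.2
  d <- log10(p$y_max) - log10(1 / contrast_at(ch, v2))
  beta_manual <- 2 * (log10(sf_at(ch, u2)) - log10(p$f_max)) /
    (log10(2) * sqrt(d))
  expect_equal(p$beta, beta_manual)
  # third click at the same height as the first: delta = 0
  p0 <- params_from_clicks(c(0.5, 0.5), c(0.9, 0.2), c(0.2, 0.5), ch)
  expect_equal(p0$delta, 0)
  # third click above the peak clamps to delta = 0
  p0 <- params_from_clicks(c(0.5, 0.5), c(0.9, 0.2), c(0.2, 0.9), ch)
  expect_equal(p0$delta, 0)
  # invalid second clicks
  expect_error(params_from_clicks(c(0.5, 0.5), c(0.5, 0.2), c(0, 0), ch),
               "frequency above")
  expect_error(params_from_clicks(c(0.5, 0.5), c(0.3, 0.2), c(0, 0), ch),
               "frequency above")
  expect_error(params_from_clicks(c(0.5, 0.5), c(0.9, 0.8), c(0, 0), ch),
               "below the peak")
  expect_error(params_from_clicks(c(0.5, 1.5), c(0.9, 0.2), c(0, 0), ch),
               "fractions")
})

test_that("clicks_from_params inverts params_from_clicks inside the chart", {
  ch <- chart_spec()
  draws <- withr::with_seed(11, data.frame(
    y_max = 10^runif(25, log10(50), log10(900)),
    f_max = 10^runif(25, log10(0.3), log10(4)),
    beta = runif(25, 1, 4),
    delta = runif(25, 0, 1.2)))
  for (i in seq_len(nrow(draws))) {
    truth <- csf_params(draws$y_max[i], draws$f_max[i], draws$beta[i],
                        draws$delta[i])
    cl <- clicks_from_params(truth, ch)
    expect_false(cl$clipped)
    back <- params_from_clicks(cl$click1, cl$click2, cl$click3, ch)
    expect_equal(unclass(back), unclass(truth), tolerance = 1e-9)
  }
})

test_that("fit_csf recovers noiseless parameters and matches a grid oracle", {
  truth <- ref_params()
  sfs <- paper_sfs()
  fit <- fit_csf(sfs, sensitivity(truth, sfs))
  for (p in c("y_max", "f_max", "beta", "delta")) {
    expect_equal(fit$params[[p]], truth[[p]], tolerance = 1e-3)
  }
  expect_gt(fit$r_squared, 0.9999)
  expect_length(fit$residuals, length(sfs))
  # grid-search oracle on a small box around the truth: the optimiser's SSE
  # must not exceed the best grid point's SSE, whose minimum sits at truth
  y <- log10(sensitivity(truth, sfs))
  grid <- expand.grid(y_max = truth$y_max * c(0.99, 0.995, 1, 1.005, 1.01),
                      f_max = truth$f_max * c(0.99, 0.995, 1, 1.005, 1.01),
                      beta = truth$beta * c(0.99, 1, 1.01),
                      delta = truth$delta * c(0.99, 1, 1.01))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    pr <- csf_params(grid$y_max[i], grid$f_max[i], grid$beta[i],
                     grid$delta[i])
    sum((y - log_sensitivity(pr, sfs))^2)
  }, numeric(1))
  expect_equal(unlist(grid[which.min(sse), ]), unlist(unclass(truth)),
               ignore_attr = TRUE)
  expect_lte(fit$sse, min(sse) + 1e-12)
})

test_that("an inactive truncation leaves the parabola fit unaffected", {
  truth <- csf_params(100, 3, 3, 3)  # plateau below every sampled point
  sfs <- paper_sfs()
  fit <- fit_csf(sfs, sensitivity(truth, sfs))
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$params$y_max, truth$y_max, tolerance = 1e-3)
  expect_equal(fit$params$f_max, truth$f_max, tolerance = 1e-3)
  expect_equal(fit$params$beta, truth$beta, tolerance = 1e-3)
})

test_that("degenerate (flat) input yields a flagged fit, not an error", {
  fit <- fit_csf(paper_sfs(), rep(50, 7))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$r_squared))
  expect_error(fit_csf(c(1, 2, 3), c(1, 2, 3)), ">= 4")
  expect_error(fit_csf(paper_sfs(), rep(-1, 7)), "positive")
})

test_that("average_curves averages point-by-point", {
  p <- ref_params()
  one <- average_curves(list(p))
  expect_equal(one$mean_log_sens, log_sensitivity(p, one$sf))
  expect_true(all(one$sd_log_sens == 0))
  two <- average_curves(list(p, p))
  expect_equal(two$mean_log_sens, log_sensitivity(p, two$sf))
  expect_true(all(two$sd_log_sens == 0))
  a <- csf_params(100, 2, 3, 0.5)
  b <- csf_params(1000, 2, 3, 0.5)
  avg <- average_curves(list(a, b), sf_grid = 2)
  expect_equal(avg$mean_log_sens, 2.5)
  expect_equal(avg$sd_log_sens, stats::sd(c(2, 3)))
  expect_error(average_curves(list()), "empty")
})

test_that("area under the log CSF matches analytic and refinement oracles", {
  # flat curve at log sensitivity 1 over [0.5, 30]: a rectangle
  flat <- csf_params(10, 30, 1e6, 0)
  expect_equal(area_under_curve(flat, 0.5, 30), log10(60), tolerance = 1e-10)
  # a curve entirely below sensitivity 1 clamps to zero area
  expect_equal(area_under_curve(csf_params(0.5, 3, 3, 0), 0.5, 30), 0)
  # refinement oracle: 1e5-point Riemann sum
  p <- csf_params(294, 3.6, 5.1, 0.9)
  x <- seq(log10(0.5), log10(30), length.out = 1e5)
  mid <- (x[-1] + x[-length(x)]) / 2
  riemann <- sum(pmax(log_sensitivity(p, 10^mid), 0) * diff(x))
  expect_equal(area_under_curve(p, 0.5, 30), riemann, tolerance = 1e-3)
  expect_error(area_under_curve(p, 3, 2), "sf_lo")
})
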