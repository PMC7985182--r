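test_that("population sampling is deterministic and honours degenerate specs", {
  spec <- population_spec("adult", n = 20, seed = 5)
  a <- sample_population(spec)
  b <- sample_population(spec)
  expect_identical(a, b)
  expect_length(a, 20)
  expect_s3_class(a[[1]]$true_csf, "csf_params")
  # zero-SD spec yields the mean observer exactly
  m <- c(beta = 5.13, delta = 0.90, f_max = 3.62, y_max = 294.33)
  one <- sample_population(population_spec(
    "adult", n = 1, means = m, sds = m * 0, seed = 1))[[1]]
  expect_equal(unlist(unclass(one$true_csf))[names(m)], m)
  expect_error(population_spec("adult", n = 0), "n must be")
  expect_error(population_spec("adult", means = c(beta = -1, delta = 1,
                                                  f_max = 1, y_max = 1)),
               "positive")
})

test_that("sampled parameters converge to the gold-standard group moments", {
  # moderate n here; the acceptance suite checks 2-SE calibration at n = 1e4
  pop <- sample_population(population_spec("child", n = 4000, seed = 7))
  vals <- vapply(pop, function(o) unlist(unclass(o$true_csf)), numeric(4))
  targets <- list(mean = c(y_max = 168.18, f_max = 3.94, beta = 5.01,
                           delta = 0.84),
                  sd = c(y_max = 86.48, f_max = 0.85, beta = 0.75,
                         delta = 0.24))
  for (p in rownames(vals)) {
    se <- stats::sd(vals[p, ]) / sqrt(ncol(vals))
    expect_lt(abs(mean(vals[p, ]) - targets$mean[[p]]), 3 * se)
    expect_equal(stats::sd(vals[p, ]), targets$sd[[p]], tolerance = 0.05)
  }
})

test_that("responses follow the anchored psychometric function", {
  obs <- sample_population(population_spec("adult", n = 1, seed = 3))[[1]]
  thr <- -log_sensitivity(obs$true_csf, 2)
  expect_true(respond(obs, 2, thr + 2, seed = 1))     # far above threshold
  hits_low <- mean(vapply(1:2000, function(k)
    respond(obs, 2, thr - 2, seed = k), logical(1)))
  expect_equal(hits_low, 0.5, tolerance = 0.05)       # guess rate
  at_thr <- withr::with_seed(8, mean(vapply(1:10000, function(k)
    respond(obs, 2, thr), logical(1))))
  expect_lt(abs(at_thr - 0.82), 0.012)                # ~3 binomial SEs
})

test_that("zero bias and zero noise make the click round trip exact", {
  m <- c(beta = 4, delta = 0.6, f_max = 3, y_max = 200)
  obs <- sample_population(population_spec(
    "adult", n = 1, means = m, sds = m * 0,
    chart_bias = zero_chart_bias(), seed = 1))[[1]]
  ch <- chart_spec()
  cl <- simulate_clicks(obs, ch, run = 1, seed = 4)
  expect_false(cl$clipped)
  back <- params_from_clicks(cl$click1, cl$click2, cl$click3, ch)
  expect_equal(unclass(back), unclass(obs$true_csf), tolerance = 1e-9)
})

test_that("zero per-run noise repeats clicks; nonzero noise varies them", {
  quiet_bias <- lapply(zero_chart_bias(), function(b) {
    b["shift"] <- -0.2; b["obs_sd"] <- 0.2; b
  })
  pop <- sample_population(population_spec(
    "adult", n = 3, chart_bias = quiet_bias, seed = 6))
  ch <- chart_spec()
  for (obs in pop) {
    r1 <- simulate_clicks(obs, ch, run = 1, seed = 2)
    r2 <- simulate_clicks(obs, ch, run = 2, seed = 2)
    expect_identical(r1$click1, r2$click1)
    expect_identical(r1$click2, r2$click2)
  }
  noisy <- sample_population(population_spec("adult", n = 1, seed = 6))[[1]]
  n1 <- simulate_clicks(noisy, ch, run = 1, seed = 2)
  n2 <- simulate_clicks(noisy, ch, run = 2, seed = 2)
  expect_false(identical(n1$click1, n2$click1))
  expect_identical(n1$click1,
                   simulate_clicks(noisy, ch, run = 1, seed = 2)$click1)
})

test_that("default adult bias reproduces the chart-row calibration targets", {
  pop <- sample_population(population_spec("adult", n = 10000, seed = 42))
  ch <- chart_spec()
  derived <- vapply(pop, function(o) {
    cl <- simulate_clicks(o, ch, run = 1, seed = 99)
    unlist(params_from_clicks(cl$click1, cl$click2, cl$click3,
                              ch)[c("beta", "y_max")])
  }, numeric(2))
  # chart-derived beta ~ 3.19 and y_max ~ 667 (within 2 SE at n = 1e4) while
  # the gold-standard truth keeps beta ~ 5.13
  se_beta <- stats::sd(derived["beta", ]) / 100
  se_ymax <- stats::sd(derived["y_max", ]) / 100
  expect_lt(abs(mean(derived["beta", ]) - 3.193333), 2 * se_beta)
  expect_lt(abs(mean(derived["y_max", ]) - 667.35), 2 * se_ymax)
  true_beta <- vapply(pop, function(o) o$true_csf$beta, numeric(1))
  expect_lt(abs(mean(true_beta) - 5.13), 2 * stats::sd(true_beta) / 100)
})

test_that("chart-vs-gold-standard directions and reliability are calibrated", {
  ch <- chart_spec()
  for (g in c("adult", "child")) {
    pop <- sample_population(population_spec(g, n = 1500, seed = 12))
    truth <- vapply(pop, function(o) unlist(unclass(o$true_csf)), numeric(4))
    runs <- lapply(1:2, function(r) vapply(pop, function(o) {
      cl <- simulate_clicks(o, ch, run = r, seed = 13)
      unlist(params_from_clicks(cl$click1, cl$click2, cl$click3,
                                ch)[c("y_max", "f_max", "beta", "delta")])
    }, numeric(4)))
    chart_means <- rowMeans((runs[[1]] + runs[[2]]) / 2)
    expect_gt(chart_means["y_max"], mean(truth["y_max", ]))  # inflated peak
    expect_lt(chart_means["beta"], mean(truth["beta", ]))    # compressed width
    expect_lt(chart_means["f_max"], mean(truth["f_max", ]))  # shifted peak
    for (p in rownames(runs[[1]])) {
      r <- stats::cor(runs[[1]][p, ], runs[[2]][p, ])
      expect_gt(r, 0.5)
      expect_lt(r, 0.9)
    }
  }
})
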