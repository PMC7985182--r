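# Synthetic observer populations calibrated so that the QUEST-side true CSFs
# and the chart-side three-click adjustments reproduce the published group
# statistics for adults and children.

# Reference group statistics (means and SDs of the truncated log-parabola
# parameters). QUEST rows are the gold-standard targets for the generative
# ("true") CSFs; chart rows are the across-run averages of the three-click
# adjustment rows and calibrate the chart-bias model.
.quest_targets <- list(
  adult = list(mean = c(beta = 5.13, delta = 0.90, f_max = 3.62, y_max = 294.33),
               sd   = c(beta = 1.02, delta = 0.36, f_max = 0.82, y_max = 135.19)),
  child = list(mean = c(beta = 5.01, delta = 0.84, f_max = 3.94, y_max = 168.18),
               sd   = c(beta = 0.75, delta = 0.24, f_max = 0.85, y_max = 86.48)))

.chart_targets <- list(
  adult = list(mean = c(beta = 3.193333, delta = 1.05, f_max = 2.983333,
                        y_max = 667.35),
               sd   = c(beta = 0.906667, delta = 0.736667, f_max = 1.293333,
                        y_max = 443.7067)),
  child = list(mean = c(beta = 3.163333, delta = 0.856667, f_max = 2.77,
                        y_max = 539.80),
               sd   = c(beta = 0.896667, delta = 0.486667, f_max = 0.886667,
                        y_max = 333.5067)))

# Parameter sampling families: y_max and f_max are log-normal, beta and delta
# are normal truncated at zero.
.param_family <- c(beta = "truncnorm", delta = "truncnorm",
                   f_max = "lognorm", y_max = "lognorm")

# Solve for the parent N(mu, sigma) whose zero-truncated version has the
# requested mean and SD.
.solve_truncnorm <- function(m, s) {
  moments <- function(mu, sig) {
    a <- -mu / sig
    z <- stats::pnorm(a, lower.tail = FALSE)
    lam <- stats::dnorm(a) / z
    mean_t <- mu + sig * lam
    var_t <- sig^2 * (1 + a * lam - lam^2)
    c(mean_t, sqrt(max(var_t, 0)))
  }
  obj <- function(th) {
    mm <- moments(th[1], exp(th[2]))
    (mm[1] - m)^2 + (mm[2] - s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.rtruncnorm <- function(n, mu, sigma) {
  u <- stats::runif(n, stats::pnorm(0, mu, sigma), 1)
  stats::qnorm(u, mu, sigma)
}

# Variance of log(X) for X ~ N(mu, sigma) truncated to (0, Inf).
.truncnorm_logvar <- function(mu, sigma) {
  z <- stats::pnorm(0, mu, sigma, lower.tail = FALSE)
  dens <- function(x) stats::dnorm(x, mu, sigma) / z
  m1 <- stats::integrate(function(x) log(x) * dens(x), 0, Inf,
                         rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(x) log(x)^2 * dens(x), 0, Inf,
                         rel.tol = 1e-10)$value
  m2 - m1^2
}

# Mean and SD of min(X, cap) for X lognormal with log-scale parameters
# (mu, s) — closed form.
.censored_lnorm_moments <- function(mu, s, cap) {
  lc <- log(cap)
  p_over <- stats::pnorm((lc - mu) / s, lower.tail = FALSE)
  e1 <- exp(mu + s^2 / 2) * stats::pnorm((lc - mu - s^2) / s) + cap * p_over
  e2 <- exp(2 * mu + 2 * s^2) * stats::pnorm((lc - mu - 2 * s^2) / s) +
    cap^2 * p_over
  c(mean = e1, sd = sqrt(max(e2 - e1^2, 0)))
}

# Solve (mu, sigma) so that min(LN(mu, sigma), cap) has the requested mean
# exactly and an SD as close as possible to the requested one, subject to a
# plausibility constraint: at most `floor_p` of the population may fall below
# peak sensitivity `floor_val`. The constraint matters because a bounded
# distribution can only reach an SD close to its two-point maximum by piling
# mass on both extremes — i.e. by inventing observers who barely see the
# chart at all. For fixed sigma the censored mean is strictly increasing in
# mu, so mu comes from root-finding; sigma is then the smallest value whose
# mean-matched censored SD attains the target, or the largest feasible sigma
# when the target SD is out of reach under the constraint.
.solve_censored_lnorm <- function(m, s, cap, floor_val = 20, floor_p = 0.01) {
  stopifnot(m < cap)
  mu_for_mean <- function(sig) {
    stats::uniroot(function(mu) .censored_lnorm_moments(mu, sig, cap)[1] - m,
                   lower = log(m) - 6 * sig - 1, upper = log(cap) + 6 * sig,
                   tol = 1e-12)$root
  }
  profile <- function(sig) {
    mu <- mu_for_mean(sig)
    c(sd = unname(.censored_lnorm_moments(mu, sig, cap)[2]),
      p_floor = stats::pnorm((log(floor_val) - mu) / sig))
  }
  sig_grid <- seq(0.05, 4, by = 0.05)
  prof <- vapply(sig_grid, profile, numeric(2))
  feasible <- prof["p_floor", ] <= floor_p
  if (!any(feasible)) stop("censored-lognormal solve: no feasible sigma")
  idx <- which(feasible)
  hit <- idx[prof["sd", idx] >= s]
  sig <- if (length(hit)) {
    i <- hit[1]
    if (i == 1) sig_grid[1] else {
      stats::uniroot(function(g) profile(g)["sd"] - s,
                     lower = sig_grid[i - 1], upper = sig_grid[i],
                     tol = 1e-10)$root
    }
  } else {
    # SD target unattainable under the plausibility constraint: take the
    # most-dispersed feasible population (documented behaviour).
    sig_grid[max(idx)]
  }
  list(mu = mu_for_mean(sig), sigma = sig)
}

#' Calibrate the chart-bias model for a group
#'
#' The chart-perceived parameters are modelled as a multiplicative log-space
#' transform of the true parameters:
#' `log(p_chart) = log(p_true) + shift + eta_observer + eps_run`, with
#' `eta ~ N(0, obs_sd^2)` stable within an observer and
#' `eps ~ N(0, run_sd^2)` drawn anew on every chart run. For each parameter
#' the shift and the total bias variance are solved so that the population
#' mean and SD of the chart-perceived values match the chart-row reference
#' statistics; for `y_max` the solve accounts for censoring at the chart's
#' maximum displayable sensitivity (`1 / c_lo`), since the reference spread
#' is only reachable as a censored distribution on that chart. The censored
#' solve matches the mean exactly and approaches the reference SD from below
#' when reaching it would require an implausible near-two-point population
#' (more than 1% of observers with chart peak sensitivity under 20). The bias
#' variance is then split so that the expected inter-run (log-scale)
#' reliability equals `reliability`.
#'
#' @param group `"adult"` or `"child"`.
#' @param chart The [chart_spec] used for the runs (sets the censoring cap).
#' @param reliability Target inter-run correlation (default 0.70).
#' @param quest_mean,quest_sd,chart_mean,chart_sd Optional named vectors
#'   (`beta, delta, f_max, y_max`) overriding the built-in reference rows.
#' @return A list with one `c(shift, obs_sd, run_sd)` entry per parameter
#'   (shifts in natural-log units).
#' @export
calibrate_chart_bias <- function(group = c("adult", "child"),
                                 chart = chart_spec(), reliability = 0.7,
                                 quest_mean = NULL, quest_sd = NULL,
                                 chart_mean = NULL, chart_sd = NULL) {
  group <- match.arg(group)
  qm <- if (is.null(quest_mean)) .quest_targets[[group]]$mean else quest_mean
  qs <- if (is.null(quest_sd)) .quest_targets[[group]]$sd else quest_sd
  cm <- if (is.null(chart_mean)) .chart_targets[[group]]$mean else chart_mean
  cs <- if (is.null(chart_sd)) .chart_targets[[group]]$sd else chart_sd

  out <- list()
  for (p in names(.param_family)) {
    m_t <- qm[[p]]; s_t <- qs[[p]]; m_c <- cm[[p]]; s_c <- cs[[p]]
    # log-scale variance of the true parameter (for the reliability split)
    if (s_t == 0) {
      v_log <- 0
    } else if (.param_family[[p]] == "lognorm") {
      v_log <- log(1 + (s_t / m_t)^2)
    } else {
      pars <- .solve_truncnorm(m_t, s_t)
      v_log <- .truncnorm_logvar(pars$mu, pars$sigma)
    }
    if (p == "y_max") {
      cap <- 1 / chart$c_lo
      sol <- .solve_censored_lnorm(m_c, s_c, cap)
      mu_true <- log(m_t) - v_log / 2
      shift <- sol$mu - mu_true
      w <- sol$sigma^2 - v_log
    } else {
      a <- m_c / m_t
      b <- (m_c^2 + s_c^2) / (m_t^2 + s_t^2)
      w <- log(b / a^2)
      shift <- log(a) - w / 2
    }
    if (w <= 0) {
      warning(sprintf(
        "calibrate_chart_bias: %s chart spread not above true spread; using minimal noise", p))
      w <- 1e-6
    }
    run_var <- min((1 - reliability) * (v_log + w), w)
    out[[p]] <- c(shift = shift, obs_sd = sqrt(w - run_var),
                  run_sd = sqrt(run_var))
  }
  out
}

#' Population specification for synthetic observers
#'
#' Describes the generative distribution of true CSFs for a group. `y_max`
#' and `f_max` are sampled log-normally and `beta` and `delta` from normals
#' truncated at zero; all four are moment-matched so the sample means and SDs
#' converge to the reference (or supplied) values as `n` grows. The chart
#' bias defaults to [calibrate_chart_bias] for the group.
#'
#' @param group `"adult"` or `"child"`.
#' @param n Number of observers (default 96 adults / 74 children).
#' @param means,sds Optional named vectors (`beta, delta, f_max, y_max`)
#'   overriding the reference gold-standard rows.
#' @param chart_bias Optional chart-bias list as returned by
#'   [calibrate_chart_bias]; use zeros for a bias-free population.
#' @param chart Chart used for click simulation (default [chart_spec]).
#' @param reliability Target inter-run reliability for the default bias.
#' @param slope,guess,lapse,target Psychometric settings shared by all
#'   observers.
#' @param seed Sampling seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(group = c("adult", "child"),
                            n = c(adult = 96, child = 74)[[match.arg(group)]],
                            means = NULL, sds = NULL, chart_bias = NULL,
                            chart = chart_spec(), reliability = 0.7,
                            slope = 3.5, guess = 0.5, lapse = 0.01,
                            target = 0.82, seed = 1) {
  group <- match.arg(group)
  if (n < 1) stop("population_spec: n must be >= 1", call. = FALSE)
  m <- if (is.null(means)) .quest_targets[[group]]$mean else means
  s <- if (is.null(sds)) .quest_targets[[group]]$sd else sds
  if (any(m <= 0)) {
    stop("population_spec: parameter means must be positive", call. = FALSE)
  }
  if (any(s < 0)) stop("population_spec: SDs must be >= 0", call. = FALSE)
  if (is.null(chart_bias)) {
    chart_bias <- calibrate_chart_bias(group, chart = chart,
                                       reliability = reliability)
  }
  structure(list(group = group, n = n, means = m, sds = s,
                 chart_bias = chart_bias, chart = chart, slope = slope,
                 guess = guess, lapse = lapse, target = target, seed = seed),
            class = "population_spec")
}

#' Zero chart bias (for noise-free round-trip checks)
#'
#' @return A chart-bias list with zero shift and zero noise for every
#'   parameter.
#' @export
zero_chart_bias <- function() {
  lapply(stats::setNames(nm = names(.param_family)),
         function(p) c(shift = 0, obs_sd = 0, run_sd = 0))
}

#' Sample a population of synthetic observers
#'
#' Draws `spec$n` observers: a true CSF for each (moment-matched to the
#' group's gold-standard statistics), the shared psychometric settings, and a
#' stable per-observer chart-bias effect for each parameter. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [population_spec].
#' @return A list of `observer_profile` objects.
#' @export
#' @examples
#' pop <- sample_population(population_spec("adult", n = 5, seed = 1))
#' pop[[1]]$true_csf
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  draw_param <- function(p) {
    m <- spec$means[[p]]; s <- spec$sds[[p]]
    if (s == 0) return(rep(m, n))
    if (.param_family[[p]] == "lognorm") {
      sig2 <- log(1 + (s / m)^2)
      stats::rlnorm(n, log(m) - sig2 / 2, sqrt(sig2))
    } else {
      pars <- .solve_truncnorm(m, s)
      .rtruncnorm(n, pars$mu, pars$sigma)
    }
  }
  withr::with_seed(spec$seed, {
    vals <- lapply(stats::setNames(nm = names(.param_family)), draw_param)
    etas <- lapply(stats::setNames(nm = names(.param_family)), function(p)
      stats::rnorm(n, 0, spec$chart_bias[[p]][["obs_sd"]]))
    lapply(seq_len(n), function(i) {
      structure(list(
        id = sprintf("%s_%03d", spec$group, i),
        group = spec$group,
        true_csf = csf_params(vals$y_max[i], vals$f_max[i], vals$beta[i],
                              vals$delta[i]),
        slope = spec$slope, guess = spec$guess, lapse = spec$lapse,
        target = spec$target,
        chart_bias = spec$chart_bias,
        chart_eta = vapply(etas, `[`, numeric(1), i)),
        class = "observer_profile")
    })
  })
}

#' Simulate a two-alternative orientation response
#'
#' Bernoulli draw from the observer's Weibull psychometric function at the
#' shown contrast. The threshold at each frequency is the reciprocal of the
#' observer's true CSF sensitivity, and the function is anchored so that the
#' probability of a correct response at threshold equals the observer's
#' target level (0.82 by default) — the staircase's estimand therefore equals
#' the generative CSF.
#'
#' @param observer An `observer_profile`.
#' @param sf Spatial frequency of the grating (cycles per degree).
#' @param log10_contrast Log10 Michelson contrast shown.
#' @param seed Optional seed for a local draw stream; by default the current
#'   RNG stream is used.
#' @return Logical: correct response?
#' @export
respond <- function(observer, sf, log10_contrast, seed = NULL) {
  thr <- -log_sensitivity(observer$true_csf, sf)
  p <- weibull_prob(log10_contrast, thr, observer$slope, observer$guess,
                    observer$lapse, observer$target)
  draw <- function() stats::runif(1) < p
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate the three chart clicks of one run
#'
#' Applies the observer's chart bias to the true CSF — a fixed log-space
#' shift, the observer's stable effect, and fresh per-run noise — and returns
#' the clicks a noise-free adjuster would place for those perceived
#' parameters ([clicks_from_params]). With zero bias and zero noise the round
#' trip through [params_from_clicks] recovers the true CSF exactly (up to
#' chart-edge clipping).
#'
#' @param observer An `observer_profile`.
#' @param chart A [chart_spec].
#' @param run Run index (1-3); part of the noise stream's identity, so runs
#'   differ while remaining reproducible.
#' @param seed Master seed for the run noise.
#' @return A list with `click1`, `click2`, `click3`, `clipped`, and
#'   `perceived` (the chart-perceived [csf_params] before clipping).
#' @export
simulate_clicks <- function(observer, chart, run = 1, seed = 1) {
  eps <- withr::with_seed(
    derive_seed(seed, "clicks", observer$id, run),
    stats::rnorm(length(.param_family)) *
      vapply(observer$chart_bias, `[[`, numeric(1), "run_sd"))
  names(eps) <- names(observer$chart_bias)
  perceived <- vapply(stats::setNames(nm = names(.param_family)), function(p) {
    true_val <- observer$true_csf[[p]]
    if (true_val == 0) return(0)  # delta = 0 stays at 0
    true_val * exp(observer$chart_bias[[p]][["shift"]] +
                     observer$chart_eta[[p]] + eps[[p]])
  }, numeric(1))
  pars <- csf_params(perceived[["y_max"]], perceived[["f_max"]],
                     perceived[["beta"]], perceived[["delta"]])
  clicks <- clicks_from_params(pars, chart)
  clicks$perceived <- pars
  clicks
}
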