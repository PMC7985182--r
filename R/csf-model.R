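# Truncated log-parabola CSF model: evaluation, three-click parameterisation,
# least-squares fitting, point-by-point curve averaging and AUC.

#' Truncated log-parabola parameters
#'
#' Container for the four parameters of the truncated log-parabola contrast
#' sensitivity function: a log-parabola in log spatial frequency with a flat
#' plateau on the low-frequency side.
#'
#' @param y_max Peak linear contrast sensitivity (reciprocal of the Michelson
#'   contrast threshold at the peak); must be positive.
#' @param f_max Spatial frequency of the peak, cycles per degree; positive.
#' @param beta Full width at half maximum of the log-parabola, in octaves;
#'   positive.
#' @param delta Low-frequency truncation depth, in log10 sensitivity units
#'   (decades); non-negative. `delta = 0` truncates at the peak, large `delta`
#'   leaves the parabola untouched over any finite frequency range.
#' @return An object of class `csf_params`.
#' @export
#' @examples
#' p <- csf_params(y_max = 100, f_max = 2, beta = 2, delta = 0.5)
#' sensitivity(p, 2)
csf_params <- function(y_max, f_max, beta, delta) {
  vals <- c(y_max = y_max, f_max = f_max, beta = beta, delta = delta)
  if (any(!is.finite(vals))) {
    stop("csf_params: all parameters must be finite", call. = FALSE)
  }
  if (y_max <= 0 || f_max <= 0 || beta <= 0 || delta < 0) {
    stop("csf_params: need y_max > 0, f_max > 0, beta > 0, delta >= 0",
         call. = FALSE)
  }
  structure(as.list(vals), class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "CSF (truncated log-parabola): y_max = %.4g, f_max = %.4g cpd, beta = %.4g oct, delta = %.4g\n",
    x$y_max, x$f_max, x$beta, x$delta))
  invisible(x)
}

#' Log10 contrast sensitivity of a truncated log-parabola
#'
#' Evaluates the model in log10 units. The parabola branch is
#' `log10(y_max) - ((log10(sf) - log10(f_max)) / (beta * log10(2) / 2))^2`;
#' below the peak frequency, wherever the parabola falls under the plateau
#' `log10(y_max) - delta`, the plateau value is returned instead. The two
#' branches meet continuously at the crossover frequency.
#'
#' @param params A [csf_params] object.
#' @param sf Spatial frequency (cycles per degree), vectorised; must be > 0.
#' @return Log10 contrast sensitivity (decades), same length as `sf`.
#' @export
#' @examples
#' p <- csf_params(100, 2, 2, 0.5)
#' log_sensitivity(p, c(0.5, 2, 4))  # plateau, peak, one octave above
log_sensitivity <- function(params, sf) {
  stopifnot(inherits(params, "csf_params"))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("log_sensitivity: sf must be finite and positive", call. = FALSE)
  }
  lpeak <- log10(params$y_max)
  half_width <- params$beta * log10(2) / 2
  parab <- lpeak - ((log10(sf) - log10(params$f_max)) / half_width)^2
  plateau <- lpeak - params$delta
  ifelse(sf < params$f_max & parab < plateau, plateau, parab)
}

#' Linear contrast sensitivity
#'
#' Convenience wrapper: `10 ^ log_sensitivity(params, sf)`.
#'
#' @inheritParams log_sensitivity
#' @return Linear sensitivity (strictly positive), same length as `sf`.
#' @export
sensitivity <- function(params, sf) {
  10^log_sensitivity(params, sf)
}

#' CSF parameters from three chart clicks
#'
#' Maps three click positions on a Campbell-Robson chart to the four
#' truncated log-parabola parameters. Each click is a pair of fractions
#' `c(u, v)` with `u` the horizontal fraction (0 = left edge) and `v` the
#' vertical fraction measured from the *bottom* of the chart (0 = bottom row,
#' maximum contrast). The first click places the peak: `f_max` from the log
#' frequency axis and `y_max` as the reciprocal of the contrast at that
#' height. The second click, which must lie to the right of and below the
#' peak, sets `beta` as the unique width for which the right half-parabola
#' passes through that chart position. The third click's height sets the
#' plateau: `delta = log10(y_max) - log10(sensitivity at click 3)`, floored
#' at 0 (a third click above the peak is clamped to `delta = 0`).
#'
#' @param click1,click2,click3 Numeric pairs `c(u, v)` of chart fractions in
#'   `[0, 1]`.
#' @param chart A [chart_spec] object providing the log axis mappings.
#' @return A [csf_params] object.
#' @export
#' @examples
#' ch <- chart_spec()
#' params_from_clicks(c(0.5, 0.8), c(0.8, 0.4), c(0.5, 0.6), ch)
params_from_clicks <- function(click1, click2, click3, chart) {
  clicks <- list(click1, click2, click3)
  for (cl in clicks) {
    if (length(cl) != 2 || any(!is.finite(cl)) || any(cl < 0) || any(cl > 1)) {
      stop("params_from_clicks: clicks must be pairs of fractions in [0, 1]",
           call. = FALSE)
    }
  }
  f_max <- sf_at(chart, click1[1])
  y_max <- 1 / contrast_at(chart, click1[2])
  sf2 <- sf_at(chart, click2[1])
  s2 <- 1 / contrast_at(chart, click2[2])
  if (sf2 <= f_max) {
    stop("params_from_clicks: click 2 must lie at a frequency above f_max",
         call. = FALSE)
  }
  d <- log10(y_max) - log10(s2)
  if (d <= 0) {
    stop("params_from_clicks: click 2 must lie below the peak sensitivity",
         call. = FALSE)
  }
  beta <- 2 * (log10(sf2) - log10(f_max)) / (log10(2) * sqrt(d))
  s3 <- 1 / contrast_at(chart, click3[2])
  delta <- max(0, log10(y_max) - log10(s3))
  csf_params(y_max, f_max, beta, delta)
}

#' Chart clicks that encode a set of CSF parameters
#'
#' Inverse of [params_from_clicks]: computes the three click fractions a
#' noise-free adjuster would produce for the given parameters. Click 2 is
#' placed at the point where the right half-parabola has dropped one decade
#' below the peak (`sf = f_max * 2^(beta/2)`, sensitivity `y_max / 10`),
#' which makes the mapping invertible. Positions outside the chart are
#' clamped to its edges (with small safety margins so that a width click
#' remains placeable), so extreme parameters are censored at the chart range
#' rather than rejected; the `clipped` attribute reports whether any clamp
#' fired.
#'
#' @param params A [csf_params] object.
#' @param chart A [chart_spec] object.
#' @return A list with elements `click1`, `click2`, `click3` (fraction pairs)
#'   and `clipped` (logical).
#' @export
clicks_from_params <- function(params, chart) {
  stopifnot(inherits(params, "csf_params"))
  clipped <- FALSE
  clamp <- function(x, lo, hi) {
    y <- min(max(x, lo), hi)
    if (y != x) clipped <<- TRUE
    y
  }
  # click 1: the peak. Keep a right margin so click 2 fits, and a bottom
  # margin so the one-decade width point stays below the peak.
  u1 <- clamp(sf_frac(chart, params$f_max), 0, 0.99)
  v_floor <- contrast_frac(chart, 1 / 2.5)  # y_max >= 2.5
  v1 <- clamp(contrast_frac(chart, 1 / params$y_max), v_floor, 1)
  f_eff <- sf_at(chart, u1)
  y_eff <- 1 / contrast_at(chart, v1)
  # click 2: one decade below the peak on the right branch.
  sf2 <- f_eff * 2^(params$beta / 2)
  u2 <- clamp(sf_frac(chart, sf2), min(u1 + 0.005, 1), 1)
  s2 <- y_eff / 10
  v2 <- clamp(contrast_frac(chart, 1 / s2), 0, max(v1 - 0.005, 0))
  # click 3: the plateau height.
  s3 <- y_eff * 10^(-params$delta)
  v3 <- clamp(contrast_frac(chart, 1 / s3), 0, 1)
  u3 <- clamp(u1 / 2, 0, 1)
  list(click1 = c(u1, v1), click2 = c(u2, v2), click3 = c(u3, v3),
       clipped = clipped)
}

# Deterministic multi-start points for the bounded fit, in the transformed
# space (log10 y_max, log10 f_max, beta, delta).
.fit_starts <- function(sfs, log_sens, lower, upper) {
  data_start <- c(min(max(max(log_sens), log10(lower[1])), log10(upper[1])),
                  min(max(log10(sfs[which.max(log_sens)]), log10(lower[2])),
                      log10(upper[2])),
                  4, 0.5)
  grid <- as.matrix(expand.grid(ly = c(1.7, 2.7), lf = c(0.2, 0.8),
                                beta = c(2.5, 6)))
  starts <- rbind(data_start,
                  cbind(grid, delta = 0.6)[seq_len(7), , drop = FALSE])
  unname(starts)
}

#' Fit a truncated log-parabola to sensitivity data
#'
#' Bounded least squares on log10 sensitivities: minimises the sum of squared
#' differences between `log10(sensitivities)` and the model over
#' `y_max in [2, 5000]`, `f_max in [0.2, 20]` cpd, `beta in [0.5, 12]`
#' octaves and `delta in [0, 3]`. Eight deterministic multi-starts feed
#' `L-BFGS-B` (in a transformed space with `y_max` and `f_max` on log10
#' scales), and the best solution is polished with a bound-clamped
#' Nelder-Mead pass, so the fit is fully deterministic.
#'
#' @param sfs Spatial frequencies (cycles per degree), at least 4 points.
#' @param sensitivities Positive linear sensitivities, same length.
#' @param lower,upper Named parameter bounds in the order
#'   `y_max, f_max, beta, delta`.
#' @return An object of class `csf_fit`: a list with `params`
#'   ([csf_params]), `r_squared` (coefficient of determination on log10
#'   sensitivities), `residuals` (observed minus fitted log10 sensitivity),
#'   `sse`, and `degenerate` (`TRUE` when all sensitivities are equal, in
#'   which case `r_squared` is `NA` and the returned curve is flat at the
#'   common level).
#' @export
#' @examples
#' truth <- csf_params(294.33, 3.62, 5.13, 0.90)
#' sfs <- c(0.5, 0.99, 1.96, 3.87, 7.66, 15.16, 30)
#' fit <- fit_csf(sfs, sensitivity(truth, sfs))
#' fit$r_squared
fit_csf <- function(sfs, sensitivities,
                    lower = c(y_max = 2, f_max = 0.2, beta = 0.5, delta = 0),
                    upper = c(y_max = 5000, f_max = 20, beta = 12, delta = 3)) {
  if (length(sfs) < 4 || length(sensitivities) != length(sfs)) {
    stop("fit_csf: need >= 4 (sf, sensitivity) pairs", call. = FALSE)
  }
  if (any(sensitivities <= 0) || any(sfs <= 0)) {
    stop("fit_csf: frequencies and sensitivities must be positive",
         call. = FALSE)
  }
  y <- log10(sensitivities)

  if (max(y) - min(y) < .Machine$double.eps^0.5) {
    flat <- csf_params(min(max(10^y[1], lower[1]), upper[1]),
                       exp(mean(log(sfs))), mean(c(lower[3], upper[3])), 0)
    return(structure(list(params = flat, r_squared = NA_real_,
                          residuals = y - log_sensitivity(flat, sfs),
                          sse = sum((y - log_sensitivity(flat, sfs))^2),
                          degenerate = TRUE),
                     class = "csf_fit"))
  }

  lo <- c(log10(lower[1]), log10(lower[2]), lower[3], lower[4])
  hi <- c(log10(upper[1]), log10(upper[2]), upper[3], upper[4])
  to_params <- function(th) csf_params(10^th[1], 10^th[2], th[3], th[4])
  objective <- function(th) {
    th <- pmin(pmax(th, lo), hi)
    sum((y - log_sensitivity(to_params(th), sfs))^2)
  }

  starts <- .fit_starts(sfs, y, lower, upper)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lo), hi), objective,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  polish <- stats::optim(best$par, objective, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
  if (polish$value < best$value) best <- polish

  th <- pmin(pmax(best$par, lo), hi)
  params <- to_params(th)
  fitted <- log_sensitivity(params, sfs)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(params = params, r_squared = 1 - sse / sst,
                 residuals = y - fitted, sse = sse, degenerate = FALSE),
            class = "csf_fit")
}

#' @export
print.csf_fit <- function(x, ...) {
  cat(sprintf("Truncated log-parabola fit (R^2 = %.4f%s)\n",
              x$r_squared, if (x$degenerate) ", degenerate" else ""))
  print(x$params)
  invisible(x)
}

#' Point-by-point average of CSF curves
#'
#' Evaluates each curve's log10 sensitivity on a common frequency grid and
#' returns the per-point mean and standard deviation across curves.
#'
#' @param params_list Non-empty list of [csf_params] objects.
#' @param sf_grid Spatial frequency grid (cycles per degree), typically
#'   log-spaced.
#' @return A data frame with columns `sf`, `mean_log_sens`, `sd_log_sens`.
#' @export
average_curves <- function(params_list,
                           sf_grid = 10^seq(log10(0.5), log10(30),
                                            length.out = 100)) {
  if (length(params_list) == 0) {
    stop("average_curves: empty curve list", call. = FALSE)
  }
  mat <- vapply(params_list, log_sensitivity, numeric(length(sf_grid)),
                sf = sf_grid)
  mat <- matrix(mat, nrow = length(sf_grid))
  data.frame(
    sf = sf_grid,
    mean_log_sens = rowMeans(mat),
    sd_log_sens = if (ncol(mat) == 1) rep(0, length(sf_grid))
                  else apply(mat, 1, stats::sd))
}

#' Area under the log CSF
#'
#' Trapezoidal integral of `max(log_sensitivity, 0)` over log10 spatial
#' frequency on a fixed 256-point grid — the conventional area under the log
#' CSF above sensitivity 1.
#'
#' @param params A [csf_params] object.
#' @param sf_lo,sf_hi Integration limits in cycles per degree,
#'   `0 < sf_lo < sf_hi`.
#' @param n_grid Number of grid points (default 256).
#' @return The area, in decades times log10 cycles per degree.
#' @export
#' @examples
#' area_under_curve(csf_params(294.33, 3.62, 5.13, 0.90), 0.5, 30)
area_under_curve <- function(params, sf_lo, sf_hi, n_grid = 256) {
  if (!(sf_lo > 0 && sf_hi > sf_lo)) {
    stop("area_under_curve: need 0 < sf_lo < sf_hi", call. = FALSE)
  }
  x <- seq(log10(sf_lo), log10(sf_hi), length.out = n_grid)
  y <- pmax(log_sensitivity(params, 10^x), 0)
  sum(diff(x) * (y[-1] + y[-n_grid]) / 2)
}
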