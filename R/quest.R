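# QUEST Bayesian adaptive staircase and the seven-frequency session protocol
# for the gold-standard CSF measurement.

#' Weibull psychometric function in log10 contrast
#'
#' Probability of a correct response in a two-alternative orientation
#' judgement, as a function of log10 contrast:
#' `p = guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - threshold) + e)))`,
#' with the offset `e` chosen so that `p(threshold) = target`. Anchoring the
#' function at the target performance level makes the threshold returned by a
#' staircase targeting `target` coincide with the `threshold` parameter.
#'
#' @param x Log10 Michelson contrast (vectorised).
#' @param threshold Log10 contrast threshold (vectorised; recycled against
#'   `x`).
#' @param slope Weibull slope (default 3.5).
#' @param guess Guess rate (default 0.5, two alternatives).
#' @param lapse Lapse rate (default 0.01).
#' @param target Performance level that defines the threshold (default 0.82).
#' @return Probability of a correct response.
#' @export
#' @examples
#' weibull_prob(-2, threshold = -2)  # = 0.82 by construction
weibull_prob <- function(x, threshold, slope = 3.5, guess = 0.5,
                         lapse = 0.01, target = 0.82) {
  if (target <= guess || target >= 1 - lapse) {
    stop("weibull_prob: target must lie strictly between guess and 1 - lapse",
         call. = FALSE)
  }
  q <- (target - guess) / (1 - guess - lapse)
  e <- log10(-log(1 - q))
  guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - threshold) + e)))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Initialise a QUEST staircase
#'
#' Places a Gaussian prior over a grid of candidate log10-contrast thresholds.
#' The first recommended intensity is the prior mean (posterior-mean
#' placement, the QUEST mean variant).
#'
#' @param prior_mean Prior mean log10 contrast threshold (e.g. a
#'   ModelFest-style starting value).
#' @param prior_sd Prior standard deviation in decades (default 1).
#' @param grid_lo,grid_hi,grid_n Grid of candidate thresholds: default 400
#'   points on log10 contrast in `[-4, 0]`.
#' @inheritParams weibull_prob
#' @return An object of class `quest_state`.
#' @export
quest_init <- function(prior_mean, prior_sd = 1, grid_lo = -4, grid_hi = 0,
                       grid_n = 400, slope = 3.5, guess = 0.5, lapse = 0.01,
                       target = 0.82) {
  if (target <= guess || target >= 1 - lapse) {
    stop("quest_init: target must lie strictly between guess and 1 - lapse",
         call. = FALSE)
  }
  if (prior_sd <= 0) stop("quest_init: prior_sd must be positive", call. = FALSE)
  grid <- seq(grid_lo, grid_hi, length.out = grid_n)
  log_post <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  log_post <- log_post - .logsumexp(log_post)
  structure(list(grid = grid, log_post = log_post, slope = slope,
                 guess = guess, lapse = lapse, target = target,
                 n_trials = 0L),
            class = "quest_state")
}

#' Posterior-mean threshold estimate of a QUEST staircase
#'
#' @param state A `quest_state`.
#' @return Posterior mean log10 contrast threshold.
#' @export
quest_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  sum(state$grid * exp(state$log_post))
}

#' Next recommended test intensity
#'
#' The mean variant of QUEST tests at the current posterior mean of the
#' threshold.
#'
#' @param state A `quest_state`.
#' @return Recommended log10 contrast for the next trial.
#' @export
quest_next <- function(state) {
  quest_estimate(state)
}

#' Update a QUEST staircase with one trial
#'
#' Multiplies the posterior over candidate thresholds by the Weibull
#' likelihood of the observed response at the shown intensity. Updates
#' commute, so the posterior depends only on the set of (intensity, response)
#' pairs.
#'
#' @param state A `quest_state`.
#' @param intensity Log10 contrast shown on the trial (finite).
#' @param correct Logical: was the response correct?
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, intensity, correct) {
  stopifnot(inherits(state, "quest_state"))
  if (!is.finite(intensity)) {
    stop("quest_update: intensity must be finite", call. = FALSE)
  }
  p <- weibull_prob(intensity, state$grid, state$slope, state$guess,
                    state$lapse, state$target)
  state$log_post <- state$log_post + if (isTRUE(correct)) log(p) else log1p(-p)
  state$log_post <- state$log_post - .logsumexp(state$log_post)
  state$n_trials <- state$n_trials + 1L
  state
}

#' Default QUEST starting values
#'
#' Log10-contrast starting values for the seven test frequencies. The
#' published protocol seeds each staircase with group-average Gabor
#' thresholds; those exact numbers are not available, so the packaged default
#' is the adult group-mean truncated log-parabola evaluated at the seven
#' frequencies, rounded to 0.1 log units. They are plain configuration
#' inputs: pass your own vector to use different starts.
#'
#' @param sfs Test frequencies (cycles per degree).
#' @return Named numeric vector of log10 contrast starting values.
#' @export
default_start_values <- function(sfs = c(0.5, 0.99, 1.96, 3.87, 7.66, 15.16, 30)) {
  defaults <- c(-1.6, -1.9, -2.3, -2.5, -2.3, -1.8, -1.1)
  if (length(sfs) == 7) stats::setNames(defaults, sfs)
  else stats::setNames(rep(-2, length(sfs)), sfs)
}

#' Build the randomized session plan
#'
#' The default plan is 48 trials at each of the seven frequencies 0.5, 0.99,
#' 1.96, 3.87, 7.66, 15.16 and 30 cycles per degree — 336 trials in four
#' blocks of 84. Within each block every frequency appears equally often
#' (12 times by default) in randomized order, and each trial's orientation is
#' drawn equiprobably horizontal or vertical.
#'
#' @param sfs Test frequencies (cycles per degree).
#' @param trials_per_sf Trials per frequency (default 48); must be divisible
#'   by `n_blocks`.
#' @param n_blocks Number of blocks (default 4).
#' @param seed Seed for the order and orientation randomisation.
#' @return A data frame with columns `trial`, `block`, `sf`, `orientation`,
#'   of class `session_plan`.
#' @export
session_plan <- function(sfs = c(0.5, 0.99, 1.96, 3.87, 7.66, 15.16, 30),
                         trials_per_sf = 48, n_blocks = 4, seed = 1) {
  if (trials_per_sf %% n_blocks != 0) {
    stop("session_plan: trials_per_sf must be divisible by n_blocks",
         call. = FALSE)
  }
  per_block <- trials_per_sf / n_blocks
  plan <- withr::with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      order <- sample(rep(sfs, per_block))
      data.frame(block = b, sf = order,
                 orientation = sample(c("horizontal", "vertical"),
                                      length(order), replace = TRUE))
    })
    do.call(rbind, blocks)
  })
  plan <- cbind(trial = seq_len(nrow(plan)), plan)
  class(plan) <- c("session_plan", "data.frame")
  plan
}

#' Simulate one gold-standard QUEST session
#'
#' Runs one independent QUEST staircase per frequency, interleaved in the
#' plan's randomized order. On each trial the staircase for the trial's
#' frequency recommends an intensity (clipped to the displayable range), the
#' observer's response is drawn from its psychometric function, and the
#' staircase is updated. The final per-frequency estimates are the posterior
#' means.
#'
#' @param observer An `observer_profile` (see [sample_population]), or a
#'   function `(sf, log10_contrast) -> logical` giving the response directly
#'   (useful for deterministic test observers).
#' @param plan A [session_plan].
#' @param start_values Named vector of prior-mean log10 contrasts, one per
#'   frequency in the plan (default [default_start_values]).
#' @param prior_sd Prior SD in decades (default 1).
#' @param contrast_range Displayable contrast range; recommendations are
#'   clipped to it before presentation (default `c(1e-4, 0.5)`).
#' @param seed Seed for the response stream.
#' @param ... Passed to [quest_init] (grid and psychometric settings).
#' @return An object of class `session_result`: list with `estimates`
#'   (named log10-contrast thresholds per frequency), `sensitivities`
#'   (their reciprocals on the linear scale) and `trials` (the full trial
#'   log).
#' @export
run_session <- function(observer, plan = session_plan(),
                        start_values = default_start_values(unique(plan$sf)),
                        prior_sd = 1, contrast_range = c(1e-4, 0.5),
                        seed = 1, ...) {
  sfs <- sort(unique(plan$sf))
  if (is.null(names(start_values))) names(start_values) <- sfs
  states <- lapply(sfs, function(sf)
    quest_init(unname(start_values[as.character(sf)]), prior_sd = prior_sd, ...))
  names(states) <- as.character(sfs)

  answer <- if (is.function(observer)) {
    function(sf, x) observer(sf, x)
  } else {
    function(sf, x) respond(observer, sf, x)
  }

  log_contrast <- numeric(nrow(plan))
  correct <- logical(nrow(plan))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(plan))) {
      key <- as.character(plan$sf[i])
      x <- quest_next(states[[key]])
      x <- min(max(x, log10(contrast_range[1])), log10(contrast_range[2]))
      ok <- answer(plan$sf[i], x)
      states[[key]] <- quest_update(states[[key]], x, ok)
      log_contrast[i] <- x
      correct[i] <- ok
    }
  })

  estimates <- vapply(states, quest_estimate, numeric(1))
  trials <- cbind(plan, log10_contrast = log_contrast, correct = correct)
  structure(list(estimates = estimates,
                 sensitivities = 10^(-estimates),
                 trials = trials),
            class = "session_result")
}
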