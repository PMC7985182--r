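# End-to-end synthetic replication: generate populations, simulate QUEST
# sessions and chart runs, fit, exclude, summarise, compare, predict.

#' Study configuration
#'
#' Bundles every stage's settings. All stage seeds are derived from the
#' master seed with [derive_seed], so reruns are bit-for-bit reproducible and
#' stages have independent streams.
#'
#' @param n_adult,n_child Group sizes (defaults 96 and 74).
#' @param chart The [chart_spec] used for the chart runs.
#' @param n_chart_runs Number of three-click runs per observer (default 3).
#' @param sfs Gold-standard test frequencies.
#' @param trials_per_sf,n_blocks Session structure (defaults 48 and 4).
#' @param start_values QUEST prior means (log10 contrast) per frequency.
#' @param prior_sd QUEST prior SD (decades).
#' @param contrast_range Displayable contrast range for the staircase.
#' @param cv A [cv_config] for the prediction stage.
#' @param seed Master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_adult = 96, n_child = 74, chart = chart_spec(),
                         n_chart_runs = 3,
                         sfs = c(0.5, 0.99, 1.96, 3.87, 7.66, 15.16, 30),
                         trials_per_sf = 48, n_blocks = 4,
                         start_values = default_start_values(sfs),
                         prior_sd = 1, contrast_range = c(1e-4, 0.5),
                         cv = cv_config(), seed = 1) {
  structure(list(n_adult = n_adult, n_child = n_child, chart = chart,
                 n_chart_runs = n_chart_runs, sfs = sfs,
                 trials_per_sf = trials_per_sf, n_blocks = n_blocks,
                 start_values = start_values, prior_sd = prior_sd,
                 contrast_range = contrast_range, cv = cv, seed = seed),
            class = "study_config")
}

#' Validate a study configuration
#'
#' @param config A [study_config].
#' @return Character vector of problems; empty when the configuration is
#'   valid. Each entry names the offending field.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!inherits(config, "study_config")) {
    return("config: not a study_config object")
  }
  if (config$n_adult < 1) add("n_adult: must be >= 1")
  if (config$n_child < 1) add("n_child: must be >= 1")
  ch <- tryCatch({
    do.call(chart_spec, unclass(config$chart))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(ch)) add(paste0("chart: ", ch))
  if (config$trials_per_sf %% config$n_blocks != 0) {
    add("trials_per_sf: must be divisible by n_blocks")
  }
  if (any(config$sfs <= 0)) add("sfs: frequencies must be positive")
  if (length(config$start_values) != length(config$sfs)) {
    add("start_values: need one starting value per frequency")
  }
  if (!(config$contrast_range[1] > 0 &&
        config$contrast_range[2] > config$contrast_range[1] &&
        config$contrast_range[2] <= 1)) {
    add("contrast_range: need 0 < lo < hi <= 1")
  }
  if (length(config$cv$fwhm_grid) < 1) add("cv$fwhm_grid: empty width grid")
  if (config$n_chart_runs < 1) add("n_chart_runs: must be >= 1")
  problems
}

# One observer's contribution to the parameter table: a fitted quest row and
# n_chart_runs adjusted chart rows.
.observer_rows <- function(obs, config) {
  plan <- session_plan(config$sfs, config$trials_per_sf, config$n_blocks,
                       seed = derive_seed(config$seed, "plan", obs$id))
  session <- run_session(obs, plan, start_values = config$start_values,
                         prior_sd = config$prior_sd,
                         contrast_range = config$contrast_range,
                         seed = derive_seed(config$seed, "quest", obs$id),
                         slope = obs$slope, guess = obs$guess,
                         lapse = obs$lapse, target = obs$target)
  fit <- fit_csf(config$sfs, session$sensitivities)
  rows <- parameter_row(obs$id, obs$group, "quest", fit$params,
                        fit$r_squared)
  for (r in seq_len(config$n_chart_runs)) {
    clicks <- simulate_clicks(obs, config$chart, run = r,
                              seed = derive_seed(config$seed, "chart"))
    pars <- params_from_clicks(clicks$click1, clicks$click2, clicks$click3,
                               config$chart)
    rows <- rbind(rows, parameter_row(obs$id, obs$group,
                                      sprintf("chart_run%d", r), pars))
  }
  rows
}

#' Run the full synthetic study
#'
#' Executes the whole pipeline: sample adult and child populations, simulate
#' a gold-standard QUEST session and the three-click chart runs for every
#' observer, fit the truncated log-parabola to the QUEST estimates, apply the
#' exclusion rules, summarise the parameter table, run the paired
#' comparisons, AUC correlations and reliability, and (optionally) the full
#' nested-CV prediction grid. Every stage draws from a stream derived from
#' the master seed, so the same configuration always yields identical output.
#'
#' @param config A [study_config]; validated before anything runs.
#' @param with_prediction Run the (comparatively slow) prediction grid?
#'   Default `TRUE`.
#' @return An object of class `csf_study`: list with `table_raw`, `table`
#'   (post-exclusion), `exclusions`, `summary`, `comparisons`, `auc_cor`,
#'   `reliability`, `cv` (or `NULL`), `populations`, `config`.
#' @export
#' @examples
#' \donttest{
#' smoke <- run_study(study_config(n_adult = 5, n_child = 5,
#'                                 cv = cv_config(n_iterations = 2)),
#'                    with_prediction = FALSE)
#' smoke$summary
#' }
run_study <- function(config = study_config(), with_prediction = TRUE) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("run_study: invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  stage <- "generate"
  result <- tryCatch({
    pops <- list(
      adult = sample_population(population_spec(
        "adult", n = config$n_adult, chart = config$chart,
        seed = derive_seed(config$seed, "population", "adult"))),
      child = sample_population(population_spec(
        "child", n = config$n_child, chart = config$chart,
        seed = derive_seed(config$seed, "population", "child"))))

    stage <- "simulate"
    table_raw <- do.call(rbind, lapply(c(pops$adult, pops$child),
                                       .observer_rows, config = config))

    stage <- "exclude"
    excl <- apply_exclusions(table_raw)

    stage <- "stats"
    summary_tab <- summarize_params(excl$table)
    comparisons <- paired_comparisons(excl$table)
    auc_cor <- auc_correlations(excl$table)
    rel <- reliability(excl$table)

    cv <- NULL
    if (with_prediction) {
      stage <- "predict"
      cfg <- config$cv
      cfg$seed <- derive_seed(config$seed, "cv")
      cv <- run_matrix(excl$table, cfg)
    }

    list(table_raw = table_raw, table = excl$table,
         exclusions = excl$exclusions, summary = summary_tab,
         comparisons = comparisons, auc_cor = auc_cor, reliability = rel,
         cv = cv, populations = pops, config = config)
  }, error = function(e) {
    stop(sprintf("run_study: stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(result) <- "csf_study"
  result
}

#' @export
print.csf_study <- function(x, ...) {
  cat(sprintf("Synthetic CSF study: %d raw rows, %d observers excluded\n",
              nrow(x$table_raw), length(unique(x$exclusions$observer_id))))
  print(x$summary)
  invisible(x)
}
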