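# Nested cross-validated Gaussian-kernel support-vector regression of the
# gold-standard CSF parameters from the chart-adjusted parameters, with a
# permutation null.

#' Cross-validation configuration
#'
#' @param n_iterations Outer iterations (default 100).
#' @param outer_divisor Outer test-set size rule: `floor(n / outer_divisor)`
#'   observations (default 6, i.e. 16 of 96 adults, 12 of 74 children).
#' @param inner_folds Inner folds for model selection (default 5).
#' @param fwhm_grid Gaussian-kernel FWHM grid (default 0.1 to 5 in steps of
#'   0.1 — 50 candidate widths).
#' @param cost,epsilon Fixed SVR hyperparameters (`C = 1`,
#'   epsilon-insensitive loss width 0.1); only the kernel width is selected.
#' @param r2_method Test-set R^2 definition: `"one_minus_sse_sst"`
#'   (`1 - SSE/SST`, may be negative; default) or `"squared_cor"`.
#' @param seed Master seed; per-iteration split and permutation streams are
#'   derived from it.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 100, outer_divisor = 6, inner_folds = 5,
                      fwhm_grid = seq(0.1, 5, by = 0.1), cost = 1,
                      epsilon = 0.1,
                      r2_method = c("one_minus_sse_sst", "squared_cor"),
                      seed = 1) {
  r2_method <- match.arg(r2_method)
  if (any(fwhm_grid <= 0)) {
    stop("cv_config: kernel widths must be positive", call. = FALSE)
  }
  structure(list(n_iterations = n_iterations, outer_divisor = outer_divisor,
                 inner_folds = inner_folds, fwhm_grid = fwhm_grid,
                 cost = cost, epsilon = epsilon, r2_method = r2_method,
                 seed = seed),
            class = "cv_config")
}

# FWHM of the Gaussian kernel -> e1071 gamma (kernel exp(-gamma |u - v|^2)).
.fwhm_to_gamma <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  1 / (2 * sigma^2)
}

.standardize <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Nested cross-validated SVR prediction
#'
#' One iteration: the data are split into an outer test set of
#' `floor(n / outer_divisor)` random observations and a training set; the
#' training set is split evenly into `inner_folds` folds; for every candidate
#' kernel FWHM and every fold an epsilon-SVR is trained on the remaining
#' folds and scored by RMSE on the held-out fold; the single fold-model with
#' the globally lowest inner RMSE (ties broken towards the smallest width,
#' then the lowest fold) is applied unchanged to the outer test set, and the
#' test RMSE and R^2 are recorded. Features and targets are z-scored with
#' outer-training statistics only, so RMSE is in target-SD units and no
#' test-set information leaks into standardisation, training or selection.
#' Deterministic given `config$seed`.
#'
#' @param features Numeric matrix (observers x predictors).
#' @param targets Numeric vector, one value per observer.
#' @param config A [cv_config].
#' @param permute Re-pair targets with random observers each iteration
#'   (permutation null)?
#' @param perm `"shuffle"` (default) draws a fresh random permutation per
#'   iteration; `"identity"` applies the identity permutation, which
#'   reproduces the unpermuted analysis exactly under the same seed (the
#'   permutation stream is separate from the split stream).
#' @return An object of class `cv_report`: list with `results` (one row per
#'   iteration: chosen width, inner RMSE, test RMSE, test R^2, test indices),
#'   `summary` (means and SDs), `permuted`, `config`.
#' @export
nested_cv <- function(features, targets, config = cv_config(),
                      permute = FALSE, perm = c("shuffle", "identity")) {
  perm <- match.arg(perm)
  x <- as.matrix(features)
  y <- as.numeric(targets)
  n <- nrow(x)
  if (length(y) != n || anyNA(x) || anyNA(y)) {
    stop("nested_cv: features/targets must be complete and conformable",
         call. = FALSE)
  }
  test_n <- floor(n / config$outer_divisor)
  if (test_n < 2) {
    stop("nested_cv: outer test set would have fewer than 2 observations",
         call. = FALSE)
  }
  degenerate <- stats::sd(y) == 0
  if (degenerate) {
    warning("nested_cv: zero-variance targets; report flagged degenerate")
    results <- data.frame(iteration = seq_len(config$n_iterations),
                          fwhm = NA_real_, fold = NA_integer_,
                          inner_rmse = NA_real_, rmse = NA_real_,
                          r2 = NA_real_)
    return(structure(list(
      results = results, test_sets = vector("list", config$n_iterations),
      summary = c(mean_rmse = NA_real_, sd_rmse = NA_real_,
                  mean_r2 = NA_real_, sd_r2 = NA_real_),
      permuted = permute, degenerate = TRUE, config = config),
      class = "cv_report"))
  }

  rows <- vector("list", config$n_iterations)
  test_sets <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    y_it <- if (permute) {
      p <- if (perm == "shuffle") {
        withr::with_seed(derive_seed(config$seed, "perm", it), sample(n))
      } else {
        seq_len(n)
      }
      y[p]
    } else {
      y
    }
    split <- withr::with_seed(derive_seed(config$seed, "split", it), {
      idx <- sample(n)
      list(test = idx[seq_len(test_n)], train = idx[-seq_len(test_n)])
    })
    train <- split$train
    fold_id <- rep(seq_len(config$inner_folds), length.out = length(train))

    ctr <- colMeans(x[train, , drop = FALSE])
    scl <- apply(x[train, , drop = FALSE], 2, stats::sd)
    zx <- .standardize(x, ctr, scl)
    my <- mean(y_it[train])
    sy <- stats::sd(y_it[train])
    if (sy == 0) sy <- 1
    zy <- (y_it - my) / sy

    best <- list(rmse = Inf, model = NULL, fwhm = NA_real_, fold = NA_integer_)
    for (w in config$fwhm_grid) {
      gamma <- .fwhm_to_gamma(w)
      for (f in seq_len(config$inner_folds)) {
        tr <- train[fold_id != f]
        va <- train[fold_id == f]
        fit <- e1071::svm(zx[tr, , drop = FALSE], zy[tr],
                          type = "eps-regression", kernel = "radial",
                          gamma = gamma, cost = config$cost,
                          epsilon = config$epsilon, scale = FALSE)
        pred <- stats::predict(fit, zx[va, , drop = FALSE])
        rmse <- sqrt(mean((pred - zy[va])^2))
        if (rmse < best$rmse) {
          best <- list(rmse = rmse, model = fit, fwhm = w, fold = f)
        }
      }
    }

    pt <- stats::predict(best$model, zx[split$test, , drop = FALSE])
    zt <- zy[split$test]
    sse <- sum((pt - zt)^2)
    r2 <- if (config$r2_method == "one_minus_sse_sst") {
      1 - sse / sum((zt - mean(zt))^2)
    } else {
      stats::cor(pt, zt)^2
    }
    rows[[it]] <- data.frame(iteration = it, fwhm = best$fwhm,
                             fold = best$fold, inner_rmse = best$rmse,
                             rmse = sqrt(mean((pt - zt)^2)), r2 = r2)
    test_sets[[it]] <- split$test
  }
  results <- do.call(rbind, rows)
  structure(list(
    results = results,
    test_sets = test_sets,
    summary = c(mean_rmse = mean(results$rmse), sd_rmse = stats::sd(results$rmse),
                mean_r2 = mean(results$r2), sd_r2 = stats::sd(results$r2)),
    permuted = permute, degenerate = degenerate, config = config),
    class = "cv_report")
}

#' Permutation-null counterpart of [nested_cv]
#'
#' Identical procedure after randomly re-pairing predictors and targets
#' across observers on each iteration, estimating chance-level performance.
#'
#' @inheritParams nested_cv
#' @return A `cv_report` with `permuted = TRUE`.
#' @export
permutation_null <- function(features, targets, config = cv_config(),
                             perm = c("shuffle", "identity")) {
  nested_cv(features, targets, config, permute = TRUE, perm = match.arg(perm))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Nested-CV report (%d iterations%s): mean test RMSE %.3f (SD %.3f), mean test R^2 %.3f (SD %.3f)\n",
    nrow(x$results), if (x$permuted) ", permuted" else "",
    x$summary["mean_rmse"], x$summary["sd_rmse"],
    x$summary["mean_r2"], x$summary["sd_r2"]))
  invisible(x)
}

# Feature matrix from the chart rows of a parameter table: 4 columns per
# included run.
.chart_features <- function(table, group, runs_included, ids) {
  cols <- list()
  for (k in seq_len(runs_included)) {
    src <- sprintf("chart_run%d", k)
    rows <- table[table$group == group & table$source == src, ]
    rows <- rows[match(ids, rows$observer_id), ]
    for (p in .param_cols) {
      cols[[sprintf("%s_run%d", p, k)]] <- rows[[p]]
    }
  }
  as.matrix(as.data.frame(cols))
}

#' Full prediction grid
#'
#' Runs [nested_cv] and [permutation_null] for every combination of group,
#' gold-standard target parameter and number of chart runs included as
#' predictors (cumulative: run 1, runs 1-2, runs 1-3) — 2 x 4 x 3 x 2 = 48
#' report cells with the default two-group table.
#'
#' @param table Filtered parameter table (both sources present).
#' @param config A [cv_config]; each cell derives its own seed from
#'   `config$seed` and the cell labels.
#' @param runs Cumulative run counts to include (default `1:3`).
#' @param targets Gold-standard parameters to predict (default all four).
#' @return A list with `cells` (named list of `cv_report`s) and `long`
#'   (per-iteration long data frame: group, target, runs_included, permuted,
#'   iteration, fwhm, rmse, r2).
#' @export
run_matrix <- function(table, config = cv_config(), runs = 1:3,
                       targets = .param_cols) {
  cells <- list()
  long <- list()
  for (g in unique(table$group)) {
    quest <- table[table$group == g & table$source == "quest", ]
    run_srcs <- unique(table$source[grepl("^chart_run", table$source) &
                                      table$group == g])
    ids <- quest$observer_id
    for (src in run_srcs) {
      ids <- intersect(ids,
                       table$observer_id[table$source == src &
                                           table$group == g])
    }
    quest <- quest[match(ids, quest$observer_id), ]
    for (k in runs) {
      feats <- .chart_features(table, g, k, ids)
      for (tg in targets) {
        yy <- quest[[tg]]
        for (perm_flag in c(FALSE, TRUE)) {
          cfg <- config
          cfg$seed <- derive_seed(config$seed, g, tg, k, perm_flag)
          rep <- nested_cv(feats, yy, cfg, permute = perm_flag)
          key <- sprintf("%s.%s.runs%d.%s", g, tg, k,
                         if (perm_flag) "permuted" else "real")
          cells[[key]] <- rep
          long[[key]] <- cbind(group = g, target = tg, runs_included = k,
                               permuted = perm_flag, rep$results)
        }
      }
    }
  }
  list(cells = cells, long = do.call(rbind, c(long, make.row.names = FALSE)))
}
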