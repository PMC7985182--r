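# Descriptive and inferential statistics on the fitted parameter table:
# exclusions, group summaries, paired chart-vs-gold-standard comparisons,
# AUC correlations and inter-run reliability.

.param_cols <- c("beta", "delta", "f_max", "y_max")

#' Assemble a parameter table row
#'
#' Long-format row set used by all group-level statistics: one `quest` row
#' (fitted gold-standard parameters plus fit R^2) and up to three
#' `chart_run1..3` rows (adjusted parameters) per observer.
#'
#' @param observer_id,group,source Row keys; `source` is `"quest"` or
#'   `"chart_run1"`, `"chart_run2"`, `"chart_run3"`.
#' @param params A [csf_params].
#' @param r_squared Fit R^2 (NA for chart rows).
#' @return One-row data frame.
#' @export
parameter_row <- function(observer_id, group, source, params,
                          r_squared = NA_real_) {
  data.frame(observer_id = observer_id, group = group, source = source,
             beta = params$beta, delta = params$delta, f_max = params$f_max,
             y_max = params$y_max, r_squared = r_squared,
             stringsAsFactors = FALSE)
}

#' Apply the study's exclusion rules
#'
#' Two deterministic passes: first, observers whose gold-standard fit has
#' `r_squared < 0.5` are dropped entirely (reason `low_r2`); second, z-scores
#' are computed for every parameter within each group x source cell on the
#' post-filter sample, and observers with any `|z| > 3` are dropped (reason
#' `outlier`). A zero within-cell SD yields z = 0 (no exclusion).
#'
#' @param table Parameter table (rows as built by [parameter_row]).
#' @param z_cut Outlier cut-off (default 3).
#' @return A list with `table` (the filtered rows) and `exclusions`
#'   (data frame of `observer_id`, `reason`).
#' @export
apply_exclusions <- function(table, z_cut = 3) {
  stopifnot(all(c("observer_id", "group", "source", .param_cols) %in%
                  names(table)))
  quest <- table[table$source == "quest", ]
  low <- unique(quest$observer_id[!is.na(quest$r_squared) &
                                    quest$r_squared < 0.5])
  tab <- table[!(table$observer_id %in% low), ]

  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  bad <- character(0)
  for (cell in split(tab, list(tab$group, tab$source), drop = TRUE)) {
    z <- vapply(.param_cols, function(p) zscore(cell[[p]]),
                numeric(nrow(cell)))
    z <- matrix(z, nrow = nrow(cell))
    hit <- apply(abs(z) > z_cut, 1, any)
    bad <- union(bad, cell$observer_id[hit])
  }
  out <- tab[!(tab$observer_id %in% bad), ]
  if (nrow(out) == 0) {
    stop("apply_exclusions: no observers remain after filtering",
         call. = FALSE)
  }
  exclusions <- rbind(
    if (length(low)) data.frame(observer_id = low, reason = "low_r2"),
    if (length(bad)) data.frame(observer_id = bad, reason = "outlier"))
  if (is.null(exclusions)) {
    exclusions <- data.frame(observer_id = character(0),
                             reason = character(0))
  }
  list(table = out, exclusions = exclusions)
}

#' Group x source summary of the parameter table
#'
#' @param table Filtered parameter table.
#' @return Long data frame with `group`, `source`, `parameter`, `mean`, `sd`,
#'   `n`.
#' @export
summarize_params <- function(table) {
  cells <- split(table, list(table$group, table$source), drop = TRUE)
  do.call(rbind, lapply(cells, function(cell) {
    data.frame(group = cell$group[1], source = cell$source[1],
               parameter = .param_cols,
               mean = vapply(.param_cols, function(p) mean(cell[[p]]),
                             numeric(1)),
               sd = vapply(.param_cols, function(p) stats::sd(cell[[p]]),
                           numeric(1)),
               n = nrow(cell), row.names = NULL)
  }))
}

# chart value per observer: across-run mean of a parameter (or of a derived
# quantity via `fun`).
.chart_means <- function(table, fun) {
  chart <- table[grepl("^chart_run", table$source), ]
  vals <- fun(chart)
  tapply(vals, chart$observer_id, mean)
}

#' Paired chart-versus-gold-standard comparisons
#'
#' For each group and each parameter, a two-sided paired t test of the
#' across-run chart mean against the gold-standard value, plus the same test
#' on log10 sensitivity at the lowest tested frequency (0.5 cpd by default,
#' where the truncation makes `delta` itself hard to interpret), and the
#' method x group interaction F test — a one-way ANOVA of the per-observer
#' method difference scores on group, the between-subjects equivalent of the
#' mixed-design interaction.
#'
#' @param table Filtered parameter table containing both groups (the
#'   interaction test needs two) or one.
#' @param sf_low Frequency for the sensitivity comparison (default 0.5 cpd).
#' @return A list with `paired` (group, measure, n, mean_diff, t, df, p,
#'   degenerate) and `interaction` (measure, F, df1, df2, p). Zero-variance
#'   difference scores are flagged `degenerate` with `t = NA`.
#' @export
paired_comparisons <- function(table, sf_low = 0.5) {
  measures <- c(.param_cols, "log_sens_low_sf")
  value_of <- function(rows, measure) {
    if (measure == "log_sens_low_sf") {
      vapply(seq_len(nrow(rows)), function(i)
        log_sensitivity(csf_params(rows$y_max[i], rows$f_max[i],
                                   rows$beta[i], rows$delta[i]), sf_low),
        numeric(1))
    } else {
      rows[[measure]]
    }
  }

  paired <- list()
  diffs_all <- list()
  for (g in unique(table$group)) {
    tab_g <- table[table$group == g, ]
    quest <- tab_g[tab_g$source == "quest", ]
    chart <- tab_g[grepl("^chart_run", tab_g$source), ]
    ids <- intersect(quest$observer_id, unique(chart$observer_id))
    if (length(ids) < 3) {
      stop("paired_comparisons: need at least 3 paired observers",
           call. = FALSE)
    }
    quest <- quest[match(ids, quest$observer_id), ]
    for (m in measures) {
      chart_vals <- tapply(value_of(chart, m), chart$observer_id, mean)[ids]
      d <- chart_vals - value_of(quest, m)
      degenerate <- stats::sd(d) == 0
      if (degenerate && all(d == 0)) {
        # identical paired samples: no difference at all
        degenerate <- FALSE
        tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
      } else if (degenerate) {
        # constant nonzero differences: t would be infinite
        tt <- list(statistic = NA_real_, parameter = length(d) - 1,
                   p.value = NA_real_)
      } else {
        tt <- stats::t.test(chart_vals, value_of(quest, m), paired = TRUE)
      }
      paired[[length(paired) + 1]] <- data.frame(
        group = g, measure = m, n = length(d), mean_diff = mean(d),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, degenerate = degenerate)
      diffs_all[[length(diffs_all) + 1]] <- data.frame(group = g, measure = m,
                                                       diff = as.numeric(d))
    }
  }

  interaction <- NULL
  diffs <- do.call(rbind, diffs_all)
  if (length(unique(table$group)) == 2) {
    interaction <- do.call(rbind, lapply(measures, function(m) {
      d <- diffs[diffs$measure == m, ]
      within_sd <- tapply(d$diff, d$group, stats::sd)
      if (all(within_sd == 0)) {
        # constant difference scores within every group: F undefined
        return(data.frame(measure = m, F = NA_real_, df1 = 1,
                          df2 = nrow(d) - 2, p = NA_real_))
      }
      an <- stats::anova(stats::lm(diff ~ group, data = d))
      data.frame(measure = m, F = an$`F value`[1], df1 = an$Df[1],
                 df2 = an$Df[2], p = an$`Pr(>F)`[1])
    }))
  }
  list(paired = do.call(rbind, paired), interaction = interaction)
}

#' Correlations between gold-standard AUC and chart peak parameters
#'
#' Pearson correlation (with two-sided p) of each observer's area under the
#' gold-standard log CSF against the chart-adjusted `f_max` and `y_max` of
#' each run.
#'
#' @param table Filtered parameter table.
#' @param sf_range Integration range for the AUC (default `c(0.5, 30)` cpd).
#' @return Data frame with `group`, `run`, `parameter`, `r`, `p`, `n`.
#' @export
auc_correlations <- function(table, sf_range = c(0.5, 30)) {
  out <- list()
  for (g in unique(table$group)) {
    tab_g <- table[table$group == g, ]
    quest <- tab_g[tab_g$source == "quest", ]
    auc <- vapply(seq_len(nrow(quest)), function(i)
      area_under_curve(csf_params(quest$y_max[i], quest$f_max[i],
                                  quest$beta[i], quest$delta[i]),
                       sf_range[1], sf_range[2]), numeric(1))
    names(auc) <- quest$observer_id
    runs <- sort(unique(tab_g$source[grepl("^chart_run", tab_g$source)]))
    for (src in runs) {
      chart <- tab_g[tab_g$source == src, ]
      ids <- intersect(names(auc), chart$observer_id)
      chart <- chart[match(ids, chart$observer_id), ]
      for (p in c("f_max", "y_max")) {
        ct <- stats::cor.test(auc[ids], chart[[p]])
        out[[length(out) + 1]] <- data.frame(
          group = g, run = as.integer(sub("chart_run", "", src)),
          parameter = p, r = unname(ct$estimate), p = ct$p.value,
          n = length(ids))
      }
    }
  }
  do.call(rbind, out)
}

#' Inter-run reliability of the chart adjustments
#'
#' Pearson correlation of each chart parameter between every pair of runs,
#' within group.
#'
#' @param table Filtered parameter table with three chart runs.
#' @return Data frame with `group`, `parameter`, `run_a`, `run_b`, `r`, `n`.
#' @export
reliability <- function(table) {
  out <- list()
  for (g in unique(table$group)) {
    tab_g <- table[table$group == g, ]
    runs <- sort(unique(tab_g$source[grepl("^chart_run", tab_g$source)]))
    pairs <- utils::combn(runs, 2, simplify = FALSE)
    for (pr in pairs) {
      a <- tab_g[tab_g$source == pr[1], ]
      b <- tab_g[tab_g$source == pr[2], ]
      ids <- intersect(a$observer_id, b$observer_id)
      a <- a[match(ids, a$observer_id), ]
      b <- b[match(ids, b$observer_id), ]
      for (p in .param_cols) {
        r <- if (stats::sd(a[[p]]) == 0 || stats::sd(b[[p]]) == 0) {
          NA_real_  # correlation undefined for a constant run
        } else {
          stats::cor(a[[p]], b[[p]])
        }
        out[[length(out) + 1]] <- data.frame(
          group = g, parameter = p,
          run_a = as.integer(sub("chart_run", "", pr[1])),
          run_b = as.integer(sub("chart_run", "", pr[2])),
          r = r, n = length(ids))
      }
    }
  }
  do.call(rbind, out)
}
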