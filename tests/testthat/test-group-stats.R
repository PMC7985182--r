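test_that("exclusion rules drop low-R2 fits then outliers, with a log", {
  tab <- toy_table(10)
  tab$r_squared[tab$observer_id == "adult_004" & tab$source == "quest"] <- 0.4
  res <- apply_exclusions(tab)
  expect_equal(length(unique(res$table$observer_id)), 9)
  expect_equal(res$exclusions$reason[res$exclusions$observer_id == "adult_004"],
               "low_r2")
  # a gross outlier in one parameter is excluded (n must exceed ~10 for a
  # single point to reach |z| > 3: the one-outlier maximum is (n-1)/sqrt(n))
  tab2 <- toy_table(15)
  i <- tab2$observer_id == "adult_007" & tab2$source == "quest"
  tab2$y_max[i] <- 1e5
  res2 <- apply_exclusions(tab2)
  expect_false("adult_007" %in% res2$table$observer_id)
  expect_equal(res2$exclusions$reason, "outlier")
  # identical rows: zero SD means z = 0, nobody excluded
  tab3 <- toy_table(6, quest_fun = function(i) csf_params(200, 3, 5, 0.5),
                    chart_fun = function(i, r) csf_params(400, 2, 3, 0.8))
  res3 <- apply_exclusions(tab3)
  expect_equal(nrow(res3$exclusions), 0)
  expect_equal(nrow(res3$table), nrow(tab3))
  # z-scores are computed on the post-R2-filter sample: an outlier relative
  # to the filtered group is caught even if the dropped row masked it
  expect_error(apply_exclusions(toy_table(2, r_squared = function(i) 0.1)),
               "no observers remain")
})

test_that("summaries match hand computation", {
  tab <- toy_table(2, quest_fun = function(i) csf_params(c(100, 300)[i], 3, 5, 0.5),
                   chart_fun = function(i, r) csf_params(400, 2, 3, 0.8))
  s <- summarize_params(tab)
  q <- s[s$source == "quest" & s$parameter == "y_max", ]
  expect_equal(q$mean, 200)
  expect_equal(q$sd, stats::sd(c(100, 300)))
  ch <- s[s$source == "chart_run1" & s$parameter == "y_max", ]
  expect_equal(ch$sd, 0)
})

test_that("paired t statistics match the textbook formula on a fixture", {
  # printed 6-pair fixture: chart mean-of-runs y_max vs quest y_max
  quest_y <- c(210, 180, 330, 260, 150, 290)
  chart_y <- c(520, 410, 660, 500, 380, 590)
  tab <- toy_table(6,
    quest_fun = function(i) csf_params(quest_y[i], 3 + 0.1 * i, 5, 0.5 + 0.01 * i),
    chart_fun = function(i, r) csf_params(chart_y[i] + 3 * r, 2 + 0.1 * i,
                                          3, 0.8 + 0.01 * i))
  res <- paired_comparisons(tab)
  row <- res$paired[res$paired$measure == "y_max", ]
  d <- (chart_y + 6) - quest_y  # mean over runs adds mean(3 * (1:3)) = 6
  t_manual <- mean(d) / (stats::sd(d) / sqrt(6))
  expect_equal(row$t, t_manual, tolerance = 1e-10)
  expect_equal(row$df, 5)
  expect_equal(row$p, 2 * stats::pt(-abs(t_manual), 5), tolerance = 1e-10)
  expect_equal(row$mean_diff, mean(d))
  # identical paired samples give t = 0
  same <- toy_table(4, quest_fun = function(i) csf_params(100 + i, 3, 5, 0.5),
                    chart_fun = function(i, r) csf_params(100 + i, 3, 5, 0.5))
  res0 <- paired_comparisons(same)
  expect_equal(res0$paired$t[res0$paired$measure == "y_max"], 0)
  # constant nonzero differences are degenerate, flagged rather than infinite
  const <- toy_table(4, quest_fun = function(i) csf_params(100 + i, 3, 5, 0.5),
                     chart_fun = function(i, r) csf_params(200 + i, 3, 5, 0.5))
  resc <- paired_comparisons(const)
  rowc <- resc$paired[resc$paired$measure == "y_max", ]
  expect_true(rowc$degenerate)
  expect_true(is.na(rowc$t))
  expect_error(paired_comparisons(toy_table(2)), "at least 3")
})

test_that("the method-by-group interaction matches a brute-force ANOVA", {
  quest_y <- c(210, 180, 330, 260, 150, 290)
  chart_y <- c(520, 410, 660, 500, 380, 590)
  mk <- function(g, shift) toy_table(6, group = g,
    quest_fun = function(i) csf_params(quest_y[i] + shift, 3 + 0.1 * i, 5, 0.5),
    chart_fun = function(i, r) csf_params(chart_y[i], 2 + 0.1 * i, 3, 0.8))
  tab <- rbind(mk("adult", 0), mk("child", 40))
  res <- paired_comparisons(tab)
  irow <- res$interaction[res$interaction$measure == "y_max", ]
  d_adult <- chart_y - quest_y
  d_child <- chart_y - (quest_y + 40)
  d <- c(d_adult, d_child)
  grp <- rep(c(0, 1), each = 6)
  ssb <- 6 * (mean(d_adult) - mean(d))^2 + 6 * (mean(d_child) - mean(d))^2
  ssw <- sum((d_adult - mean(d_adult))^2) + sum((d_child - mean(d_child))^2)
  f_manual <- (ssb / 1) / (ssw / 10)
  expect_equal(irow$F, f_manual, tolerance = 1e-10)
  expect_equal(irow$df1, 1)
  expect_equal(irow$df2, 10)
  expect_equal(irow$p, stats::pf(f_manual, 1, 10, lower.tail = FALSE),
               tolerance = 1e-10)
  # low-frequency sensitivity comparison is reported alongside the parameters
  expect_true("log_sens_low_sf" %in% res$paired$measure)
})

test_that("AUC correlations recover collinear structure", {
  quest_pars <- lapply(1:8, function(i) csf_params(150 + 20 * i, 3, 5, 0.5))
  aucs <- vapply(quest_pars, area_under_curve, numeric(1), 0.5, 30)
  tab <- toy_table(8,
    quest_fun = function(i) quest_pars[[i]],
    chart_fun = function(i, r) csf_params(100 * aucs[i], 10 - aucs[i], 3, 0.8))
  res <- auc_correlations(tab)
  expect_equal(res$r[res$parameter == "y_max"], rep(1, 3), tolerance = 1e-10)
  expect_equal(res$r[res$parameter == "f_max"], rep(-1, 3), tolerance = 1e-10)
  expect_true(all(res$p[res$parameter == "y_max"] < 1e-6))
})

test_that("inter-run reliability is a plain Pearson correlation per pair", {
  tab <- toy_table(8, chart_fun = function(i, r) csf_params(
    400 + 10 * i, 2 + 0.1 * i, 3 + 0.05 * i, 0.8 + 0.02 * i))
  rel <- reliability(tab)
  expect_equal(nrow(rel), 12)  # 4 parameters x 3 run pairs
  expect_true(all(abs(rel$r - 1) < 1e-12))  # identical runs correlate fully
  tab2 <- toy_table(5, chart_fun = function(i, r)
    csf_params(c(400, 500, 450, 520, 410)[i] + c(0, 7, -3)[r] * i,
               2 + 0.1 * i, 3, 0.8))
  rel2 <- reliability(tab2)
  y12 <- rel2[rel2$parameter == "y_max" & rel2$run_a == 1 & rel2$run_b == 2, ]
  a <- c(400, 500, 450, 520, 410) + 0 * (1:5)
  b <- c(400, 500, 450, 520, 410) + 7 * (1:5)
  expect_equal(y12$r, stats::cor(a, b), tolerance = 1e-12)
})
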