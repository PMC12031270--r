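noiseless_records <- function(intercepts, slope, feature, n_per_group = 30) {
  tp <- seq(0, 540, length.out = n_per_group)
  rec <- data.frame(group = rep(c("control", "treated"), each = n_per_group),
                    time_min = rep(tp, 2))
  rec[[feature]] <- intercepts[rec$group] + slope * rec$time_min
  rec
}

test_that("noiseless lines are recovered to at least six significant digits", {
  rec <- noiseless_records(c(control = 1.280, treated = 0.885), 0.00125,
                           "beta_yi")
  fit <- fit_group_lines(rec, "beta_yi")
  expect_equal(fit$intercepts[["control"]], 1.280, tolerance = 1e-9)
  expect_equal(fit$intercepts[["treated"]], 0.885, tolerance = 1e-9)
  expect_equal(fit$slope, 0.00125, tolerance = 1e-9)
  expect_equal(fit$r2_adj_pct, 100, tolerance = 1e-9)

  rec2 <- noiseless_records(c(control = 2.380, treated = 1.721), 0.00076,
                            "beta_bi")
  fit2 <- fit_group_lines(rec2, "beta_bi")
  expect_equal(fit2$intercepts[["control"]], 2.380, tolerance = 1e-9)
  expect_equal(fit2$intercepts[["treated"]], 1.721, tolerance = 1e-9)
  expect_equal(fit2$slope, 0.00076, tolerance = 1e-9)
})

test_that("identical groups rarely show an intercept difference", {
  set.seed(11)
  hits <- vapply(1:100, function(i) {
    rec <- data.frame(group = rep(c("control", "treated"), each = 40),
                      time_min = rep(seq(0, 540, length.out = 40), 2))
    rec$beta_yi <- 1.2 + 0.001 * rec$time_min + rnorm(80, 0, 0.2)
    fit_group_lines(rec, "beta_yi")$intercept_diff_p <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.12)
})

test_that("the slope-equality F-test holds its nominal size on parallel data", {
  set.seed(12)
  rej <- vapply(1:200, function(i) {
    rec <- data.frame(group = rep(c("control", "treated"), each = 40),
                      time_min = rep(seq(0, 540, length.out = 40), 2))
    rec$beta_yi <- ifelse(rec$group == "control", 1.28, 0.885) +
      0.00125 * rec$time_min + rnorm(80, 0, 0.18)
    fit_group_lines(rec, "beta_yi")$slope_equality_p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("exchanging group labels keeps the slope and flips the intercept gap", {
  rec <- traj_records(seed = 13, slices_per_group = 50L)
  f1 <- fit_group_lines(rec, "beta_yi")
  rec2 <- rec
  rec2$group <- ifelse(rec$group == "control", "treated", "control")
  f2 <- fit_group_lines(rec2, "beta_yi")
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(diff(f2$intercepts), -diff(f1$intercepts), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(f2$intercept_diff_p, f1$intercept_diff_p, tolerance = 1e-12)
})

test_that("the YI shape line climbs about twice as fast as the BI line", {
  ratios <- vapply(1:25, function(s) {
    rec <- traj_records(seed = 400 + s)
    fit_group_lines(rec, "beta_yi")$slope /
      fit_group_lines(rec, "beta_bi")$slope
  }, numeric(1))
  expect_gte(mean(ratios), 1.6)
  expect_lte(mean(ratios), 2.4)
})

test_that("residual diagnostics report the four hypotheses", {
  rec <- noiseless_records(c(control = 1.28, treated = 0.885), 0.00125,
                           "beta_yi", n_per_group = 100)
  fit <- fit_group_lines(rec, "beta_yi")
  d <- residual_diagnostics(fit)
  expect_lt(abs(d$residual_mean), 1e-10)
  expect_equal(d$acf$acf[d$acf$lag == 0], 1)
  expect_equal(d$acf_limit, 1.96 / sqrt(200))

  # injected AR(1) residuals surface in the lag-1 autocorrelation
  set.seed(14)
  rec$beta_yi <- rec$beta_yi +
    as.numeric(stats::arima.sim(list(ar = 0.8), 200, sd = 0.1))
  fa <- residual_diagnostics(fit_group_lines(rec, "beta_yi"))
  expect_gt(fa$acf$acf[fa$acf$lag == 1], fa$acf_limit)

  # heavy-tailed residuals are caught by the normality test
  set.seed(15)
  power <- mean(vapply(1:50, function(i) {
    rec$beta_yi <- 1.2 + 0.001 * rec$time_min + 0.1 * rt(200, df = 2)
    residual_diagnostics(fit_group_lines(rec, "beta_yi"))$shapiro_p < 0.05
  }, logical(1)))
  expect_gte(power, 0.8)

  # homoscedastic gaussian noise passes the Breusch-Pagan check
  set.seed(16)
  rec$beta_yi <- 1.2 + 0.001 * rec$time_min + rnorm(200, 0, 0.18)
  dn <- residual_diagnostics(fit_group_lines(rec, "beta_yi"))
  expect_gt(dn$bp_p, 0.01)
  expect_gt(dn$ppcc, 0.99)
})

test_that("degenerate designs are rejected", {
  rec <- data.frame(group = rep(c("control", "treated"), each = 5),
                    time_min = rep(60, 10), beta_yi = rnorm(10))
  expect_error(fit_group_lines(rec, "beta_yi"), "3 distinct timepoints")
  rec1 <- data.frame(group = "control", time_min = 1:5, beta_yi = rnorm(5))
  expect_error(fit_group_lines(rec1, "beta_yi"), "two groups")
})
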