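#' Common-slope (parallel-lines) trend of shape factors over exposure time
#'
#' Fits the full two-line model
#' `value ~ group + time + group:time` first and tests slope equality with
#' the interaction F-test. The reported coefficients are those of the
#' parallel-lines (common slope, distinct intercepts) model
#' `value ~ group + time`, the form in which the group trends are expressed
#' when the slopes do not differ; the intercept-difference test comes from
#' the group term of that model.
#'
#' @param records data.frame with `group` (two labels), `time_min` and the
#'   feature column.
#' @param feature `"beta_yi"` or `"beta_bi"` (any numeric column).
#' @param alpha Significance level for the slope-equality decision.
#' @return Object of class `trend_model`: list with `intercepts` (named per
#'   group) and their standard errors, `slope` and its standard error,
#'   `slope_equality_p` (interaction F-test), `intercept_diff_p`,
#'   `r2_adj_pct`, `see` (residual standard deviation of the parallel
#'   model), `parallel` (the `lm` fit), `full` (the two-slope `lm` fit),
#'   and `feature`.
#' @examples
#' rec <- data.frame(group = rep(c("control", "treated"), each = 20),
#'                   time_min = rep(seq(0, 540, length.out = 20), 2))
#' rec$beta_yi <- ifelse(rec$group == "control", 1.280, 0.885) +
#'   0.00125 * rec$time_min
#' fit_group_lines(rec, "beta_yi")
#' @export
fit_group_lines <- function(records, feature, alpha = 0.05) {
  y <- records[[feature]]
  g <- factor(records$group)
  t <- records$time_min
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  for (lv in levels(g)) {
    if (length(unique(t[g == lv])) < 3L)
      stop("group '", lv, "' needs at least 3 distinct timepoints")
  }
  d <- data.frame(y = y, g = g, t = t)
  full <- stats::lm(y ~ g + t + g:t, data = d)
  parallel <- stats::lm(y ~ g + t, data = d)
  slope_p <- stats::anova(parallel, full)[2, "Pr(>F)"]
  sm <- summary(parallel)
  co <- sm$coefficients
  gcoef <- paste0("g", levels(g)[2])
  a1 <- co["(Intercept)", "Estimate"]
  a2 <- a1 + co[gcoef, "Estimate"]
  # SE of the second intercept via the coefficient covariance
  V <- stats::vcov(parallel)
  se2 <- sqrt(V["(Intercept)", "(Intercept)"] + V[gcoef, gcoef] +
              2 * V["(Intercept)", gcoef])
  intercepts <- c(a1, a2)
  se_int <- c(co["(Intercept)", "Std. Error"], se2)
  names(intercepts) <- names(se_int) <- levels(g)
  structure(list(
    feature = feature,
    intercepts = intercepts,
    intercept_se = se_int,
    slope = co["t", "Estimate"],
    slope_se = co["t", "Std. Error"],
    slope_equality_p = slope_p,
    intercept_diff_p = co[gcoef, "Pr(>|t|)"],
    slopes_equal = slope_p > alpha,
    r2_adj_pct = 100 * sm$adj.r.squared,
    see = sm$sigma,
    parallel = parallel,
    full = full
  ), class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  for (lv in names(x$intercepts)) {
    cat(sprintf("%s: %s = %.4g + %.4g x time (min)\n",
                lv, x$feature, x$intercepts[[lv]], x$slope))
  }
  cat(sprintf(
    "common slope SE = %.3g; slope-equality p = %.4g; intercept-difference p = %.4g\nR2_adj = %.2f%%; SEE = %.4g\n",
    x$slope_se, x$slope_equality_p, x$intercept_diff_p, x$r2_adj_pct, x$see))
  invisible(x)
}

#' Residual diagnostics for a trend model
#'
#' Checks the four standard residual hypotheses of the linear trend fit:
#' zero mean, homoscedasticity (Breusch-Pagan test, plus the residual-vs-
#' fitted pairs for plotting), no autocorrelation (ACF with
#' \eqn{\pm 1.96/\sqrt{n}} limits), and normality (Shapiro-Wilk test plus
#' the probability-plot correlation coefficient). All are reported; none
#' gates the fit.
#'
#' @param model A `trend_model` from [fit_group_lines()].
#' @param max_lag Largest ACF lag (default 24, capped at n - 1).
#' @return List with `residual_mean`, `bp_stat`/`bp_p` (heteroscedasticity),
#'   `acf` (data.frame lag/acf), `acf_limit`, `shapiro_stat`/`shapiro_p`,
#'   `ppcc` (correlation of sorted residuals with normal plotting
#'   positions), and `fitted_vs_residual` (data.frame for export).
#' @export
residual_diagnostics <- function(model, max_lag = 24L) {
  stopifnot(inherits(model, "trend_model"))
  fit <- model$parallel
  e <- stats::residuals(fit)
  n <- length(e)
  max_lag <- min(max_lag, n - 1L)
  bp <- lmtest::bptest(fit)
  ac <- stats::acf(e, lag.max = max_lag, plot = FALSE, demean = TRUE)
  sh <- stats::shapiro.test(e)
  qs <- stats::qnorm(stats::ppoints(n))
  ppcc <- stats::cor(sort(e), qs)
  list(
    residual_mean = mean(e),
    bp_stat = unname(bp$statistic), bp_p = unname(bp$p.value),
    acf = data.frame(lag = as.vector(ac$lag), acf = as.vector(ac$acf)),
    acf_limit = 1.96 / sqrt(n),
    shapiro_stat = unname(sh$statistic), shapiro_p = unname(sh$p.value),
    ppcc = ppcc,
    fitted_vs_residual = data.frame(fitted = stats::fitted(fit), residual = e)
  )
}
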