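#!/usr/bin/env Rscript
# Stage 4: temporal trend of the shape factors.
#
# Fits the common-slope (parallel-lines) model shape ~ group + time for
# each index, tests slope equality and the intercept difference, and runs
# the residual diagnostics (zero mean, Breusch-Pagan homoscedasticity,
# autocorrelation, Shapiro-Wilk normality).

suppressPackageStartupMessages(library(pearbrowning))

if (!file.exists("results/pipeline/slice_records.csv"))
  stop("run analysis/02_extract_features.R first")
rec <- read_slice_records("results/pipeline/slice_records.csv")

rows <- list()
for (feature in c("beta_yi", "beta_bi")) {
  fit <- fit_group_lines(rec, feature)
  d <- residual_diagnostics(fit)
  print(fit)
  cat(sprintf(
    "  residual mean %.2e; BP p = %.3f; Shapiro p = %.3f; PPCC = %.4f\n",
    d$residual_mean, d$bp_p, d$shapiro_p, d$ppcc))
  rows[[feature]] <- data.frame(
    feature = feature,
    intercept_control = fit$intercepts[["control"]],
    intercept_treated = fit$intercepts[["treated"]],
    slope_per_min = fit$slope, slope_se = fit$slope_se,
    slope_equality_p = fit$slope_equality_p,
    intercept_diff_p = fit$intercept_diff_p,
    r2_adj_pct = fit$r2_adj_pct, see = fit$see,
    bp_p = d$bp_p, shapiro_p = d$shapiro_p)
}
trend <- do.call(rbind, rows)
utils::write.csv(trend, "results/trend_summary.csv", row.names = FALSE)

cat(sprintf("\nSlope ratio YI/BI: %.2f\n",
            trend$slope_per_min[trend$feature == "beta_yi"] /
              trend$slope_per_min[trend$feature == "beta_bi"]))
cat("Summary written to results/trend_summary.csv\n")
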