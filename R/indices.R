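#' Browning Index (BI)
#'
#' Dimensionless purity-of-brown metric computed from CIE Lab* values:
#' \deqn{X = \frac{a^* + 1.75 L^*}{5.645 L^* + a^* - 3.012 b^*}, \qquad
#'       BI = \frac{100 (X - 0.31)}{0.17}.}
#' Pixels whose denominator is smaller than `eps` in magnitude are
#' undefined and returned as `NA` (never imputed).
#'
#' @param L,a,b Lab* channel values (vectorised).
#' @param eps Degenerate-denominator threshold (default 1e-6).
#' @return BI values, `NA` where the denominator is degenerate.
#' @examples
#' browning_index(50, 10, 20)  # ~ 64.85
#' @export
browning_index <- function(L, a, b, eps = 1e-6) {
  den <- 5.645 * L + a - 3.012 * b
  X <- (a + 1.75 * L) / den
  out <- 100 * (X - 0.31) / 0.17
  out[abs(den) < eps] <- NA_real_
  out
}

#' Yellowing Index (YI)
#'
#' Dimensionless yellowness metric \eqn{YI = 142.86\, b^*/L^*}. Pixels with
#' `L <= eps` (black) carry no meaningful yellowness ratio and are `NA`.
#'
#' @param L,b Lab* channel values (vectorised).
#' @param eps Lightness floor below which YI is undefined.
#' @return YI values, `NA` where L* is degenerate.
#' @examples
#' yellowing_index(50, 20)  # 57.144
#' @export
yellowing_index <- function(L, b, eps = 1e-6) {
  out <- 142.86 * b / L
  out[L <= eps] <- NA_real_
  out
}

#' Invert (BI, YI, L*) to (a*, b*)
#'
#' Exact algebraic inversion of the two index formulas at fixed lightness,
#' used by the synthetic generator to paint pixels carrying prescribed index
#' values: \eqn{b = YI \cdot L / 142.86} and, with
#' \eqn{X = 0.31 + 0.17\, BI / 100},
#' \eqn{a = [X (5.645 L - 3.012 b) - 1.75 L] / (1 - X)}.
#'
#' @param BI,YI Target index values (vectorised).
#' @param L Lightness, must be > 0.
#' @return List with numeric components `a` and `b`; round-trips through
#'   [browning_index()] / [yellowing_index()] to machine precision.
#' @export
lab_from_indices <- function(BI, YI, L) {
  if (any(L <= 0)) stop("L* must be strictly positive")
  X <- 0.31 + 0.17 * BI / 100
  if (any(abs(1 - X) < 1e-12))
    stop("X = 1 is singular: BI cannot be inverted at this value")
  b <- YI * L / 142.86
  a <- (X * (5.645 * L - 3.012 * b) - 1.75 * L) / (1 - X)
  list(a = a, b = b)
}

#' Per-slice BI and YI maps and samples
#'
#' Evaluates both indices over one segmented slice. The maps keep the full
#' canvas geometry with `NA` outside the component (and at degenerate
#' pixels); the samples are the flat vectors of defined values that feed the
#' Weibull fit.
#'
#' @param lab H x W x 3 Lab* array.
#' @param comp A `slice_component` from [extract_slices()].
#' @param eps Degeneracy threshold passed to the index functions.
#' @return List with `bi_map`, `yi_map` (H x W matrices), `bi`, `yi`
#'   (numeric vectors of defined values) and `n_degenerate` (pixels of the
#'   component where either index was undefined).
#' @export
index_maps_for_slice <- function(lab, comp, eps = 1e-6) {
  stopifnot(inherits(comp, "slice_component"))
  d <- dim(lab)
  if (!all(dim(comp$mask) == d[1:2]))
    stop("component mask does not match image geometry")
  idx <- which(comp$mask)
  L <- lab[, , 1][idx]; a <- lab[, , 2][idx]; b <- lab[, , 3][idx]
  bi <- browning_index(L, a, b, eps = eps)
  yi <- yellowing_index(L, b, eps = eps)
  n_degen <- sum(is.na(bi) | is.na(yi))
  if (all(is.na(bi)) || all(is.na(yi)))
    stop("slice component ", comp$id, " has no defined index pixels")
  bi_map <- matrix(NA_real_, d[1], d[2]); bi_map[idx] <- bi
  yi_map <- matrix(NA_real_, d[1], d[2]); yi_map[idx] <- yi
  list(bi_map = bi_map, yi_map = yi_map,
       bi = bi[is.finite(bi)], yi = yi[is.finite(yi)],
       n_degenerate = n_degen)
}

#' Summarise an index sample
#'
#' @param x Numeric vector of index values.
#' @return One-row data.frame with n, mean, sd, min, max.
#' @export
index_summary <- function(x) {
  data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
             min = min(x), max = max(x))
}
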