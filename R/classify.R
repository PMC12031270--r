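#' Kernel Bayes classifier over Weibull shape factors
#'
#' Fits a Bayes classifier on one or two shape-factor features
#' (`beta_bi`, `beta_yi`). The default method is a probabilistic-neural-
#' network-style kernel rule: features are standardised, each class gets a
#' Gaussian kernel density estimate with a single common smoothing parameter
#' `sigma`, and a point is assigned to the class maximising
#' prior x density. When `bandwidth` is not supplied, `sigma` is *trained*
#' by jackknife: the leave-one-out correct-classification rate is computed
#' on a log-spaced grid of candidate values and the maximiser is kept (ties
#' broken toward the smallest candidate).
#'
#' Alternatives: `method = "kde_silverman"` uses per-class, per-feature
#' Gaussian-kernel densities with Silverman's rule-of-thumb bandwidths;
#' `method = "naive_gauss"` uses independent Gaussian class likelihoods.
#'
#' @param records data.frame with a `group` column (two labels) and the
#'   feature columns.
#' @param features Character subset of `c("beta_bi", "beta_yi")` (or any
#'   numeric columns of `records`).
#' @param method Classifier variant; see Details.
#' @param bandwidth Optional fixed smoothing parameter (standardised-feature
#'   units for `"pnn"`, raw units per feature for `"kde_silverman"`).
#' @param sigma_grid Candidate smoothing values for jackknife training.
#' @param priors Class prior probabilities; `"empirical"` (default) uses
#'   class frequencies, or a named numeric vector summing to 1.
#' @return Object of class `browning_bayes` with a [predict()] method.
#' @export
bayes_fit <- function(records, features = c("beta_bi", "beta_yi"),
                      method = c("pnn", "kde_silverman", "naive_gauss"),
                      bandwidth = NULL,
                      sigma_grid = exp(seq(log(0.05), log(3), length.out = 30)),
                      priors = "empirical") {
  method <- match.arg(method)
  if (length(features) == 0L) stop("at least one feature is required")
  if (!all(features %in% names(records)))
    stop("missing feature column(s): ",
         paste(setdiff(features, names(records)), collapse = ", "))
  y <- as.character(records$group)
  cls <- sort(unique(y))
  if (length(cls) < 2L) stop("need records from at least 2 classes")
  if (any(table(y) < 2L)) stop("need at least 2 records per class")
  X <- as.matrix(records[, features, drop = FALSE])
  storage.mode(X) <- "double"
  for (cl in cls) for (j in seq_along(features)) {
    if (stats::sd(X[y == cl, j]) == 0 && method != "pnn")
      stop("feature '", features[j], "' is constant within class '", cl,
           "'; supply an explicit bandwidth")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  if (any(scale_ == 0))
    stop("feature(s) constant over the training set; ",
         "supply an explicit bandwidth or drop the feature")
  if (identical(priors, "empirical")) {
    pr <- table(y)[cls] / length(y)
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), cls))
      stop("priors must be named with the class labels")
    pr <- priors[cls] / sum(priors)
  }
  model <- list(method = method, features = features, classes = cls,
                priors = as.numeric(pr), center = center, scale = scale_,
                X = sweep(sweep(X, 2, center), 2, scale_, "/"),
                X_raw = X, y = y)
  if (method == "pnn") {
    if (!is.null(bandwidth)) {
      model$sigma <- bandwidth
    } else {
      tr <- .pnn_train_sigma(model$X, y, cls, model$priors, sigma_grid)
      model$sigma <- tr$sigma
      model$loo_rate <- tr$rate
    }
  } else if (method == "kde_silverman") {
    model$h <- lapply(cls, function(cl) {
      apply(X[y == cl, , drop = FALSE], 2, function(v) {
        if (!is.null(bandwidth)) return(bandwidth)
        s <- min(stats::sd(v), stats::IQR(v) / 1.34)
        if (s <= 0) s <- stats::sd(v)
        0.9 * s * sum(y == cl)^(-1 / 5)
      })
    })
    names(model$h) <- cls
  } else {
    model$mu <- lapply(cls, function(cl) colMeans(X[y == cl, , drop = FALSE]))
    model$sd <- lapply(cls, function(cl)
      apply(X[y == cl, , drop = FALSE], 2, stats::sd))
    names(model$mu) <- names(model$sd) <- cls
  }
  structure(model, class = "browning_bayes")
}

# leave-one-out class scores for the common-sigma kernel rule: full-sample
# priors times the class-conditional mean kernel density, with the
# denominator corrected for the left-out point (using raw kernel sums
# instead would deflate the own-class prior and bias exchangeable data
# toward the other class)
.pnn_loo_scores <- function(D2, y, cls, priors, sigma) {
  n <- length(y)
  nc <- as.numeric(table(y)[cls])
  K <- exp(-D2 / (2 * sigma^2))
  diag(K) <- 0
  vapply(seq_along(cls), function(j) {
    priors[j] * rowSums(K[, y == cls[j], drop = FALSE]) /
      (nc[j] - (y == cls[j]))
  }, numeric(n))
}

# train sigma by maximising the leave-one-out correct rate on a grid
.pnn_train_sigma <- function(Xs, y, cls, priors, sigma_grid) {
  D2 <- as.matrix(stats::dist(Xs))^2
  rates <- vapply(sigma_grid, function(s) {
    sc <- .pnn_loo_scores(D2, y, cls, priors, s)
    mean(cls[max.col(sc, ties.method = "first")] == y)
  }, numeric(1))
  best <- which.max(rates)  # ties -> smallest sigma
  list(sigma = sigma_grid[best], rate = rates[best])
}

#' Predict class labels from a fitted kernel Bayes classifier
#'
#' @param object A `browning_bayes` model.
#' @param newdata data.frame containing the model's feature columns (or a
#'   numeric matrix in feature order).
#' @param type `"class"` for labels, `"score"` for the per-class
#'   prior-times-density scores.
#' @param ... Unused.
#' @return Character vector of class labels, or a score matrix.
#' @export
predict.browning_bayes <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  newdata <- matrix(as.numeric(newdata), ncol = length(object$features))
  cls <- object$classes
  if (object$method == "pnn") {
    Z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
    sc <- vapply(seq_along(cls), function(k) {
      Tr <- object$X[object$y == cls[k], , drop = FALSE]
      d2 <- outer(rowSums(Z^2), rowSums(Tr^2), "+") - 2 * Z %*% t(Tr)
      object$priors[k] * rowMeans(exp(-d2 / (2 * object$sigma^2)))
    }, numeric(nrow(newdata)))
  } else if (object$method == "kde_silverman") {
    sc <- vapply(seq_along(cls), function(k) {
      Tr <- object$X_raw[object$y == cls[k], , drop = FALSE]
      h <- object$h[[cls[k]]]
      dens <- rep(1, nrow(newdata)) %o% rep(1, nrow(Tr))
      for (j in seq_along(h)) {
        dj <- outer(newdata[, j], Tr[, j], "-") / h[j]
        dens <- dens * stats::dnorm(dj) / h[j]
      }
      object$priors[k] * rowMeans(dens)
    }, numeric(nrow(newdata)))
  } else {
    sc <- vapply(seq_along(cls), function(k) {
      ll <- rep(0, nrow(newdata))
      for (j in seq_along(object$features)) {
        ll <- ll + stats::dnorm(newdata[, j], object$mu[[cls[k]]][j],
                                object$sd[[cls[k]]][j], log = TRUE)
      }
      log(object$priors[k]) + ll
    }, numeric(nrow(newdata)))
  }
  sc <- matrix(sc, ncol = length(cls), dimnames = list(NULL, cls))
  if (type == "score") return(sc)
  # ties broken toward the lexicographically first class (columns sorted)
  cls[max.col(sc, ties.method = "first")]
}

#' Jackknife (leave-one-out) correct-classification rates
#'
#' Each record is predicted by a classifier trained on all the others; the
#' per-class and overall percentages of correct predictions are returned.
#' For the default `"pnn"` method the smoothing parameter is the one whose
#' leave-one-out rate is maximal — training and validation are the same
#' jackknife loop, mirroring how the classifier is trained in practice. For
#' the other methods every fold is refit from scratch. The result is
#' deterministic given the records, and invariant to record order.
#'
#' @inheritParams bayes_fit
#' @param ... Passed to [bayes_fit()].
#' @return List with `per_class` (named vector, %), `overall` (%),
#'   `predictions` (character vector aligned with `records`), and for
#'   `"pnn"` the trained `sigma`.
#' @export
jackknife_rate <- function(records, features = c("beta_bi", "beta_yi"),
                           method = c("pnn", "kde_silverman", "naive_gauss"),
                           ...) {
  method <- match.arg(method)
  y <- as.character(records$group)
  cls <- sort(unique(y))
  n <- length(y)
  if (method == "pnn") {
    model <- bayes_fit(records, features, method = "pnn", ...)
    D2 <- as.matrix(stats::dist(model$X))^2
    sc <- .pnn_loo_scores(D2, y, cls, model$priors, model$sigma)
    pred <- cls[max.col(sc, ties.method = "first")]
    sigma <- model$sigma
  } else {
    pred <- character(n)
    for (i in seq_len(n)) {
      m <- bayes_fit(records[-i, , drop = FALSE], features, method = method,
                     ...)
      pred[i] <- predict(m, records[i, , drop = FALSE])
    }
    sigma <- NULL
  }
  per_class <- vapply(cls, function(cl) 100 * mean(pred[y == cl] == cl),
                      numeric(1))
  out <- list(per_class = per_class, overall = 100 * mean(pred == y),
              predictions = pred)
  if (!is.null(sigma)) out$sigma <- sigma
  out
}

#' Binary confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives for the chosen positive class).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("confusion matrix must contain at least one case")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from predicted and actual labels
#'
#' @param actual,predicted Label vectors of equal length.
#' @param positive The label treated as positive.
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(actual, predicted, positive) {
  stopifnot(length(actual) == length(predicted))
  confusion_matrix(tp = sum(actual == positive & predicted == positive),
                   fp = sum(actual != positive & predicted == positive),
                   fn = sum(actual == positive & predicted != positive),
                   tn = sum(actual != positive & predicted != positive))
}

#' Exchange the positive and negative class of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return The confusion matrix seen from the other class.
#' @export
swap_classes <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  confusion_matrix(tp = cm$tn, fp = cm$fn, fn = cm$fp, tn = cm$tp)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy \eqn{(TP+TN)/(TP+FP+FN+TN)}, precision \eqn{TP/(TP+FP)},
#' recall (sensitivity) \eqn{TP/(TP+FN)} and the F-measure
#' \eqn{F_1 = 2PR/(P+R)}, all for the positive class. A metric whose
#' denominator is zero is `NA` (undefined), never 0. Counts are exact
#' integers so the arithmetic is exact up to the final division.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `accuracy`, `precision`, `recall`, `f1` in \[0, 1\]
#'   and `total`, the number of cases.
#' @examples
#' confusion_metrics(confusion_matrix(2080, 0, 137, 1863))
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  p <- div(cm$tp, cm$tp + cm$fp)
  r <- div(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else
    2 * p * r / (p + r)
  list(accuracy = div(cm$tp + cm$tn, total), precision = p, recall = r,
       f1 = f1, total = total)
}

#' Gain of a combined-feature classifier over single-feature ones
#'
#' Average improvement, in percentage points, of a combined-feature correct-
#' classification rate over the mean of the corresponding single-feature
#' rates for the same class.
#'
#' @param combined Combined-feature rate (%).
#' @param singles Numeric vector of single-feature rates (%).
#' @return Percentage-point gain.
#' @export
combined_feature_gain <- function(combined, singles) {
  combined - mean(singles)
}

#' Fisher's LSD pairwise comparison of group means
#'
#' One-way ANOVA pooled-variance least-significant-difference test: a pair
#' of groups differs significantly when the absolute difference of means
#' exceeds \eqn{t_{1-\alpha/2,\,df_E}\sqrt{MSE(1/n_i+1/n_j)}}.
#'
#' @param records data.frame with `group` and the feature column.
#' @param feature Column name of the response.
#' @param alpha Significance level (default 0.05).
#' @return List with `anova_p` (overall F-test p-value), `mse`, `df`, and
#'   `pairs`, a data.frame of pairwise differences, LSD thresholds and
#'   significance flags.
#' @export
lsd_compare <- function(records, feature, alpha = 0.05) {
  y <- records[[feature]]
  g <- factor(records$group)
  ns <- table(g)
  if (nlevels(g) < 2L || any(ns < 2L))
    stop("need at least 2 groups with at least 2 records each")
  fit <- stats::aov(y ~ g)
  dfe <- stats::df.residual(fit)
  mse <- stats::deviance(fit) / dfe
  anova_p <- stats::anova(fit)[1, "Pr(>F)"]
  means <- tapply(y, g, mean)
  lv <- levels(g)
  combs <- utils::combn(lv, 2)
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  n1 <- as.numeric(ns[combs[1, ]])
  n2 <- as.numeric(ns[combs[2, ]])
  pairs <- data.frame(
    group1 = combs[1, ], group2 = combs[2, ],
    diff = as.numeric(means[combs[1, ]] - means[combs[2, ]]),
    lsd = as.numeric(tcrit * sqrt(mse * (1 / n1 + 1 / n2))),
    row.names = NULL
  )
  pairs$significant <- abs(pairs$diff) > pairs$lsd
  list(anova_p = anova_p, mse = mse, df = dfe,
       means = means, pairs = pairs)
}
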