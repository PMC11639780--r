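#' Empirical ROC curve and AUC
#'
#' Builds the empirical receiver operating characteristic curve for a score
#' against a binary outcome, with test-positive defined as score at or above
#' the threshold. The AUC is computed by trapezoidal integration over the
#' curve, which for the empirical ROC equals the tie-corrected Mann-Whitney
#' estimator P(score+ > score-) + P(score+ = score-)/2.
#'
#' @param scores numeric vector; higher score = more likely positive.
#' @param labels logical or 0/1 vector (or factor/character with
#'   `positive_label`) marking the positive class.
#' @param positive_label for non-logical labels, the level treated as
#'   positive (default `"deceased"`).
#' @return object of class `fg_roc`: list with `thresholds` (ascending,
#'   with a +Inf sentinel so the curve runs from sensitivity 1/specificity 0
#'   to sensitivity 0/specificity 1), `sens`, `spec`, `auc`, `n_pos`,
#'   `n_neg`.
#' @examples
#' empirical_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
empirical_roc <- function(scores, labels, positive_label = "deceased") {
  y <- .as_binary(labels, positive_label)
  stopifnot(length(scores) == length(y))
  if (any(!is.finite(scores))) {
    stop("empirical_roc: scores must be finite", call. = FALSE)
  }
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("empirical_roc: need at least one positive and one negative label",
         call. = FALSE)
  }
  thresholds <- c(sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) sum(scores >= t & y) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & !y) / n_neg,
                 numeric(1))
  # trapezoid over (FPR, TPR); thresholds ascend so FPR descends
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  structure(
    list(thresholds = thresholds, sens = sens, spec = spec, auc = auc,
         n_pos = n_pos, n_neg = n_neg, scores = scores, labels = y),
    class = "fg_roc"
  )
}

.as_binary <- function(labels, positive_label) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(labels == 1)
  }
  as.character(labels) == positive_label
}

#' @export
print.fg_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Confidence interval for an empirical AUC
#'
#' Two standard methods are provided: DeLong's nonparametric variance
#' (default) based on placement values, and the Hanley-McNeil
#' exponential-approximation standard error. Both yield Wald intervals on
#' the AUC scale, truncated to \[0, 1\].
#'
#' @param roc an `fg_roc` object from [empirical_roc()].
#' @param conf_level confidence level (default 0.95).
#' @param method `"delong"` or `"hanley_mcneil"`.
#' @return list with `auc`, `se`, `lower`, `upper`, `method`, `conf_level`.
#' @export
auc_ci <- function(roc, conf_level = 0.95,
                   method = c("delong", "hanley_mcneil")) {
  stopifnot(inherits(roc, "fg_roc"), conf_level > 0, conf_level < 1)
  method <- match.arg(method)
  x <- roc$scores[roc$labels]    # positives
  y <- roc$scores[!roc$labels]   # negatives
  m <- length(x); n <- length(y)
  auc <- roc$auc
  if (method == "delong") {
    # placement values: V10[i] = P-hat(x_i > Y) + .5 P-hat(x_i = Y)
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                  numeric(1))
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc, se = se,
       lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       method = method, conf_level = conf_level)
}

#' Sensitivity, specificity, and 2x2 table at a score cutoff
#'
#' Test-positive is score at or above `cutoff`. Sensitivity is a/(a+b)
#' (true positives among outcome-positives) and specificity d/(c+d).
#' If either outcome class is empty the corresponding metric is `NA` and
#' flagged, never silently reported as 0.
#'
#' @inheritParams empirical_roc
#' @param cutoff finite numeric threshold.
#' @return list with `sensitivity`, `specificity`, `table` (named vector
#'   a, b, c, d), `cutoff`, and `undefined` (character vector naming any
#'   metric with an empty denominator).
#' @export
metrics_at_cutoff <- function(scores, labels, cutoff,
                              positive_label = "deceased") {
  stopifnot(is.finite(cutoff))
  y <- .as_binary(labels, positive_label)
  tab <- c(a = sum(y & scores >= cutoff), b = sum(y & scores < cutoff),
           c = sum(!y & scores >= cutoff), d = sum(!y & scores < cutoff))
  undefined <- character(0)
  sens <- if (tab["a"] + tab["b"] > 0) {
    unname(tab["a"] / (tab["a"] + tab["b"]))
  } else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tab["c"] + tab["d"] > 0) {
    unname(tab["d"] / (tab["c"] + tab["d"]))
  } else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  list(sensitivity = sens, specificity = spec, table = tab,
       cutoff = cutoff, undefined = undefined)
}
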