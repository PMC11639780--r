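#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors and
#' odds-ratio confidence intervals, plus the Hosmer-Lemeshow
#' goodness-of-fit statistic on groups formed from deciles of predicted
#' risk. Convergence is declared when the largest absolute coefficient
#' change drops below `tol`; complete separation (a coefficient diverging
#' while fitted probabilities pin to 0/1) is detected and raised as an
#' error rather than silently clipped.
#'
#' @param design numeric matrix of predictors (no intercept column; one is
#'   added). Column names are used for coefficient labels.
#' @param outcome binary 0/1 (or logical) response vector.
#' @param conf_level confidence level for Wald odds-ratio intervals.
#' @param tol convergence tolerance on the coefficient step.
#' @param max_iter maximum IRLS iterations.
#' @param hl_groups target number of Hosmer-Lemeshow risk groups.
#' @return object of class `fg_logit`: list with `coefficients`, `se`,
#'   `z`, `p`, `or`, `or_lower`, `or_upper`, `fitted`, `converged`,
#'   `iterations`, `deviance`, and `hosmer_lemeshow` (list `chi2`, `df`,
#'   `p`, `groups`).
#' @export
logistic_fit <- function(design, outcome, conf_level = 0.95,
                         tol = 1e-8, max_iter = 50, hl_groups = 10) {
  x <- as.matrix(design)
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (ncol(x) > 0) {
    const <- apply(x, 2, function(col) diff(range(col)) == 0)
    if (any(const)) {
      stop("logistic_fit: constant predictor column: ",
           paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    }
  }
  xm <- cbind(`(Intercept)` = 1, x)
  if (length(y) <= ncol(xm)) {
    stop("logistic_fit: need more observations than parameters",
         call. = FALSE)
  }
  beta <- rep(0, ncol(xm))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(xm %*% beta)
    p_hat <- stats::plogis(eta)
    w <- p_hat * (1 - p_hat)
    w <- pmax(w, 1e-10)
    z <- eta + (y - p_hat) / w
    fit <- stats::lm.wfit(xm, z, w)
    step <- fit$coefficients - beta
    beta <- fit$coefficients
    if (any(!is.finite(beta))) {
      stop("logistic_fit: singular or collinear design", call. = FALSE)
    }
    if (max(abs(beta)) > 30) {
      stop(paste("logistic_fit: coefficient diverging;",
                 "data appear completely separated"), call. = FALSE)
    }
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(xm %*% beta)
  p_hat <- stats::plogis(eta)
  dev0 <- -2 * sum(y * log(pmax(p_hat, 1e-300)) +
                     (1 - y) * log(pmax(1 - p_hat, 1e-300)))
  # separation: likelihood saturates (deviance -> 0) while a coefficient
  # keeps growing instead of the step shrinking below tol
  if (!converged && (dev0 < 1e-6 || max(abs(beta)) > 15)) {
    stop(paste("logistic_fit: coefficient diverging;",
               "data appear completely separated"), call. = FALSE)
  }
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  info <- crossprod(xm * sqrt(w))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  zval <- beta / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  dev <- dev0
  hl <- hosmer_lemeshow(y, p_hat, groups = hl_groups)
  structure(
    list(coefficients = beta, se = se, z = zval,
         p = 2 * stats::pnorm(-abs(zval)),
         or = exp(beta), or_lower = exp(beta - zq * se),
         or_upper = exp(beta + zq * se),
         fitted = p_hat, converged = converged, iterations = iter,
         deviance = dev, vcov = vcov, hosmer_lemeshow = hl),
    class = "fg_logit"
  )
}

#' Hosmer-Lemeshow goodness-of-fit statistic
#'
#' Partitions observations into groups by deciles of predicted risk
#' (fewer groups when ties collapse decile boundaries) and compares
#' observed to expected event counts; the statistic is referred to a
#' chi-square with (groups - 2) degrees of freedom.
#'
#' @param y binary 0/1 outcomes.
#' @param p_hat fitted probabilities.
#' @param groups target number of risk groups (default 10).
#' @return list with `chi2`, `df`, `p`, `groups` (the number actually
#'   formed).
#' @export
hosmer_lemeshow <- function(y, p_hat, groups = 10) {
  stopifnot(length(y) == length(p_hat), all(y %in% c(0, 1)))
  breaks <- unique(stats::quantile(p_hat, probs = seq(0, 1, length.out = groups + 1)))
  if (length(breaks) < 3) {
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                groups = length(breaks) - 1))
  }
  g <- cut(p_hat, breaks = breaks, include.lowest = TRUE)
  obs <- tapply(y, g, sum)
  exp_ <- tapply(p_hat, g, sum)
  n_g <- tapply(y, g, length)
  keep <- !is.na(n_g) & n_g > 0
  obs <- obs[keep]; exp_ <- exp_[keep]; n_g <- n_g[keep]
  p_bar <- exp_ / n_g
  denom <- pmax(n_g * p_bar * (1 - p_bar), 1e-10)
  chi2 <- sum((obs - exp_)^2 / denom)
  df <- length(obs) - 2
  list(chi2 = unname(chi2), df = df,
       p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
           else NA_real_,
       groups = length(obs))
}

#' @export
print.fg_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (%d iterations, %sconverged)\n",
              x$iterations, if (x$converged) "" else "NOT "))
  tab <- data.frame(
    estimate = x$coefficients, se = x$se, p = x$p,
    OR = x$or, lower = x$or_lower, upper = x$or_upper
  )
  print(round(tab, 4))
  hl <- x$hosmer_lemeshow
  if (!is.na(hl$chi2)) {
    cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %.3f\n",
                hl$chi2, hl$df, hl$p))
  }
  invisible(x)
}
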