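#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table (a, b, c, d) = (outcome+/test+, outcome+/test-,
#' outcome-/test+, outcome-/test-), the odds ratio is ad/bc with Woolf's
#' log-scale interval exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)).
#' With a zero cell the OR and interval are undefined; setting
#' `haldane = TRUE` applies the Haldane-Anscombe correction (0.5 added to
#' every cell) before computing. The correction is off by default.
#'
#' @param table numeric vector of four nonnegative counts, in order
#'   a, b, c, d.
#' @param conf_level confidence level in (0, 1).
#' @param haldane add 0.5 to every cell when any cell is zero.
#' @return list with `or`, `lower`, `upper`, `conf_level`, `table`,
#'   `corrected` (logical). With a zero cell and `haldane = FALSE`, `or`
#'   and the limits are `Inf`/`NaN` as arithmetic dictates and
#'   `undefined = TRUE` is set.
#' @examples
#' odds_ratio(c(18, 2, 45, 104))  # OR 20.8, CI approx (4.63, 93.4)
#' @export
odds_ratio <- function(table, conf_level = 0.95, haldane = FALSE) {
  tab <- .check_2x2(table)
  stopifnot(conf_level > 0, conf_level < 1)
  corrected <- FALSE
  if (any(tab == 0)) {
    if (haldane) {
      tab <- tab + 0.5
      corrected <- TRUE
    } else {
      or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
      return(list(or = unname(or), lower = NaN, upper = NaN,
                  conf_level = conf_level, table = tab,
                  corrected = FALSE, undefined = TRUE))
    }
  }
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  se_log <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       lower = unname(exp(log(or) - z * se_log)),
       upper = unname(exp(log(or) + z * se_log)),
       conf_level = conf_level, table = tab, corrected = corrected,
       undefined = FALSE)
}

.check_2x2 <- function(table) {
  tab <- as.numeric(table)
  if (length(tab) != 4 || any(tab < 0) || any(tab != round(tab))) {
    stop("expected four nonnegative integer counts (a, b, c, d)",
         call. = FALSE)
  }
  if (sum(tab) < 1) stop("empty 2x2 table", call. = FALSE)
  names(tab) <- c("a", "b", "c", "d")
  tab
}

#' Pearson chi-square test for a 2x2 table with Cohen's w
#'
#' Computes the closed-form 2x2 Pearson statistic
#' chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on 1 degree of freedom,
#' without Yates continuity correction by default, and the effect size
#' w = sqrt(chi2 / n) that drives post-hoc power.
#'
#' @inheritParams odds_ratio
#' @param correct apply the Yates continuity correction
#'   (|ad - bc| reduced by n/2 before squaring).
#' @return list with `chi2`, `df` (always 1), `p`, `w`, `n`.
#' @examples
#' chi_square_2x2(c(18, 2, 45, 104))  # chi2 approx 26.97, w approx 0.399
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  tab <- .check_2x2(table)
  n <- sum(tab)
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    stop("chi_square_2x2: degenerate margin (zero row or column sum)",
         call. = FALSE)
  }
  det <- abs(a * d - b * cc)
  if (correct) det <- max(0, det - n / 2)
  chi2 <- unname(n * det^2 / prod(margins))
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       w = sqrt(chi2 / n), n = unname(n))
}

#' Noncentral chi-square CDF by Poisson-mixture series
#'
#' Evaluates F(x; df, lambda) as the Poisson(lambda/2)-weighted mixture of
#' central chi-square CDFs with df + 2i degrees of freedom. Terms are summed
#' from i = 0 upward and the series is truncated once the remaining Poisson
#' tail mass falls below `rel_tol` relative to the accumulated weight; since
#' every central CDF lies in \[0, 1\] the truncation error is bounded by
#' that tail mass.
#'
#' @param x nonnegative quantile.
#' @param df degrees of freedom (>= 1).
#' @param lambda noncentrality parameter (>= 0).
#' @param rel_tol relative truncation tolerance.
#' @return CDF value in \[0, 1\].
#' @keywords internal
pnchisq_series <- function(x, df, lambda, rel_tol = 1e-12) {
  stopifnot(x >= 0, df >= 1, lambda >= 0)
  if (lambda == 0) return(stats::pchisq(x, df))
  half <- lambda / 2
  total <- 0
  acc_w <- 0
  i <- 0
  log_w <- -half  # log Poisson(0; lambda/2) weight
  repeat {
    w <- exp(log_w)
    total <- total + w * stats::pchisq(x, df + 2 * i)
    acc_w <- acc_w + w
    if (1 - acc_w < rel_tol * max(acc_w, 1)) break
    i <- i + 1
    log_w <- log_w + log(half) - log(i)
    if (i > 1e6) break  # safety; unreachable for realistic lambda
  }
  min(1, total)
}

#' Post-hoc power of a chi-square test
#'
#' Computes the achieved power of a Pearson chi-square test given the
#' sample size and Cohen's effect size w. The noncentrality is
#' lambda = n w^2, the critical value the (1 - alpha) quantile of the
#' central chi-square with `df` degrees of freedom, and the power
#' 1 - F_noncentral(critical; df, lambda) with the noncentral CDF evaluated
#' by [pnchisq_series()].
#'
#' @param n_total total sample size (>= 1).
#' @param w Cohen's effect size (>= 0).
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (default 1 for a 2x2 table).
#' @return object of class `fg_power`: list with `n_total`,
#'   `effect_size_w`, `alpha`, `df`, `noncentrality_lambda`,
#'   `critical_value`, `power`.
#' @examples
#' posthoc_power_chi2(169, 0.395, 0.05, 1)  # power 0.99925
#' @export
posthoc_power_chi2 <- function(n_total, w, alpha = 0.05, df = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("posthoc_power_chi2: alpha must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(n_total >= 1, w >= 0, df >= 1)
  lambda <- n_total * w^2
  crit <- stats::qchisq(1 - alpha, df)
  power <- 1 - pnchisq_series(crit, df, lambda)
  structure(
    list(n_total = n_total, effect_size_w = w, alpha = alpha, df = as.integer(df),
         noncentrality_lambda = lambda, critical_value = crit, power = power),
    class = "fg_power"
  )
}

#' @export
print.fg_power <- function(x, ...) {
  cat(sprintf(
    "Post-hoc chi-square power: %.5f (n = %d, w = %.3f, lambda = %.2f, critical chi2 = %.2f, alpha = %.2f)\n",
    x$power, x$n_total, x$effect_size_w, x$noncentrality_lambda,
    x$critical_value, x$alpha))
  invisible(x)
}
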