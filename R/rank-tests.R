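#' Mann-Whitney U test for two independent samples
#'
#' Computes U for the first sample from midranks,
#' U = R_x - n_x(n_x + 1)/2 where R_x is the rank sum of `x` in the pooled
#' sample. The two-sided p-value uses the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction; when the pooled
#' sample size is at most `exact_max` and there are no ties, the exact
#' permutation distribution of U is enumerated instead.
#'
#' @param x,y nonempty numeric samples.
#' @param exact_max largest pooled size for which exact enumeration is
#'   attempted (default 12).
#' @return list with `u` (statistic for `x`), `p` (two-sided), `method`
#'   (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney_u: both samples must be nonempty", call. = FALSE)
  }
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- n_x * n_y / 2

  if (!ties && n <= exact_max) {
    # exact null distribution: U over all choose(n, n_x) rank assignments
    combos <- utils::combn(n, n_x)
    u_all <- colSums(matrix(seq_len(n)[combos], nrow = n_x)) -
      n_x * (n_x + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    return(list(u = u, p = p, method = "exact", n_x = n_x, n_y = n_y))
  }

  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations identical: U is degenerate at its mean
    return(list(u = u, p = 1, method = "normal_approx",
                n_x = n_x, n_y = n_y))
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
  list(u = u, p = p, method = "normal_approx", n_x = n_x, n_y = n_y)
}

#' Kruskal-Wallis rank test for three or more groups
#'
#' H statistic with tie correction, referred to the chi-square distribution
#' with k - 1 degrees of freedom. For two groups the caller is directed to
#' [mann_whitney_u()].
#'
#' @param groups list of at least three nonempty numeric vectors.
#' @param allow_two permit two groups (mainly to exercise the identity
#'   between H and the squared normal-approximation Mann-Whitney z).
#' @return list with `h`, `df`, `p`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 5
#' @export
kruskal_wallis <- function(groups, allow_two = FALSE) {
  min_groups <- if (allow_two) 2 else 3
  if (!is.list(groups) || length(groups) < min_groups) {
    stop(paste("kruskal_wallis: need at least 3 groups;",
               "use mann_whitney_u() for two"), call. = FALSE)
  }
  if (any(lengths(groups) == 0)) {
    stop("kruskal_wallis: every group must be nonempty", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  stopifnot(is.numeric(pooled), all(is.finite(pooled)))
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rank_sums <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / lengths(groups)) - 3 * (n + 1)
  tie_tab <- table(pooled)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (correction > 0) h <- h / correction
  df <- length(groups) - 1
  list(h = unname(h), df = df,
       p = stats::pchisq(h, df, lower.tail = FALSE), n = n)
}
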