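test_that("empirical ROC matches brute-force pair counting and handles ties", {
  r <- empirical_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)

  expect_equal(empirical_roc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
  expect_equal(empirical_roc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  expect_error(empirical_roc(1:4, c(1, 1, 1, 1)), "positive")
})

test_that("ROC curve runs from (sens 1, spec 0) to (sens 0, spec 1) with monotone sensitivity", {
  set.seed(41)
  for (rep_i in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(0:10, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- empirical_roc(scores, labels)
    k <- length(r$thresholds)
    expect_equal(r$sens[1], 1); expect_equal(r$spec[1], 0)
    expect_equal(r$sens[k], 0); expect_equal(r$spec[k], 1)
    expect_true(all(diff(r$sens) <= 0))
    expect_true(all(diff(r$spec) >= 0))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }
})

test_that("AUC times n_pos*n_neg equals the midrank Mann-Whitney U on random instances", {
  set.seed(1234)
  for (rep_i in 1:200) {
    n <- sample(6:40, 1)
    scores <- sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- empirical_roc(scores, labels)
    u <- mann_whitney_u(scores[labels == 1], scores[labels == 0])$u
    expect_equal(r$auc * r$n_pos * r$n_neg, u, tolerance = 1e-10)
    expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC confidence intervals (DeLong, Hanley-McNeil) agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(99)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c(1, 0), c(40, 60))
  r <- empirical_roc(scores, labels)
  ci <- auc_ci(r, 0.95, "delong")
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(labels, scores,
                                                 direction = "<")))
  expect_equal(ci$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ci$lower, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(ci$upper, as.numeric(ref[3]), tolerance = 1e-6)
  hm <- auc_ci(r, 0.95, "hanley_mcneil")
  expect_true(hm$lower < hm$auc && hm$auc < hm$upper)
})

test_that("cutoff metrics reproduce the reconstructed cohort counts and edge cases", {
  # 20 deceased of whom 18 score >= cutoff; 149 surviving, 104 below
  scores <- c(rep(6, 18), rep(3, 2), rep(6, 45), rep(3, 104))
  labels <- rep(c("deceased", "surviving"), c(20, 149))
  m <- metrics_at_cutoff(scores, labels, 5)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 104 / 149, tolerance = 1e-12)
  expect_equal(unname(m$table), c(18, 2, 45, 104))
  expect_equal(sum(m$table), 169)

  all_above <- metrics_at_cutoff(c(6, 7, 8), c(1, 0, 0), 5)
  expect_equal(all_above$sensitivity, 1)
  expect_equal(all_above$specificity, 0)
  none <- metrics_at_cutoff(c(1, 2, 3), c(1, 0, 0), 99)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)

  one_class <- metrics_at_cutoff(c(1, 2), c(1, 1), 1.5)
  expect_true("specificity" %in% one_class$undefined)
  expect_true(is.na(one_class$specificity))
})

test_that("odds ratio and Woolf interval match hand computation and invariances", {
  o <- odds_ratio(reconstructed_table())
  expect_equal(o$or, 18 * 104 / (2 * 45), tolerance = 1e-12)
  se <- sqrt(1 / 18 + 1 / 2 + 1 / 45 + 1 / 104)
  expect_equal(o$lower, exp(log(o$or) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(o$upper, exp(log(o$or) + qnorm(0.975) * se), tolerance = 1e-12)

  expect_equal(odds_ratio(c(1, 1, 1, 1))$or, 1)
  # row scaling leaves the OR unchanged
  expect_equal(odds_ratio(c(3 * 18, 3 * 2, 45, 104))$or, o$or)

  # CI ordering and widening with confidence level
  set.seed(5)
  for (i in 1:25) {
    tab <- rpois(4, 20) + 1
    o95 <- odds_ratio(tab, 0.95)
    o99 <- odds_ratio(tab, 0.99)
    expect_true(o95$lower <= o95$or && o95$or <= o95$upper)
    expect_true(o99$lower <= o95$lower && o99$upper >= o95$upper)
  }

  z <- odds_ratio(c(5, 0, 3, 7))
  expect_true(z$undefined)
  zc <- odds_ratio(c(5, 0, 3, 7), haldane = TRUE)
  expect_true(is.finite(zc$or) && zc$corrected)
})

test_that("2x2 chi-square matches the closed form, base R, and is symmetric", {
  ct <- chi_square_2x2(reconstructed_table())
  expect_equal(ct$chi2, 169 * (18 * 104 - 2 * 45)^2 / (20 * 149 * 63 * 106),
               tolerance = 1e-12)
  expect_equal(ct$w, sqrt(ct$chi2 / 169), tolerance = 1e-12)

  ref <- chisq.test(matrix(reconstructed_table(), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(ct$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-10)

  indep <- chi_square_2x2(c(10, 10, 10, 10))
  expect_equal(indep$chi2, 0); expect_equal(indep$w, 0)
  expect_equal(indep$p, 1)

  # transpose symmetry
  expect_equal(chi_square_2x2(c(18, 45, 2, 104))$chi2, ct$chi2)
  expect_error(chi_square_2x2(c(0, 0, 5, 5)), "margin")

  # Yates correction reduces the statistic
  expect_lt(chi_square_2x2(reconstructed_table(), correct = TRUE)$chi2,
            ct$chi2)
})

test_that("noncentral chi-square series matches base R and the df=1 closed form", {
  # base R pchisq(ncp) as independent oracle over a grid
  for (lam in c(0.1, 1, 5, 26.37, 80)) {
    for (x in c(0.5, 3.84, 10, 40)) {
      for (df in c(1, 3)) {
        expect_equal(pnchisq_series(x, df, lam),
                     pchisq(x, df, ncp = lam), tolerance = 1e-10)
      }
    }
  }
  # df = 1 normal closed form: P(chi2_1(lambda) <= x) =
  # Phi(sqrt(x) - sqrt(lambda)) - Phi(-sqrt(x) - sqrt(lambda))
  for (lam in c(0.5, 4, 12, 26.368225, 60)) {
    x <- qchisq(0.95, 1)
    closed <- pnorm(sqrt(x) - sqrt(lam)) - pnorm(-sqrt(x) - sqrt(lam))
    expect_equal(pnchisq_series(x, 1, lam), closed, tolerance = 1e-10)
  }
})

test_that("post-hoc power: null gives alpha, monotone in n and w, limits to 1", {
  expect_equal(posthoc_power_chi2(50, 0, 0.05)$power, 0.05, tolerance = 1e-10)
  expect_equal(posthoc_power_chi2(169, 0, 0.01)$power, 0.01, tolerance = 1e-10)

  pw_n <- vapply(c(20, 50, 100, 200, 400, 1000),
                 function(n) posthoc_power_chi2(n, 0.3)$power, numeric(1))
  expect_true(all(diff(pw_n) > 0))
  pw_w <- vapply(seq(0.05, 0.8, by = 0.05),
                 function(w) posthoc_power_chi2(169, w)$power, numeric(1))
  expect_true(all(diff(pw_w) > 0))
  expect_gt(posthoc_power_chi2(5000, 0.5)$power, 1 - 1e-12)

  p <- posthoc_power_chi2(169, 0.395)
  expect_equal(p$noncentrality_lambda, 169 * 0.395^2)
  expect_true(p$power >= p$alpha && p$power <= 1)
  expect_error(posthoc_power_chi2(169, 0.395, alpha = 1.2), "alpha")
})

test_that("Mann-Whitney U: exact enumeration, symmetry, and agreement with wilcox.test", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$u, 0)
  expect_equal(m$p, 0.1)  # 2 of choose(6,3)=20 assignments as extreme
  expect_equal(m$method, "exact")

  # identical multisets: U = n_x n_y / 2
  expect_equal(mann_whitney_u(c(1, 2, 5), c(1, 2, 5))$u, 4.5)

  # swap symmetry
  set.seed(8)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$u, 15 * 20 - b$u)
  expect_equal(a$p, b$p)

  # base R oracle (normal approximation, continuity correction, ties)
  xt <- round(rnorm(30), 1); yt <- round(rnorm(35, 0.3), 1)
  ours <- mann_whitney_u(xt, yt)
  ref <- suppressWarnings(wilcox.test(xt, yt, correct = TRUE, exact = FALSE))
  expect_equal(ours$u, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # exact case against base R exact p
  xe <- c(1.2, 3.4, 5.1, 7.7); ye <- c(2.2, 4.9, 6.3)
  ref_e <- wilcox.test(xe, ye, exact = TRUE)
  expect_equal(mann_whitney_u(xe, ye)$p, ref_e$p.value, tolerance = 1e-12)

  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney p-values are approximately uniform under the null", {
  set.seed(2024)
  reps <- 10000
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    pvals[i] <- mann_whitney_u(rnorm(20), rnorm(20))$p
  }
  ks <- max(abs(sort(pvals) - (seq_len(reps) / reps)))
  expect_lt(ks, 0.05)
})

test_that("Kruskal-Wallis: ties, identities, and base R agreement", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$h, 0)
  expect_equal(same$p, 1)

  g <- list(c(1, 2), c(3, 4), c(5, 6))
  ours <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(ours$h, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  set.seed(31)
  gt <- list(round(rnorm(12), 1), round(rnorm(15, 0.4), 1),
             round(rnorm(9, -0.2), 1))
  ours_t <- kruskal_wallis(gt)
  ref_t <- kruskal.test(gt)
  expect_equal(ours_t$h, unname(ref_t$statistic), tolerance = 1e-12)

  # two groups forced through: H equals the squared normal-approx MW z
  x <- c(1.5, 2.2, 4.8, 9.1); y <- c(3.3, 5.6, 7.7, 8.8, 10.2)
  h2 <- kruskal_wallis(list(x, y), allow_two = TRUE)
  u <- mann_whitney_u(x, y)$u
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  z <- (u - n_x * n_y / 2) / sqrt(n_x * n_y * (n + 1) / 12)
  expect_equal(h2$h, z^2, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(1:3, 4:6)), "mann_whitney_u")
  expect_error(kruskal_wallis(list(1:3, 4:6, numeric(0))), "nonempty")
})
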