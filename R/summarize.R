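#' Two-group comparison table (median/IQR or counts)
#'
#' Summarises each requested variable per outcome group the way clinical
#' two-group tables are presented: continuous variables as median
#' (25th--75th percentile), compared by the Mann-Whitney U test;
#' categorical variables as n (%) per level, compared by the chi-square
#' test. Quartiles use linear interpolation between order statistics
#' (R quantile type 7, configurable).
#'
#' @param cohort data frame, one row per patient.
#' @param group_col name of the binary grouping column
#'   (default `"outcome"`).
#' @param variables character vector of column names to summarise.
#' @param quantile_type passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return data frame with one row per continuous variable (or per level
#'   of a categorical variable): `variable`, `level`, per-group summary
#'   strings, numeric per-group `q25/q50/q75` or `n/pct`, `test`,
#'   `statistic`, `p`.
#' @export
summarize_groups <- function(cohort, group_col = "outcome", variables,
                             quantile_type = 7) {
  stopifnot(is.data.frame(cohort), group_col %in% names(cohort))
  g <- as.character(cohort[[group_col]])
  lev <- sort(unique(g))
  if (length(lev) != 2) {
    stop("summarize_groups: grouping column must have exactly two levels",
         call. = FALSE)
  }
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown) > 0) {
    stop("summarize_groups: unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      .summ_continuous(v, x, g, lev, quantile_type)
    } else {
      .summ_categorical(v, as.character(x), g, lev)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.summ_continuous <- function(v, x, g, lev, qtype) {
  qs <- lapply(lev, function(l) {
    stats::quantile(x[g == l], c(.25, .5, .75), na.rm = TRUE, type = qtype,
                    names = FALSE)
  })
  mw <- mann_whitney_u(x[g == lev[1]][!is.na(x[g == lev[1]])],
                       x[g == lev[2]][!is.na(x[g == lev[2]])])
  data.frame(
    variable = v, level = NA_character_,
    group1 = .fmt_iqr(qs[[1]]), group2 = .fmt_iqr(qs[[2]]),
    g1_q25 = qs[[1]][1], g1_q50 = qs[[1]][2], g1_q75 = qs[[1]][3],
    g2_q25 = qs[[2]][1], g2_q50 = qs[[2]][2], g2_q75 = qs[[2]][3],
    g1_n = NA_real_, g1_pct = NA_real_, g2_n = NA_real_, g2_pct = NA_real_,
    test = "mann_whitney", statistic = mw$u, p = mw$p,
    stringsAsFactors = FALSE
  )
}

.summ_categorical <- function(v, x, g, lev) {
  tab <- table(factor(x), factor(g, levels = lev))
  if (nrow(tab) < 2) {
    chi2 <- NA_real_; p <- NA_real_
  } else if (nrow(tab) == 2) {
    ct <- chi_square_2x2(c(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]))
    chi2 <- ct$chi2; p <- ct$p
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  do.call(rbind, lapply(rownames(tab), function(l) {
    n1 <- tab[l, 1]; n2 <- tab[l, 2]
    p1 <- 100 * n1 / sum(tab[, 1]); p2 <- 100 * n2 / sum(tab[, 2])
    data.frame(
      variable = v, level = l,
      group1 = sprintf("%d (%.2f%%)", n1, p1),
      group2 = sprintf("%d (%.2f%%)", n2, p2),
      g1_q25 = NA_real_, g1_q50 = NA_real_, g1_q75 = NA_real_,
      g2_q25 = NA_real_, g2_q50 = NA_real_, g2_q75 = NA_real_,
      g1_n = as.numeric(n1), g1_pct = p1,
      g2_n = as.numeric(n2), g2_pct = p2,
      test = "chi_square", statistic = chi2, p = p,
      stringsAsFactors = FALSE
    )
  }))
}

.fmt_iqr <- function(q) {
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}
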