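#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object.
#'
#' @param crp_unit unit of the CRP column in input CSVs.
#' @param fgmi_cutoff FGMI high-risk cutoff (test-positive means total at
#'   or above this; default 5).
#' @param ci_level confidence level for all intervals.
#' @param alpha significance level used in the post-hoc power analysis.
#' @param seed integer seed recorded in the report and used for any
#'   simulation the caller couples to this config.
#' @param auc_ci_method `"delong"` or `"hanley_mcneil"`.
#' @param chi_correct Yates continuity correction for the 2x2 chi-square.
#' @param haldane Haldane-Anscombe 0.5 correction for zero cells in the
#'   odds ratio.
#' @param min_group_n smallest per-outcome group size for which the
#'   inference sections are attempted; below it they are reported as
#'   `"insufficient n"`.
#' @return object of class `fg_config`.
#' @export
analysis_config <- function(crp_unit = c("mg_dl", "mg_l"), fgmi_cutoff = 5,
                            ci_level = 0.95, alpha = 0.05, seed = 1L,
                            auc_ci_method = c("delong", "hanley_mcneil"),
                            chi_correct = FALSE, haldane = FALSE,
                            min_group_n = 2) {
  crp_unit <- match.arg(crp_unit)
  auc_ci_method <- match.arg(auc_ci_method)
  stopifnot(fgmi_cutoff > 0, ci_level > 0, ci_level < 1,
            alpha > 0, alpha < 1, min_group_n >= 1)
  structure(
    list(crp_unit = crp_unit, fgmi_cutoff = fgmi_cutoff,
         ci_level = ci_level, alpha = alpha, seed = as.integer(seed),
         auc_ci_method = auc_ci_method, chi_correct = chi_correct,
         haldane = haldane, min_group_n = min_group_n),
    class = "fg_config"
  )
}

# lab columns summarised in the Table-4-style comparison, in display order
.lab_vars <- c("crp", "wbc", "hemoglobin", "sodium", "creatinine",
               "glucose", "platelets", "albumin", "neutrophils",
               "neutrophil_pct", "lymphocytes", "lymphocyte_pct",
               "monocytes", "monocyte_pct", "eosinophils",
               "eosinophil_pct", "nlr", "mlr", "plr", "crp_alb_ratio")

#' Run the full scoring and validation analysis
#'
#' Executes the complete workflow on a cohort: FGMI and LRINEC scores for
#' every patient, demographic and laboratory group comparisons, the FGMI
#' ROC curve with AUC confidence interval, sensitivity/specificity and the
#' 2x2 table at the FGMI cutoff, the odds ratio with Woolf interval, the
#' chi-square test with Cohen's w, the post-hoc power at the observed
#' sample size, and a logistic regression of outcome on the five FGMI
#' parameters with Hosmer-Lemeshow fit. When either outcome group is
#' smaller than `config$min_group_n` the inference sections are replaced
#' by the marker `"insufficient n"`.
#'
#' @param cohort data frame in internal column names (from
#'   [read_cohort()] or [generate_cohort()]), or a path to a cohort CSV.
#' @param config an [analysis_config()].
#' @return object of class `fg_report`: nested list with elements
#'   `config`, `n`, `group_sizes`, `scores` (FGMI and LRINEC cohort
#'   scorings), `demographics`, `labs`, `roc`, `cutoff`, `odds_ratio`,
#'   `chi_square`, `power`, `logistic`, `notes`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "fg_config"))
  if (is.character(cohort)) {
    cohort <- read_cohort(cohort, crp_unit = config$crp_unit)
  }
  if (!"outcome" %in% names(cohort) ||
      length(unique(stats::na.omit(cohort$outcome))) < 2) {
    stop("run_full_analysis: cohort must contain both outcome groups",
         call. = FALSE)
  }
  notes <- character(0)

  fgmi <- score_cohort(cohort, "FGMI")
  lrinec <- score_cohort(cohort, "LRINEC")
  group_sizes <- table(cohort$outcome)

  demo_vars <- intersect(c("age", "sex", "comorbidity", "polymicrobial"),
                         names(cohort))
  demographics <- summarize_groups(cohort, "outcome", demo_vars)
  lab_vars <- intersect(.lab_vars, names(cohort))
  labs <- summarize_groups(cohort, "outcome", lab_vars)

  lrinec_bands <- NULL
  if (!is.null(lrinec$band_counts)) {
    lrinec_bands <- lrinec$band_counts
  }

  small <- min(group_sizes) < config$min_group_n
  if (small || is.null(fgmi$scores)) {
    notes <- c(notes, "inference sections skipped: insufficient n")
    roc <- cutoff <- or <- chi2 <- power <- logistic <- "insufficient n"
  } else {
    sc <- fgmi$scores
    roc_obj <- empirical_roc(sc$total, sc$outcome)
    roc <- list(curve = roc_obj,
                ci = auc_ci(roc_obj, config$ci_level, config$auc_ci_method))
    cutoff <- metrics_at_cutoff(sc$total, sc$outcome, config$fgmi_cutoff)
    or <- odds_ratio(cutoff$table, config$ci_level, haldane = config$haldane)
    chi2 <- tryCatch(
      chi_square_2x2(cutoff$table, correct = config$chi_correct),
      error = function(e) {
        notes <<- c(notes, paste("chi-square:", conditionMessage(e)))
        NULL
      })
    power <- if (!is.null(chi2)) {
      posthoc_power_chi2(chi2$n, chi2$w, config$alpha, df = 1)
    }
    logistic <- tryCatch({
      keep <- stats::complete.cases(
        cohort[, c(.fgmi_parameters, "outcome")])
      design <- as.matrix(cohort[keep, .fgmi_parameters])
      logistic_fit(design, cohort$outcome[keep] == "deceased",
                   conf_level = config$ci_level)
    }, error = function(e) {
      notes <<- c(notes, paste("logistic:", conditionMessage(e)))
      paste("not fitted:", conditionMessage(e))
    })
  }

  structure(
    list(config = config, n = nrow(cohort),
         group_sizes = as.list(group_sizes),
         scores = list(fgmi = fgmi, lrinec = lrinec),
         demographics = demographics, labs = labs,
         lrinec_bands = lrinec_bands,
         roc = roc, cutoff = cutoff, odds_ratio = or,
         chi_square = chi2, power = power, logistic = logistic,
         notes = notes),
    class = "fg_report"
  )
}

#' Serialise an analysis report to JSON
#'
#' Writes the machine-readable form of an `fg_report` with full numeric
#' precision. Output is deterministic: identical cohort, config, and seed
#' give byte-identical files.
#'
#' @param report an `fg_report` from [run_full_analysis()].
#' @param path output file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_analysis_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "fg_report"))
  insufficient <- identical(report$roc, "insufficient n")
  x <- list(
    config = unclass(report$config),
    n = report$n,
    group_sizes = report$group_sizes,
    fgmi = list(
      scored = if (is.null(report$scores$fgmi$scores)) 0
               else nrow(report$scores$fgmi$scores),
      unscorable = nrow(report$scores$fgmi$unscorable),
      scores = report$scores$fgmi$scores
    ),
    lrinec = list(
      scored = if (is.null(report$scores$lrinec$scores)) 0
               else nrow(report$scores$lrinec$scores),
      unscorable = nrow(report$scores$lrinec$unscorable),
      scores = report$scores$lrinec$scores
    ),
    demographics = report$demographics,
    labs = report$labs,
    validation = if (insufficient) "insufficient n" else list(
      auc = report$roc$ci$auc,
      auc_ci = c(report$roc$ci$lower, report$roc$ci$upper),
      auc_ci_method = report$roc$ci$method,
      sensitivity = report$cutoff$sensitivity,
      specificity = report$cutoff$specificity,
      table_2x2 = as.list(report$cutoff$table),
      odds_ratio = report$odds_ratio[c("or", "lower", "upper")],
      chi_square = report$chi_square[c("chi2", "df", "p", "w")],
      power = unclass(report$power)
    ),
    notes = report$notes
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null", na = "null",
                           pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @export
print.fg_report <- function(x, ...) {
  cat("Fournier's gangrene cohort analysis\n")
  cat(sprintf("  n = %d (%s)\n", x$n,
              paste(sprintf("%s %d", names(x$group_sizes),
                            unlist(x$group_sizes)), collapse = ", ")))
  if (identical(x$roc, "insufficient n")) {
    cat("  inference: insufficient n\n")
  } else {
    cat(sprintf("  FGMI AUC %.3f (%d%% CI %.3f-%.3f, %s)\n",
                x$roc$ci$auc, round(100 * x$roc$ci$conf_level),
                x$roc$ci$lower, x$roc$ci$upper, x$roc$ci$method))
    cat(sprintf("  at cutoff %g: sensitivity %.1f%%, specificity %.1f%%\n",
                x$cutoff$cutoff, 100 * x$cutoff$sensitivity,
                100 * x$cutoff$specificity))
    if (isTRUE(x$odds_ratio$undefined)) {
      cat("  odds ratio undefined (zero cell; Haldane correction off)\n")
    } else {
      cat(sprintf("  odds ratio %.2f (%.2f-%.2f)\n", x$odds_ratio$or,
                  x$odds_ratio$lower, x$odds_ratio$upper))
    }
    cat(sprintf("  chi2 %.2f (w = %.3f), post-hoc power %.5f\n",
                x$chi_square$chi2, x$chi_square$w, x$power$power))
  }
  for (n_ in x$notes) cat("  note:", n_, "\n")
  invisible(x)
}
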