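#' Score every record of a cohort under one rubric
#'
#' Applies [fgmi_score()] or [lrinec_score()] row by row, preserving input
#' order. Records missing a required input are reported as unscorable (with
#' the missing field names) rather than imputed or silently dropped.
#'
#' @param cohort data frame, one row per patient, with the lab columns the
#'   rubric needs (internal units: CRP in mg/L) and optionally `patient_id`
#'   and `outcome`.
#' @param rubric `"FGMI"` or `"LRINEC"`.
#' @return an object of class `fg_cohort_scores`: list with
#'   \describe{
#'     \item{scores}{data frame of scorable rows: `patient_id`, `rubric`,
#'       one column per component, `total`, `band`, and `outcome` when
#'       present in the input.}
#'     \item{unscorable}{data frame `patient_id`, `missing_fields` for the
#'       rows that could not be scored.}
#'     \item{band_counts}{table of band by outcome (when outcome present)
#'       for downstream 2x2 construction.}
#'   }
#' @export
score_cohort <- function(cohort, rubric = c("FGMI", "LRINEC")) {
  rubric <- match.arg(rubric)
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("score_cohort: 'cohort' must be a nonempty data frame",
         call. = FALSE)
  }
  scorer <- if (rubric == "FGMI") fgmi_score else lrinec_score
  ids <- if ("patient_id" %in% names(cohort)) {
    as.character(cohort$patient_id)
  } else {
    sprintf("row%d", seq_len(nrow(cohort)))
  }
  res <- lapply(seq_len(nrow(cohort)), function(i) scorer(cohort[i, ]))
  ok <- vapply(res, function(r) inherits(r, "fg_score"), logical(1))

  scores <- NULL
  if (any(ok)) {
    comp <- do.call(rbind, lapply(res[ok], function(r) r$component_points))
    scores <- data.frame(
      patient_id = ids[ok],
      rubric = rubric,
      comp,
      total = vapply(res[ok], `[[`, integer(1), "total"),
      band = vapply(res[ok], `[[`, character(1), "band"),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
    if ("outcome" %in% names(cohort)) {
      scores$outcome <- as.character(cohort$outcome)[ok]
    }
  }
  unscorable <- data.frame(
    patient_id = ids[!ok],
    missing_fields = vapply(res[!ok], function(r)
      paste(r$missing, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  band_counts <- NULL
  if (!is.null(scores) && "outcome" %in% names(scores)) {
    band_counts <- table(band = scores$band, outcome = scores$outcome)
  }
  structure(
    list(scores = scores, unscorable = unscorable,
         band_counts = band_counts),
    class = "fg_cohort_scores"
  )
}

#' @export
print.fg_cohort_scores <- function(x, ...) {
  n_ok <- if (is.null(x$scores)) 0 else nrow(x$scores)
  cat(sprintf("Cohort scoring (%s): %d scored, %d unscorable\n",
              if (n_ok > 0) x$scores$rubric[1] else "?",
              n_ok, nrow(x$unscorable)))
  if (!is.null(x$band_counts)) {
    print(x$band_counts)
  }
  invisible(x)
}

#' 2x2 outcome-by-band contingency table at a score cutoff
#'
#' Builds the table that drives odds-ratio, chi-square, and power analyses:
#' rows are outcome (positive = `positive_label`), columns are test result
#' (positive = total score at or above `cutoff`). Cell `a` counts
#' outcome-positive/test-positive, `b` outcome-positive/test-negative,
#' `c` outcome-negative/test-positive, `d` outcome-negative/test-negative.
#'
#' @param totals numeric vector of total scores.
#' @param outcomes vector of outcome labels.
#' @param cutoff numeric; test-positive means `totals >= cutoff`.
#' @param positive_label outcome level counted as positive
#'   (default `"deceased"`).
#' @return named integer vector `c(a, b, c, d)`.
#' @export
band_table_2x2 <- function(totals, outcomes, cutoff = 5,
                           positive_label = "deceased") {
  stopifnot(length(totals) == length(outcomes), is.finite(cutoff))
  pos <- outcomes == positive_label
  test_pos <- totals >= cutoff
  c(a = sum(pos & test_pos), b = sum(pos & !test_pos),
    c = sum(!pos & test_pos), d = sum(!pos & !test_pos))
}
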