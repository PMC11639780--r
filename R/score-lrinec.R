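#' LRINEC score and risk band
#'
#' Computes the Laboratory Risk Indicator for Necrotizing Fasciitis from six
#' routine labs, using the standard component rubric of Wong et al.:
#' \describe{
#'   \item{CRP (mg/L)}{\eqn{\ge 150}: 4; otherwise 0}
#'   \item{WBC (10^3/uL)}{\eqn{< 15}: 0; 15--25: 1; \eqn{> 25}: 2}
#'   \item{Hemoglobin (g/dL)}{\eqn{> 13.5}: 0; 11--13.5: 1; \eqn{< 11}: 2}
#'   \item{Sodium (mmol/L)}{\eqn{< 135}: 2; otherwise 0}
#'   \item{Creatinine (mg/dL)}{\eqn{> 1.6}: 2; otherwise 0}
#'   \item{Glucose (mg/dL)}{\eqn{> 180}: 1; otherwise 0}
#' }
#' The total ranges 0--13 and is banded as low (\eqn{\le 5}), moderate
#' (6--7), or high (\eqn{\ge 8}).
#'
#' CRP must be supplied in mg/L. Cohort files whose CRP column is recorded
#' in mg/dL are converted (x 10) at read time; see [read_cohort()].
#'
#' @param record list or one-row data frame with numeric fields `crp`
#'   (mg/L), `wbc` (10^3/uL), `hemoglobin` (g/dL), `sodium` (mmol/L),
#'   `creatinine` (mg/dL), `glucose` (mg/dL).
#' @return an `fg_score` object (see [fgmi_score()]) with rubric
#'   `"LRINEC"`, or an `fg_unscorable` object if any input is missing.
#' @examples
#' lrinec_score(list(crp = 294.7, wbc = 19.49, hemoglobin = 11.25,
#'                   sodium = 131, creatinine = 1.5, glucose = 170.5))
#' @export
lrinec_score <- function(record) {
  record <- as.list(record)
  fields <- c("crp", "wbc", "hemoglobin", "sodium", "creatinine", "glucose")
  missing <- .missing_fields(record, fields)
  if (length(missing) > 0) {
    return(.unscorable("LRINEC", missing))
  }
  v <- lapply(record[fields], as.numeric)
  if (any(vapply(v, function(x) !is.finite(x) || x < 0, logical(1)))) {
    stop("lrinec_score: all inputs must be finite and nonnegative",
         call. = FALSE)
  }
  pts <- c(
    crp        = if (v$crp >= 150) 4L else 0L,
    wbc        = if (v$wbc > 25) 2L else if (v$wbc >= 15) 1L else 0L,
    hemoglobin = if (v$hemoglobin < 11) 2L
                 else if (v$hemoglobin <= 13.5) 1L else 0L,
    sodium     = if (v$sodium < 135) 2L else 0L,
    creatinine = if (v$creatinine > 1.6) 2L else 0L,
    glucose    = if (v$glucose > 180) 1L else 0L
  )
  total <- sum(pts)
  structure(
    list(
      rubric = "LRINEC",
      component_points = pts,
      total = as.integer(total),
      band = if (total >= 8) "high" else if (total >= 6) "moderate" else "low"
    ),
    class = "fg_score"
  )
}
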