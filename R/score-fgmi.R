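#' FGMI component points for a single parameter
#'
#' The Fournier's Gangrene Mortality Index (FGMI) awards 0, 1, or 2 points to
#' each of five preoperative parameters. The published rubric prints three
#' bands per parameter; because the printed bands leave small gaps (e.g.
#' albumin between 2.5 and 2.6 g/dL, lymphocyte percentages between 9 and
#' 10), each parameter is interpreted here as three ordered regions defined
#' only by its severe and benign thresholds, the middle band being the
#' complement. Every printed band value receives the printed points and
#' every positive real value receives exactly one score.
#'
#' The bands are:
#' \describe{
#'   \item{age}{\eqn{\ge 60} years: 2; \eqn{< 40}: 0; otherwise 1}
#'   \item{creatinine}{\eqn{\ge 1.5} mg/dL: 2; \eqn{< 1.0}: 0; otherwise 1}
#'   \item{albumin}{\eqn{\le 2.5} g/dL: 2; \eqn{\ge 3.1}: 0; otherwise 1}
#'   \item{lymphocyte_pct}{\eqn{\le 5}\%: 2; \eqn{\ge 10}\%: 0; otherwise 1}
#'   \item{nlr}{\eqn{\ge 15}: 2; \eqn{< 10}: 0; otherwise 1}
#' }
#'
#' @param parameter one of `"age"`, `"creatinine"`, `"albumin"`,
#'   `"lymphocyte_pct"`, `"nlr"`.
#' @param value numeric vector of finite parameter values; percentages must
#'   lie in (0, 100].
#' @return integer vector of points in \{0, 1, 2\}.
#' @examples
#' fgmi_component_score("age", 64.5)        # 2
#' fgmi_component_score("creatinine", 0.99) # 0
#' fgmi_component_score("lymphocyte_pct", 9.56) # 1 (gap value)
#' @export
fgmi_component_score <- function(parameter, value) {
  parameter <- match.arg(parameter, names(.fgmi_bands))
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("fgmi_component_score: 'value' must be finite numeric", call. = FALSE)
  }
  if (parameter == "lymphocyte_pct" && any(value <= 0 | value > 100)) {
    stop("fgmi_component_score: percentage out of (0, 100]", call. = FALSE)
  }
  b <- .fgmi_bands[[parameter]]
  if (b$direction == "high_bad") {
    pts <- ifelse(value >= b$severe, 2L, ifelse(value < b$benign, 0L, 1L))
  } else {
    pts <- ifelse(value <= b$severe, 2L, ifelse(value >= b$benign, 0L, 1L))
  }
  as.integer(pts)
}

# severe = threshold of the 2-point band, benign = threshold of the 0-point
# band; the 1-point band is the complement between them.
.fgmi_bands <- list(
  age            = list(direction = "high_bad", severe = 60,  benign = 40),
  creatinine     = list(direction = "high_bad", severe = 1.5, benign = 1.0),
  albumin        = list(direction = "low_bad",  severe = 2.5, benign = 3.1),
  lymphocyte_pct = list(direction = "low_bad",  severe = 5,   benign = 10),
  nlr            = list(direction = "high_bad", severe = 15,  benign = 10)
)

.fgmi_parameters <- names(.fgmi_bands)

#' FGMI total score and risk band
#'
#' Sums the five FGMI component scores (total 0--10) and assigns the risk
#' band: totals of 5 or more are high mortality risk, below 5
#' low-to-moderate.
#'
#' @param record a list or one-row data frame with numeric fields `age`,
#'   `creatinine` (mg/dL), `albumin` (g/dL), `lymphocyte_pct`, `nlr`.
#' @return an object of class `fg_score`: list with `rubric`,
#'   `component_points` (named integer vector), `total`, `band`.
#'   If any of the five inputs is missing the record is unscorable and a
#'   `fg_unscorable` object is returned instead, naming the missing fields.
#' @examples
#' fgmi_score(list(age = 64.5, creatinine = 1.5, albumin = 2.68,
#'                 lymphocyte_pct = 4.81, nlr = 18.21))  # total 9, high
#' @export
fgmi_score <- function(record) {
  record <- as.list(record)
  missing <- .missing_fields(record, .fgmi_parameters)
  if (length(missing) > 0) {
    return(.unscorable("FGMI", missing))
  }
  pts <- vapply(
    .fgmi_parameters,
    function(p) fgmi_component_score(p, as.numeric(record[[p]])),
    integer(1)
  )
  total <- sum(pts)
  structure(
    list(
      rubric = "FGMI",
      component_points = pts,
      total = as.integer(total),
      band = if (total >= 5) "high" else "low_moderate"
    ),
    class = "fg_score"
  )
}

.missing_fields <- function(record, fields) {
  fields[vapply(
    fields,
    function(f) is.null(record[[f]]) || length(record[[f]]) == 0 ||
      is.na(record[[f]]),
    logical(1)
  )]
}

.unscorable <- function(rubric, missing) {
  structure(
    list(rubric = rubric, missing = missing),
    class = "fg_unscorable"
  )
}

#' @export
print.fg_score <- function(x, ...) {
  cat(sprintf("%s score: %d (%s risk)\n", x$rubric, x$total, x$band))
  comp <- paste(sprintf("%s=%d", names(x$component_points), x$component_points),
                collapse = ", ")
  cat(" components:", comp, "\n")
  invisible(x)
}

#' @export
print.fg_unscorable <- function(x, ...) {
  cat(sprintf("%s: unscorable (missing: %s)\n", x$rubric,
              paste(x$missing, collapse = ", ")))
  invisible(x)
}
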