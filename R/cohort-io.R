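# CSV schema: external column name -> internal name. CRP is handled
# separately because its external unit is configurable.
.schema_map <- c(
  age                  = "age",
  creatinine_mg_dl     = "creatinine",
  albumin_g_dl         = "albumin",
  lymphocyte_pct       = "lymphocyte_pct",
  nlr                  = "nlr",
  crp                  = "crp",
  wbc_10e3_ul          = "wbc",
  hemoglobin_g_dl      = "hemoglobin",
  sodium_mmol_l        = "sodium",
  glucose_mg_dl        = "glucose",
  platelets_10e3_ul    = "platelets",
  neutrophil_pct       = "neutrophil_pct",
  neutrophils_10e3_ul  = "neutrophils",
  lymphocytes_10e3_ul  = "lymphocytes",
  monocyte_pct         = "monocyte_pct",
  monocytes_10e3_ul    = "monocytes",
  eosinophil_pct       = "eosinophil_pct",
  eosinophils_10e3_ul  = "eosinophils",
  mlr                  = "mlr",
  plr                  = "plr",
  crp_alb_ratio        = "crp_alb_ratio"
)
.schema_mandatory <- c("patient_id", "outcome", "age", "creatinine_mg_dl",
                       "albumin_g_dl", "lymphocyte_pct", "nlr", "crp",
                       "wbc_10e3_ul", "hemoglobin_g_dl", "sodium_mmol_l",
                       "glucose_mg_dl")
.schema_character <- c("patient_id", "outcome", "sex", "comorbidity",
                       "polymicrobial")

#' Read a patient cohort CSV
#'
#' Reads the cohort schema (one header row, UTF-8, `.` decimal separator):
#' `patient_id`, `outcome` (deceased/surviving), `age`,
#' `creatinine_mg_dl`, `albumin_g_dl`, `lymphocyte_pct`, `nlr`, `crp`,
#' `wbc_10e3_ul`, `hemoglobin_g_dl`, `sodium_mmol_l`, `glucose_mg_dl`,
#' plus optional extended-lab and categorical columns. Empty cells are
#' missing values. CRP is converted to the internal unit (mg/L) according
#' to `crp_unit`; everything downstream of this reader works in mg/L.
#'
#' Malformed numeric cells are set to `NA` and collected, with row and
#' column, in the `issues` attribute. Lab values must be strictly
#' positive; percentages must lie in (0, 100]. When neutrophil %,
#' lymphocyte %, and NLR are all present but NLR differs from their ratio
#' by more than 5% relative, a validation warning is raised (the record is
#' kept).
#'
#' @param path CSV file path.
#' @param crp_unit unit of the `crp` column: `"mg_dl"` (default, x 10 on
#'   read) or `"mg_l"`.
#' @return data frame in internal column names, with attribute `issues`
#'   (data frame `row`, `column`, `value`) when malformed cells were seen.
#' @export
read_cohort <- function(path, crp_unit = c("mg_dl", "mg_l")) {
  crp_unit <- match.arg(crp_unit)
  if (!file.exists(path)) {
    stop("read_cohort: file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("read_cohort: empty file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) {
    stop("read_cohort: no data rows in ", path, call. = FALSE)
  }
  missing_cols <- setdiff(.schema_mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_cohort: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  known <- c(names(.schema_map), .schema_character)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("read_cohort: ignoring unknown column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }

  issues <- list()
  out <- data.frame(patient_id = raw$patient_id,
                    outcome = raw$outcome, stringsAsFactors = FALSE)
  bad_outcome <- !(out$outcome %in% c("deceased", "surviving")) &
    out$outcome != "" & !is.na(out$outcome)
  if (any(bad_outcome)) {
    stop("read_cohort: outcome must be 'deceased' or 'surviving' (row ",
         which(bad_outcome)[1], ")", call. = FALSE)
  }
  for (ext in intersect(names(.schema_map), names(raw))) {
    int <- .schema_map[[ext]]
    txt <- raw[[ext]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & txt != "" & is.na(val)
    if (any(bad)) {
      issues[[length(issues) + 1]] <- data.frame(
        row = which(bad), column = ext, value = txt[bad],
        stringsAsFactors = FALSE)
    }
    out[[int]] <- val
  }
  for (cc in intersect(setdiff(.schema_character, c("patient_id", "outcome")),
                       names(raw))) {
    v <- raw[[cc]]
    v[v == ""] <- NA_character_
    out[[cc]] <- v
  }
  if (crp_unit == "mg_dl" && "crp" %in% names(out)) {
    out$crp <- out$crp * 10
  }
  .validate_cohort(out)
  if (length(issues) > 0) {
    attr(out, "issues") <- do.call(rbind, issues)
  }
  out
}

.validate_cohort <- function(cohort) {
  labs <- intersect(unname(.schema_map), names(cohort))
  for (v in labs) {
    x <- cohort[[v]]
    if (any(!is.na(x) & x <= 0)) {
      stop("cohort validation: nonpositive value in '", v, "' (row ",
           which(!is.na(x) & x <= 0)[1], ")", call. = FALSE)
    }
  }
  for (v in intersect(c("lymphocyte_pct", "neutrophil_pct", "monocyte_pct",
                        "eosinophil_pct"), names(cohort))) {
    x <- cohort[[v]]
    if (any(!is.na(x) & x > 100)) {
      stop("cohort validation: percentage above 100 in '", v, "' (row ",
           which(!is.na(x) & x > 100)[1], ")", call. = FALSE)
    }
  }
  if (all(c("neutrophil_pct", "lymphocyte_pct", "nlr") %in% names(cohort))) {
    with_all <- stats::complete.cases(
      cohort[, c("neutrophil_pct", "lymphocyte_pct", "nlr")])
    if (any(with_all)) {
      implied <- cohort$neutrophil_pct[with_all] /
        cohort$lymphocyte_pct[with_all]
      rel <- abs(cohort$nlr[with_all] - implied) / implied
      if (any(rel > 0.05)) {
        warning("cohort validation: NLR differs from neutrophil%/",
                "lymphocyte% by more than 5% in ", sum(rel > 0.05),
                " record(s)", call. = FALSE)
      }
    }
  }
  invisible(cohort)
}

#' Write a patient cohort CSV
#'
#' Inverse of [read_cohort()]: maps internal column names back to the
#' cohort CSV schema and converts CRP from the internal mg/L to the
#' declared output unit. Numeric cells are formatted with 10 significant
#' digits, so a write/read round trip is idempotent.
#'
#' @param cohort data frame in internal column names (CRP in mg/L).
#' @param path output CSV path.
#' @param crp_unit unit for the written `crp` column.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, crp_unit = c("mg_dl", "mg_l")) {
  crp_unit <- match.arg(crp_unit)
  stopifnot(is.data.frame(cohort))
  out <- data.frame(patient_id = cohort$patient_id,
                    outcome = cohort$outcome, stringsAsFactors = FALSE)
  rev_map <- stats::setNames(names(.schema_map), .schema_map)
  for (int in intersect(unname(.schema_map), names(cohort))) {
    x <- cohort[[int]]
    if (int == "crp" && crp_unit == "mg_dl") x <- x / 10
    out[[rev_map[[int]]]] <- ifelse(is.na(x), "", sprintf("%.10g", x))
  }
  for (cc in intersect(setdiff(.schema_character, c("patient_id", "outcome")),
                       names(cohort))) {
    out[[cc]] <- cohort[[cc]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
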