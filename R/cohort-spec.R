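#' Fit a lognormal distribution to a quartile triplet
#'
#' Given a variable's 25th/50th/75th percentiles, returns the lognormal
#' parameters that reproduce them: mu = ln(q50) and
#' sigma = (ln(q75) - ln(q25)) / (2 z_0.75) where z_0.75 is the standard
#' normal upper quartile (0.67449). A degenerate triplet (q25 = q75)
#' yields sigma = 0, a point mass at the median.
#'
#' @param q25,q50,q75 strictly positive quartiles, q25 <= q50 <= q75.
#' @return list with `mu`, `sigma`.
#' @examples
#' fit_lognormal_from_quartiles(14.24, 18.21, 24.56)
#' @export
fit_lognormal_from_quartiles <- function(q25, q50, q75) {
  if (any(c(q25, q50, q75) <= 0)) {
    stop("fit_lognormal_from_quartiles: quartiles must be strictly positive",
         call. = FALSE)
  }
  if (!(q25 <= q50 && q50 <= q75)) {
    stop("fit_lognormal_from_quartiles: quartiles must be ordered",
         call. = FALSE)
  }
  list(mu = log(q50), sigma = (log(q75) - log(q25)) / (2 * stats::qnorm(0.75)))
}

#' Synthetic cohort specification
#'
#' Bundles everything the generator needs: group sizes, per-group quartile
#' triplets for each sampled lab, a rank-correlation plan for the Gaussian
#' copula, per-group categorical prevalences, and a seed.
#'
#' @param n_deceased,n_surviving group sizes (>= 1).
#' @param quartiles named list with elements `deceased` and `surviving`,
#'   each a named list of numeric triplets `c(q25, q50, q75)`.
#' @param rank_correlations data frame with columns `var1`, `var2`, `rho`
#'   (Spearman rank correlations imposed via the copula); unlisted pairs
#'   are independent.
#' @param prevalences named list with elements `deceased` and `surviving`,
#'   each a named numeric vector of probabilities (e.g. `male`,
#'   `comorbidity`, `polymicrobial`).
#' @param seed integer RNG seed.
#' @return object of class `fg_cohort_spec`.
#' @seealso [default_cohort_spec()] for the FGMI development-cohort
#'   calibration, [generate_cohort()].
#' @export
cohort_spec <- function(n_deceased, n_surviving, quartiles,
                        rank_correlations = NULL, prevalences = NULL,
                        seed = 1L) {
  stopifnot(n_deceased >= 1, n_surviving >= 1)
  for (grp in c("deceased", "surviving")) {
    if (is.null(quartiles[[grp]])) {
      stop("cohort_spec: quartiles must contain '", grp, "'", call. = FALSE)
    }
    for (v in names(quartiles[[grp]])) {
      q <- quartiles[[grp]][[v]]
      if (length(q) != 3 || any(!is.finite(q)) || is.unsorted(q)) {
        stop("cohort_spec: bad quartile triplet for ", grp, "$", v,
             call. = FALSE)
      }
    }
  }
  required <- c("age", "creatinine", "albumin", "lymphocyte_pct",
                "neutrophil_pct", "crp", "wbc", "hemoglobin", "sodium",
                "glucose")
  for (grp in c("deceased", "surviving")) {
    miss <- setdiff(required, names(quartiles[[grp]]))
    if (length(miss) > 0) {
      stop("cohort_spec: ", grp, " group missing required variable(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_deceased = as.integer(n_deceased),
         n_surviving = as.integer(n_surviving),
         quartiles = quartiles,
         rank_correlations = rank_correlations,
         prevalences = prevalences,
         seed = as.integer(seed)),
    class = "fg_cohort_spec"
  )
}

#' Default synthetic-cohort calibration
#'
#' Returns an [cohort_spec()] calibrated to the FGMI development cohort:
#' 20 deceased and 149 surviving patients, per-group quartile triplets for
#' every preoperative lab summarised in that cohort (CRP recorded in
#' mg/dL), categorical prevalences (sex, comorbidity, polymicrobial
#' culture), and a default rank-correlation plan of +0.6 between
#' neutrophil percentage and WBC and -0.8 between neutrophil and
#' lymphocyte percentages.
#'
#' Derived indices (NLR, MLR, PLR, CRP/albumin, differential counts) carry
#' their published triplets in the spec for reference, but the generator
#' always computes them from their components; their distributions emerge
#' from the sampled marginals and the copula rather than being imposed.
#'
#' @param seed integer RNG seed stored in the spec.
#' @return an `fg_cohort_spec` object.
#' @export
default_cohort_spec <- function(seed = 1L) {
  deceased <- list(
    age            = c(56, 64.50, 80),
    crp            = c(14.91, 29.47, 37.55),   # mg/dL
    wbc            = c(14.80, 19.49, 24.27),
    hemoglobin     = c(8.88, 11.25, 12.80),
    sodium         = c(128, 131, 134.50),
    creatinine     = c(1.00, 1.50, 2.01),
    glucose        = c(106, 170.50, 263.50),
    platelets      = c(186, 271, 380.50),
    albumin        = c(2.35, 2.68, 3.00),
    neutrophil_pct = c(84.77, 89.85, 91.62),
    lymphocyte_pct = c(3.80, 4.81, 6.28),
    monocyte_pct   = c(2.39, 3.91, 4.84),
    eosinophil_pct = c(0.02, 0.04, 0.21),
    # reference triplets for derived indices (not sampled)
    neutrophils    = c(13.26, 15.75, 22.20),
    lymphocytes    = c(0.48, 0.83, 1.17),
    monocytes      = c(0.44, 0.60, 1.07),
    eosinophils    = c(0.001, 0.01, 0.03),
    nlr            = c(14.24, 18.21, 24.56),
    mlr            = c(0.45, 0.86, 1.29),
    plr            = c(227.27, 371.70, 532.79),
    crp_alb_ratio  = c(6.28, 11.19, 13.75)
  )
  surviving <- list(
    age            = c(39, 51, 60),
    crp            = c(9.90, 20.76, 30.50),
    wbc            = c(11.60, 16.00, 20.40),
    hemoglobin     = c(10.30, 11.80, 13.20),
    sodium         = c(130, 134, 138),
    creatinine     = c(0.70, 0.90, 1.17),
    glucose        = c(106, 168, 338),
    platelets      = c(238, 301, 395),
    albumin        = c(2.75, 3.20, 3.68),
    neutrophil_pct = c(74.51, 82.50, 86.74),
    lymphocyte_pct = c(6.99, 9.56, 15.32),
    monocyte_pct   = c(4.80, 6.30, 8.39),
    eosinophil_pct = c(0.10, 0.37, 1.14),
    neutrophils    = c(8.50, 13.53, 17.29),
    lymphocytes    = c(1.09, 1.60, 2.27),
    monocytes      = c(0.69, 0.96, 1.35),
    eosinophils    = c(0.01, 0.05, 0.12),
    nlr            = c(4.73, 8.55, 12.47),
    mlr            = c(0.37, 0.65, 0.97),
    plr            = c(132.98, 185.33, 297.59),
    crp_alb_ratio  = c(2.77, 7.15, 9.28)
  )
  cohort_spec(
    n_deceased = 20, n_surviving = 149,
    quartiles = list(deceased = deceased, surviving = surviving),
    rank_correlations = data.frame(
      var1 = c("neutrophil_pct", "neutrophil_pct"),
      var2 = c("wbc", "lymphocyte_pct"),
      rho = c(0.6, -0.8),
      stringsAsFactors = FALSE
    ),
    prevalences = list(
      deceased  = c(male = 0.45,   comorbidity = 0.75,   polymicrobial = 0.25),
      surviving = c(male = 0.5235, comorbidity = 0.5705, polymicrobial = 0.3087)
    ),
    seed = seed
  )
}

#' @export
print.fg_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d deceased + %d surviving, %d calibrated labs, seed %d\n",
    x$n_deceased, x$n_surviving,
    length(x$quartiles$deceased), x$seed))
  invisible(x)
}
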