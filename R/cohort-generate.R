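# Variables drawn from fitted marginals; everything else (counts, NLR,
# MLR, PLR, CRP/albumin) is derived so records stay internally consistent.
.sampled_vars <- c("age", "crp", "wbc", "hemoglobin", "sodium",
                   "creatinine", "glucose", "platelets", "albumin",
                   "neutrophil_pct", "lymphocyte_pct", "monocyte_pct",
                   "eosinophil_pct")

#' Generate a synthetic two-group cohort
#'
#' Draws `n_deceased + n_surviving` patient records whose per-group lab
#' marginals follow two-piece lognormal distributions calibrated to the
#' spec's quartile triplets (log-scale location at the median, separate
#' spreads below and above it, so all three printed quartiles are matched
#' exactly even when the triplet is log-asymmetric), coupled by a Gaussian
#' copula implementing the spec's rank-correlation plan (Spearman rho
#' converted to the latent normal correlation by 2 sin(pi rho / 6)).
#'
#' Differential percentages (neutrophil, lymphocyte, monocyte, eosinophil)
#' are proportionally renormalised when their sum exceeds 100, keeping
#' records physiologic while preserving ranks. Derived quantities are
#' computed, never sampled: counts = percentage x WBC / 100,
#' NLR = neutrophil% / lymphocyte%, MLR = monocyte% / lymphocyte%,
#' PLR = platelets / lymphocyte count, CRP/albumin from CRP in mg/dL.
#' Outcome labels are fixed by group (the case-control structure of a
#' retrospective mortality cohort, not a prospective risk mechanism).
#'
#' Output is deterministic: the same spec and seed give identical cohorts.
#' The cohort is returned in internal units (CRP in mg/L).
#'
#' @param spec an `fg_cohort_spec`, e.g. [default_cohort_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return data frame, one row per patient, columns `patient_id`,
#'   `outcome`, `sex`, `comorbidity`, `polymicrobial`, the sampled labs,
#'   and the derived counts and indices.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fg_cohort_spec"))
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  groups <- list(deceased = spec$n_deceased, surviving = spec$n_surviving)
  parts <- lapply(names(groups), function(grp) {
    .generate_group(grp, groups[[grp]], spec)
  })
  out <- do.call(rbind, parts)
  out$patient_id <- sprintf("P%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("patient_id", setdiff(names(out), "patient_id"))]
}

.generate_group <- function(group, n, spec) {
  qmap <- spec$quartiles[[group]]
  vars <- intersect(.sampled_vars, names(qmap))

  r <- .copula_matrix(vars, spec$rank_correlations)
  z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% chol(r)
  x <- vapply(seq_along(vars), function(j) {
    .split_lognormal_quantile(z[, j], qmap[[vars[j]]])
  }, numeric(n))
  x <- matrix(x, nrow = n)  # vapply drops dim when n = 1
  colnames(x) <- vars
  df <- as.data.frame(x)

  # keep the four differential percentages physiologic (sum <= 100)
  pct <- c("neutrophil_pct", "lymphocyte_pct", "monocyte_pct",
           "eosinophil_pct")
  pct <- intersect(pct, names(df))
  if (length(pct) > 0) {
    s <- rowSums(df[pct])
    over <- s > 100
    if (any(over)) {
      df[over, pct] <- df[over, pct] * (100 / s[over])
    }
  }

  df$neutrophils <- df$neutrophil_pct * df$wbc / 100
  df$lymphocytes <- df$lymphocyte_pct * df$wbc / 100
  if ("monocyte_pct" %in% names(df)) {
    df$monocytes <- df$monocyte_pct * df$wbc / 100
  }
  if ("eosinophil_pct" %in% names(df)) {
    df$eosinophils <- df$eosinophil_pct * df$wbc / 100
  }
  df$nlr <- df$neutrophil_pct / df$lymphocyte_pct
  if ("monocyte_pct" %in% names(df)) {
    df$mlr <- df$monocyte_pct / df$lymphocyte_pct
  }
  if ("platelets" %in% names(df)) {
    df$plr <- df$platelets / df$lymphocytes
  }
  df$crp_alb_ratio <- df$crp / df$albumin  # CRP still in mg/dL here
  df$crp <- df$crp * 10                    # internal unit is mg/L

  prev <- spec$prevalences[[group]]
  df$sex <- if (!is.null(prev) && "male" %in% names(prev)) {
    ifelse(stats::runif(n) < prev[["male"]], "male", "female")
  } else NA_character_
  df$comorbidity <- if (!is.null(prev) && "comorbidity" %in% names(prev)) {
    ifelse(stats::runif(n) < prev[["comorbidity"]], "yes", "no")
  } else NA_character_
  df$polymicrobial <- if (!is.null(prev) && "polymicrobial" %in% names(prev)) {
    ifelse(stats::runif(n) < prev[["polymicrobial"]], "yes", "no")
  } else NA_character_
  df$outcome <- group
  df
}

# Two-piece lognormal quantile transform: log-scale location ln(q50) with
# separate spreads below and above the median, each calibrated to its own
# printed quartile. Published triplets are often asymmetric on the log
# scale, so a single-sigma lognormal (fit_lognormal_from_quartiles) can
# match the median and the q75/q25 ratio but not all three quartiles; the
# split form reproduces the full triplet exactly while keeping lognormal
# tails. `z` is a standard normal draw (already copula-correlated).
.split_lognormal_quantile <- function(z, q) {
  if (any(q <= 0)) {
    stop("split lognormal: quartiles must be strictly positive",
         call. = FALSE)
  }
  z75 <- stats::qnorm(0.75)
  s_lo <- (log(q[2]) - log(q[1])) / z75
  s_hi <- (log(q[3]) - log(q[2])) / z75
  exp(log(q[2]) + ifelse(z < 0, s_lo, s_hi) * z)
}

# Latent Gaussian correlation matrix for the copula. Spearman rank
# correlations map to latent correlations via 2 sin(pi rho / 6). Pairs the
# plan does not mention are completed by conditional independence given
# the plan's graph: the latent correlation is the product along the
# shortest specified path (0 when disconnected). Hard zeros instead of
# this completion can make an otherwise-sensible plan indefinite (e.g.
# +0.6 and -0.8 sharing a variable leave no room for a zero third leg);
# the path-product completion is the maximum-determinant extension when
# the specified graph is a tree.
.copula_matrix <- function(vars, plan) {
  p <- length(vars)
  r <- diag(p)
  dimnames(r) <- list(vars, vars)
  if (is.null(plan) || nrow(plan) == 0) return(r)

  latent <- diag(p)
  dimnames(latent) <- list(vars, vars)
  specified <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  for (k in seq_len(nrow(plan))) {
    v1 <- plan$var1[k]; v2 <- plan$var2[k]
    if (!(v1 %in% vars) || !(v2 %in% vars)) next
    rho <- plan$rho[k]
    if (abs(rho) > 1) {
      stop("correlation plan: |rho| > 1 for pair (", v1, ", ", v2, ")",
           call. = FALSE)
    }
    latent[v1, v2] <- latent[v2, v1] <- 2 * sin(pi * rho / 6)
    specified[v1, v2] <- specified[v2, v1] <- TRUE
  }

  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      r[i, j] <- if (specified[i, j]) {
        latent[i, j]
      } else {
        .path_product(i, j, specified, latent)
      }
    }
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    pairs <- paste(sprintf("(%s, %s)", plan$var1, plan$var2),
                   collapse = ", ")
    stop("correlation plan is not positive semi-definite; check pair(s) ",
         pairs, call. = FALSE)
  }
  r
}

# product of latent correlations along the shortest specified path
# between i and j (breadth-first), or 0 when the plan disconnects them
.path_product <- function(i, j, specified, latent) {
  p <- nrow(specified)
  prod_to <- rep(NA_real_, p)
  prod_to[i] <- 1
  frontier <- i
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(specified[v, ])) {
        if (is.na(prod_to[w])) {
          prod_to[w] <- prod_to[v] * latent[v, w]
          if (w == j) return(prod_to[j])
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  0
}
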