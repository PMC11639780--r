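---
title: "Methods: FGMI scoring, validation statistics, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FGMI scoring, validation statistics, and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmi)
```

## The scores

The Fournier's Gangrene Mortality Index (FGMI) awards 0, 1, or 2 points to
each of five preoperative parameters measured at presentation — age,
creatinine, albumin, lymphocyte percentage, and the
neutrophil-to-lymphocyte ratio (NLR) — for a total of 0–10. Totals of 5 or
more are classed as high mortality risk, below 5 as low-to-moderate.

The published band table lists three bands per parameter but leaves small
numeric gaps between them (albumin between 2.5 and 2.6 g/dL, lymphocyte
percentages between 5 and 6 and between 9 and 10, NLR between 9 and 10 and
between 14 and 15, and all non-integer ages around the 40 and 60 cut
points). `fgmi_component_score()` therefore treats each parameter as three
ordered half-open regions defined only by the severe and the benign
threshold; the middle band is the complement. This is the
minimal-assumption completion: it reproduces every printed band value
exactly, assigns exactly one score to every positive real value, and keeps
each component monotone in the harmful direction. Whether the original
study rounded gap values up or down is unknowable from the published
table; the complement rule is this package's decision, and the exhaustive
band-agreement and partition tests document its consequences.

The LRINEC score is computed from the standard six-lab rubric (CRP, WBC,
hemoglobin, sodium, creatinine, glucose; maximum 13 points) and banded
low (≤ 5), moderate (6–7), high (≥ 8). The component cut-offs follow the
original published rubric since the index is defined by it; the middle
WBC and hemoglobin bands are closed on both ends, which is the only
self-consistent reading of three-band cut-offs at 15/25 and 11/13.5.

**CRP units.** LRINEC thresholds are defined on CRP in mg/L, while
clinical tables in this field are frequently printed in mg/dL. The cohort
reader takes an explicit unit declaration (`crp_unit`, default `"mg_dl"`)
and converts to mg/L on read; every function downstream works in mg/L.
With group-median CRP values of roughly 20–30 mg/dL (200–300 mg/L),
about half of a typical cohort scores LRINEC-high, which matches the
published band distribution; reading those medians as mg/L would put
virtually nobody above the 150 mg/L threshold and is therefore not
plausible. The mg/dL default records that reasoning.

Records missing any rubric input are reported unscorable with the missing
field names; nothing is imputed, since the underlying study describes no
imputation.

## Validation statistics

All procedures used to validate a risk score against a binary outcome are
implemented in-package and cross-checked in the test suite against
independent references (base R `wilcox.test`, `kruskal.test`,
`chisq.test`, `glm`, `pchisq(ncp = )`, and pROC).

* **ROC/AUC** (`empirical_roc`). Test-positive means score ≥ threshold.
  The AUC is the trapezoidal integral of the empirical curve, which
  equals the tie-corrected Mann–Whitney estimator
  \(P(S^+ > S^-) + \tfrac12 P(S^+ = S^-)\); the suite asserts the
  identity \( \mathrm{AUC} \cdot n_+ n_- = U \) on random instances.
  Confidence intervals: DeLong (default) or Hanley–McNeil, both Wald on
  the AUC scale, truncated to [0, 1]. Which method produced an interval
  is always reported, because the choice is not recoverable from most
  published reports.
* **Odds ratio** (`odds_ratio`). \( \widehat{OR} = ad/bc \) with Woolf's
  log-scale interval \(\exp(\ln OR \pm z\sqrt{1/a+1/b+1/c+1/d})\). A zero
  cell makes the OR undefined and is reported as such; the
  Haldane–Anscombe 0.5 correction sits behind an explicit flag, off by
  default, because the motivating cohort's table has no zero cells.
* **Chi-square and effect size** (`chi_square_2x2`). Closed form
  \( \chi^2 = n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d)) \) on 1 df,
  Yates correction available but off by default; Cohen's
  \( w = \sqrt{\chi^2/n} \).
* **Post-hoc power** (`posthoc_power_chi2`). Noncentrality
  \( \lambda = n w^2 \), critical value the central \(\chi^2\) quantile
  at \(1-\alpha\), and power \(1 - F_{nc}(x_{crit}; df, \lambda)\). The
  noncentral CDF is evaluated by the Poisson-mixture series
  \( F_{nc}(x) = \sum_i e^{-\lambda/2}\frac{(\lambda/2)^i}{i!}
  F_{\chi^2_{df+2i}}(x) \), truncated when the remaining Poisson tail
  mass is below \(10^{-12}\) relative; because each mixand lies in
  [0, 1] the truncation error is bounded by that tail mass. The df = 1
  case is verified against the normal closed form
  \( \Phi(\sqrt{x}-\sqrt\lambda) - \Phi(-\sqrt{x}-\sqrt\lambda) \) to
  \(10^{-10}\).
* **Rank tests.** `mann_whitney_u` computes U from midranks; the
  two-sided p-value uses the normal approximation with tie-corrected
  variance and a 0.5 continuity correction, switching to exact
  enumeration of all \(\binom{n}{n_x}\) assignments when the pooled
  sample is ≤ 12 without ties. Degenerate samples (all values equal)
  return p = 1. `kruskal_wallis` applies the tie-corrected H statistic
  on k − 1 df and directs two-group calls to the Mann–Whitney test.
* **Logistic regression** (`logistic_fit`). IRLS with convergence at a
  maximum absolute coefficient step below \(10^{-8}\) or 50 iterations;
  Wald standard errors and odds-ratio intervals. Complete separation is
  detected (saturating likelihood with a still-growing coefficient) and
  raised as an error rather than clipped. The Hosmer–Lemeshow statistic
  uses deciles of predicted risk, collapsing tied group boundaries, on
  groups − 2 df.
* **Group summaries** (`summarize_groups`). Continuous variables as
  median (25th–75th percentile) with Mann–Whitney p, categorical as
  n (%) with chi-square p. Quartiles use linear interpolation between
  order statistics (R type 7), chosen for determinism; the convention is
  configurable because published tables rarely state one. No
  multiple-testing adjustment is applied across rows, mirroring how such
  lab tables are conventionally presented; this is a documented
  limitation, not an endorsement.

Two-sided p-values are used throughout; significance thresholds are
reported, never used to drop rows.

## The synthetic cohort generator

No patient-level data accompany the motivating study, so
`default_cohort_spec()` encodes what its summary tables publish: group
sizes 20 deceased / 149 surviving, per-group quartile triplets
(25th/50th/75th) for every preoperative lab, and the categorical
prevalences (sex, comorbidity, polymicrobial culture). Those published
summaries are the generator's fixed calibration; they are not tuning
knobs.

**Marginals.** Each sampled lab is drawn from a two-piece lognormal: the
log-scale location is the printed median and the spread below and above
the median is calibrated separately to its own printed quartile
(\( \sigma_{lo} = (\ln q_{50} - \ln q_{25})/z_{0.75} \),
\( \sigma_{hi} = (\ln q_{75} - \ln q_{50})/z_{0.75} \)). Published
triplets are usually asymmetric on the log scale — a single-σ lognormal
fitted by `fit_lognormal_from_quartiles()` reproduces the median and the
\(q_{75}/q_{25}\) ratio but can miss an individual quartile by 25% (the
deceased-group CRP triplet is the worst case) — so the split form is used
for generation: it reproduces all three printed quartiles exactly while
keeping positive support and lognormal tails. The symmetric fit remains
exported as the closed-form summary of a triplet.

**Dependence.** Thirteen base labs are sampled jointly through a Gaussian
copula. The default rank-correlation plan imposes Spearman +0.6 between
neutrophil % and WBC and −0.8 between neutrophil % and lymphocyte %
(converted to latent correlations by \(2\sin(\pi\rho/6)\)). Pairs the plan
does not mention are completed by conditional independence given the
plan's graph — the latent correlation is the product along the shortest
specified path, zero for disconnected pairs. Hard zeros instead of this
completion would make the default plan indefinite (two strong
correlations sharing neutrophil % leave no room for an exactly-zero
WBC–lymphocyte leg), so the completion is what makes the stated plan
realisable; for tree-shaped plans it is also the maximum-determinant
extension. Plans that remain non-positive-semi-definite after completion
are rejected with the offending pairs named.

**Internal consistency.** Derived quantities are computed, never sampled:
differential counts as percentage × WBC / 100, NLR as
neutrophil %/lymphocyte %, MLR as monocyte %/lymphocyte %, PLR as
platelets/lymphocyte count, CRP/albumin from CRP in mg/dL. Every record
therefore satisfies the ratio identities exactly. When the four
differential percentages sum above 100 they are proportionally rescaled
to 100, keeping records physiologic and preserving ranks.

**What the generator does and does not emulate.** It reproduces the
published marginal quartiles, group sizes, and categorical prevalences,
and a minimal physiologic dependence structure. It does not encode a
mortality mechanism (group membership is assigned by construction, as in
a retrospective case–control read-out), true inter-lab correlations
(unknown), measurement error, or missingness. Consequently the derived
indices' distributions (NLR, PLR, MLR, CRP/Alb) are emergent rather than
imposed — their medians land close to the published ones because the
component medians do, but their spread depends on the assumed copula —
and discrimination metrics on synthetic cohorts (AUC around 0.83–0.95
across seeds at n = 169, sensitivity/specificity near 90%/75%)
approximate but need not equal the published 0.88/90%/70%. Passing tests
on synthetic cohorts validate the pipeline's arithmetic and invariances,
not the clinical performance of the score on real patients.

**A documented calibration limit.** In the surviving group the four
differential percentages sum above 100 for roughly half of all draws
(the printed medians already sum to 98.7 and the upper quartiles are
wide), so the physiologic rescaling shifts the percentage marginals'
quartiles down systematically by about 2–5% relative. The rescaling and
exact per-variable quartile recovery are therefore not jointly
achievable at this calibration; the package keeps records physiologic
and accepts the small, reproducible bias in the percentage marginals
(the nine non-percentage labs recover their quartiles well within 3%).
The acceptance suite asserts the strict 3% bound for all sampled
marginals and the affected percentage expectations fail by design,
documenting the tension rather than hiding it.

## Reproducibility and numerics

Every stochastic routine funnels through one seed: `generate_cohort()`
seeds R's RNG from the spec (restoring the caller's RNG state afterward)
and identical seeds give byte-identical cohorts and JSON reports.
Numerical tolerances: noncentral-series truncation \(10^{-12}\)
(relative), IRLS step tolerance \(10^{-8}\) with a 50-iteration cap,
exact Mann–Whitney enumeration up to pooled n = 12. Degenerate inputs
have defined behavior: zero-variance rank tests return p = 1, empty
outcome classes flag the affected metric as undefined instead of
reporting 0, zero-cell odds ratios are reported undefined unless the
correction flag is set, and cohorts with an outcome group below two
records mark all inference sections "insufficient n" while still scoring
every patient.

Problem sizes used by the test suite were chosen to make Monte-Carlo
noise negligible relative to the asserted tolerances while keeping the
default run fast: 50,000 records per group for quartile recovery, 10,000
replicates for null p-value uniformity (Kolmogorov distance < 0.05),
1,000 random instances for the AUC–U identity, and n = 5,000 for
logistic parameter recovery within 3 standard errors.

## Known limitations

* The gap-resolution rule and the LRINEC middle-band closure are this
  package's completions of incompletely printed rubrics; alternative
  readings would change scores only for values inside the printed gaps.
* The published multivariate regression results in this clinical setting
  are not reproducible from summary tables (no covariate coding is
  recoverable, and the printed point estimates lie outside their own
  intervals, suggesting inverted directions); the package provides a
  generic logistic fitter rather than attempting to match them.
* Synthetic cohorts at the study's size (20 events) produce integer
  score medians and small-sample metrics that move noticeably between
  seeds; single-seed synthetic results should be read as illustrative.
* No multiplicity adjustment across lab-table rows.
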