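# fgmi

Scoring and validation tools for the **Fournier's Gangrene Mortality
Index (FGMI)**, a bedside point score for predicting in-hospital
mortality in Fournier's gangrene — the rapidly progressing necrotizing
fasciitis of the perineal and genital regions. The package is aimed at
clinical researchers who want to apply the score to their own cohorts,
audit its construction, or stress-test the statistics behind this class
of risk scores without access to patient-level data.

## The score

FGMI awards 0–2 points to each of five preoperative parameters:

| Parameter        | 2 points | 1 point    | 0 points |
|------------------|----------|------------|----------|
| Age (years)      | ≥ 60     | 40–59      | < 40     |
| Creatinine (mg/dL) | ≥ 1.5  | 1.0–1.49   | < 1.0    |
| Albumin (g/dL)   | ≤ 2.5    | 2.6–3.0    | ≥ 3.1    |
| Lymphocyte %     | ≤ 5      | 6–9        | ≥ 10     |
| NLR              | ≥ 15     | 10–14      | < 10     |

A total of ≥ 5 is high mortality risk, < 5 low-to-moderate. Values that
fall in the small gaps of the published bands are resolved by treating
each parameter as three half-open regions bounded by the severe and
benign thresholds (see the methods vignette). The LRINEC score
(CRP, WBC, hemoglobin, sodium, creatinine, glucose; bands ≤ 5 / 6–7 / ≥ 8)
is also provided for comparison.

Around the scores sits the full validation toolkit such studies use:
empirical ROC curves with AUC = the tie-corrected Mann–Whitney estimator
P(S⁺ > S⁻) + ½P(S⁺ = S⁻) and DeLong or Hanley–McNeil intervals;
sensitivity/specificity at a cutoff with the 2×2 outcome-by-band table;
odds ratios with Woolf intervals exp(ln OR ± z√(1/a+1/b+1/c+1/d));
the 2×2 chi-square with Cohen's w = √(χ²/n) and noncentral-chi-square
post-hoc power (λ = n·w²); Mann–Whitney U (exact at small n) and
Kruskal–Wallis tests; logistic regression by IRLS with Hosmer–Lemeshow
fit; and a synthetic two-group cohort generator calibrated from
published quartile summaries via two-piece lognormal marginals and a
Gaussian copula.

## Worked example

Score the deceased-group median patient and validate the score on a
synthetic cohort calibrated to the published summary tables
(20 deceased + 149 surviving):

```r
library(fgmi)

fgmi_score(list(age = 64.5, creatinine = 1.50, albumin = 2.68,
                lymphocyte_pct = 4.81, nlr = 18.21))
#> FGMI score: 9 (high risk)
#>  components: age=2, creatinine=2, albumin=1, lymphocyte_pct=2, nlr=2

co  <- generate_cohort(default_cohort_spec(seed = 1))
rep <- run_full_analysis(co, analysis_config(seed = 1))
rep
#> Fournier's gangrene cohort analysis
#>   n = 169 (deceased 20, surviving 149)
#>   FGMI AUC 0.936 (95% CI 0.894-0.977, delong)
#>   at cutoff 5: sensitivity 90.0%, specificity 83.2%
#>   odds ratio 44.64 (9.74-204.67)
#>   chi2 49.84 (w = 0.543), post-hoc power 1.00000

posthoc_power_chi2(n_total = 169, w = 0.395, alpha = 0.05, df = 1)
#> Post-hoc chi-square power: 0.99925 (n = 169, w = 0.395, lambda = 26.37,
#>   critical chi2 = 3.84, alpha = 0.05)
```

The median patient of the deceased group lands deep in the high-risk
band (9 of 10 points), while the surviving-group median patient scores 2.
On the synthetic cohort the score separates the groups cleanly
(AUC ≈ 0.93 at this seed); synthetic discrimination metrics approximate,
but need not equal, the originally reported 0.88 AUC with 90%/70%
sensitivity/specificity, because true inter-lab correlations are unknown
(see the methods vignette). The power line reproduces the canonical
post-hoc calculation for a 2×2 table at N = 169 and w = 0.395.

A thin command-line interface wraps the same functions
(`inst/cli/fgmi`): subcommands `simulate`, `score`, `validate`, and
`report`, e.g.

```sh
Rscript inst/cli/fgmi simulate --seed 1 --out cohort.csv
Rscript inst/cli/fgmi validate --input cohort.csv --out report.json
```

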