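# Worked-example patients: per-group medians of the published preoperative
# lab table (CRP in mg/L internally).
median_deceased <- function() {
  list(patient_id = "median_deceased", outcome = "deceased",
       age = 64.5, creatinine = 1.50, albumin = 2.68,
       lymphocyte_pct = 4.81, nlr = 18.21,
       crp = 294.7, wbc = 19.49, hemoglobin = 11.25,
       sodium = 131, glucose = 170.5)
}

median_surviving <- function() {
  list(patient_id = "median_surviving", outcome = "surviving",
       age = 51, creatinine = 0.90, albumin = 3.20,
       lymphocyte_pct = 9.56, nlr = 8.55,
       crp = 207.6, wbc = 16, hemoglobin = 11.80,
       sodium = 134, glucose = 168)
}

two_patient_cohort <- function() {
  rbind(as.data.frame(median_deceased()),
        as.data.frame(median_surviving()))
}

# 2x2 table implied by 90% sensitivity / 70% specificity with group sizes
# 20/149: a = 18 of 20 deceased test-positive, d = 104 of 149 surviving
# test-negative.
reconstructed_table <- function() c(a = 18, b = 2, c = 45, d = 104)

# brute-force AUC: pair count P(score+ > score-) + 0.5 P(tie)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
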