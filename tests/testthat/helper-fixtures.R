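# Small hand-built cohorts used across test files.

make_cohort_df <- function(n = 3,
                           age_years = 61,
                           retinopathy = FALSE, av_nicking = FALSE,
                           focal_narrowing = FALSE,
                           generalized_narrowing = FALSE,
                           hypertension = FALSE, diabetes = FALSE,
                           chs_grade = 1, wmh_volume_cm3 = NA,
                           followup_wmh_volume_cm3 = NA) {
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age_years = rep_len(age_years, n),
    retinopathy = rep_len(retinopathy, n),
    av_nicking = rep_len(av_nicking, n),
    focal_narrowing = rep_len(focal_narrowing, n),
    generalized_narrowing = rep_len(generalized_narrowing, n),
    hypertension = rep_len(hypertension, n),
    diabetes = rep_len(diabetes, n),
    chs_grade = rep_len(chs_grade, n),
    wmh_volume_cm3 = rep_len(wmh_volume_cm3, n),
    followup_wmh_volume_cm3 = rep_len(followup_wmh_volume_cm3, n),
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Reference contingency counts for the late-midlife clinical score
# (no/low column then significant column, severity rows none..severe).
clinical_counts <- function() {
  cbind(no_low = c(231, 509, 363, 78), significant = c(6, 45, 63, 16))
}
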