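test_that("cohort CSV round-trips through write and read", {
  df <- make_cohort_df(5, retinopathy = c(TRUE, FALSE, TRUE, FALSE, FALSE),
                       hypertension = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                       chs_grade = c(0, 1, 3, 2, 4),
                       wmh_volume_cm3 = c(1.2, NA, 10.5, 3.3, 12),
                       followup_wmh_volume_cm3 = c(2.5, NA, 15, NA, 20))
  cohort <- as_cohort(df)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})

test_that("boolean dialects are accepted case-insensitively, others rejected", {
  df <- make_cohort_df(3)
  df$retinopathy <- c("YES", "false", "1")
  df$diabetes <- c("0", "No", "TRUE")
  path <- write_cohort_csv(df)
  cohort <- read_cohort(path)
  expect_equal(cohort$retinopathy, c(TRUE, FALSE, TRUE))
  expect_equal(cohort$diabetes, c(FALSE, FALSE, TRUE))

  df$retinopathy <- c("yes", "maybe", "no")
  expect_error(read_cohort(write_cohort_csv(df)), "row 2")
})

test_that("missing prescreen features are excluded and counted by default", {
  df <- make_cohort_df(3)
  df$retinopathy <- c("1", "", "0")
  cohort <- read_cohort(write_cohort_csv(df))
  expect_equal(nrow(cohort), 2)
  rep <- exclusion_report(cohort)
  expect_equal(rep$n_excluded, 1L)
  expect_true("missing retinopathy" %in% rep$reasons$reason)

  # mode imputation keeps the row, filling with the majority value (FALSE)
  imputed <- read_cohort(write_cohort_csv(df), missing_policy = "impute_mode")
  expect_equal(nrow(imputed), 3)
  expect_false(imputed$retinopathy[2])
})

test_that("fully resolved fixtures are retained unchanged", {
  df <- make_cohort_df(4, chs_grade = c(0, 2, 3, 5))
  cohort <- read_cohort(write_cohort_csv(df))
  expect_equal(nrow(cohort), 4)
  expect_equal(exclusion_report(cohort)$n_excluded, 0L)
})

test_that("schema violations are hard errors, unknown columns a warning", {
  df <- make_cohort_df(2)
  df$hypertension <- NULL
  expect_error(read_cohort(write_cohort_csv(df)), "hypertension")

  df2 <- make_cohort_df(2)
  df2$extraneous <- 1
  expect_warning(read_cohort(write_cohort_csv(df2)), "extraneous")
})

test_that("WMH classification uses CHS grade > cutoff, volume >= cutoff", {
  df <- make_cohort_df(4, chs_grade = c(2, 3, NA, NA),
                       wmh_volume_cm3 = c(NA, NA, 9.3, 9.29))
  st <- wmh_status(as_cohort(df))
  expect_equal(st$significant, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(as.character(st$basis),
               c("chs_threshold", "chs_threshold", "volume_threshold",
                 "volume_threshold"))
  # configurable cutoff
  st2 <- wmh_status(as_cohort(df), chs_cutoff = 3)
  expect_equal(st2$significant[2], FALSE)
})

test_that("cross_tabulate partitions every classified participant", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    df <- make_cohort_df(
      n,
      age_years = runif(n, 50, 70),
      retinopathy = runif(n) < 0.1, av_nicking = runif(n) < 0.1,
      focal_narrowing = runif(n) < 0.15,
      generalized_narrowing = runif(n) < 0.25,
      hypertension = runif(n) < 0.5, diabetes = runif(n) < 0.2,
      chs_grade = sample(0:5, n, replace = TRUE))
    ct <- cross_tabulate(as_cohort(df), "combined")
    expect_equal(sum(ct), n)
    expect_true(all(ct >= 0))
  }
})

test_that("a lone severe significant participant lands in one cell", {
  df <- make_cohort_df(1, age_years = 65, hypertension = TRUE,
                       diabetes = TRUE, chs_grade = 4)
  ct <- cross_tabulate(as_cohort(df), "clinical")
  expect_equal(ct["severe", "significant"], 1L)
  expect_equal(sum(ct), 1L)
})

test_that("reference crosstabs carry the published margins", {
  for (kind in c("retinal", "clinical", "combined")) {
    ct <- aric_midlife_crosstab(kind)
    expect_equal(sum(ct), 1311L)
    expect_equal(sum(ct[, "significant"]), 130L)
  }
  expect_equal(round(130 / 1311, 3), 0.099)
  expect_equal(unclass(aric_midlife_crosstab("clinical"))[, ],
               {
                 m <- clinical_counts()
                 dimnames(m) <- dimnames(aric_midlife_crosstab("clinical"))
                 m
               },
               ignore_attr = TRUE)
})

test_that("empty cohorts are rejected", {
  expect_error(cross_tabulate(as_cohort(make_cohort_df(0)), "retinal"),
               "empty")
})
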