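test_that("the same seed yields byte-identical cohort CSVs", {
  cfg <- cohort_config(n = 500, seed = 303)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg), p1)
  write_cohort(simulate_cohort(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("seed is mandatory and probabilities are validated", {
  expect_error(cohort_config(n = 10), "seed")
  expect_error(cohort_config(n = 10, seed = 1, p_wmh = 1.5), "\\[0, 1\\]")
})

test_that("extreme prevalences are honored exactly", {
  all_sig <- simulate_cohort(cohort_config(n = 200, seed = 9, p_wmh = 1))
  expect_true(all(wmh_status(all_sig)$significant))
  none_sig <- simulate_cohort(cohort_config(n = 200, seed = 9, p_wmh = 0))
  expect_false(any(wmh_status(none_sig)$significant))
})

test_that("CHS grade sits above the cutoff exactly when WMH is significant", {
  cohort <- simulate_cohort(cohort_config(n = 2000, seed = 13))
  st <- wmh_status(cohort, basis = "chs")
  expect_identical(st$significant, cohort$chs_grade > 2)
})

test_that("generated margins recover config values within binomial error", {
  # at the published cohort size and at a large n (convergence ~ 1/sqrt(n))
  for (n in c(1311, 1e5)) {
    cohort <- simulate_cohort(cohort_config(n = n, seed = 101))
    n_sig <- sum(wmh_status(cohort)$significant)
    tol <- 3 * sqrt(n * 0.099 * 0.901)
    expect_lt(abs(n_sig - n * 0.099), tol)
  }

  # conditional feature prevalences at large n
  cohort <- simulate_cohort(cohort_config(n = 1e5, seed = 101))
  sig <- wmh_status(cohort)$significant
  fp <- default_feature_probs()
  for (f in c("retinopathy", "hypertension", "diabetes")) {
    for (status in c(FALSE, TRUE)) {
      p <- fp[f, if (status) "significant" else "no_low"]
      obs <- mean(cohort[[f]][sig == status])
      n_grp <- sum(sig == status)
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n_grp) + 1e-9)
    }
  }
  # age category margin
  p_age <- fp["age_at_or_above_cutoff", "no_low"]
  obs_age <- mean(cohort$age_years[!sig] >= 60)
  expect_lt(abs(obs_age - p_age), 3 * sqrt(p_age * (1 - p_age) / sum(!sig)))
})

test_that("clinical-score column margins match the published table's scale", {
  # generator at the published conditional probabilities, n = 1311:
  # expected clinical-score margins approximately (237, 554, 426, 94)
  cohort <- simulate_cohort(cohort_config(n = 1311, seed = 55))
  ct <- cross_tabulate(cohort, "clinical")
  margins <- rowSums(ct)
  expected <- c(none = 237, mild = 554, moderate = 426, severe = 94)
  probs <- rowSums(implied_category_probs(
    cohort_config(n = 1311, seed = 55), "clinical"))
  for (k in names(expected)) {
    tol <- 3 * sqrt(1311 * probs[k] * (1 - probs[k]))
    expect_lt(abs(margins[k] - 1311 * probs[k]), tol)
    # the implied margins themselves sit near the published counts
    expect_lt(abs(1311 * probs[k] - expected[k]), 40)
  }
})

test_that("implied severity probabilities agree with simulation", {
  cfg <- cohort_config(n = 2e5, seed = 71)
  probs <- implied_category_probs(cfg, "retinal")
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  cohort <- simulate_cohort(cfg)
  ct <- cross_tabulate(cohort, "retinal")
  expect_lt(max(abs(ct / sum(ct) - probs)), 0.005)
})

test_that("implied P(score = 3 | WMH) has the closed product form", {
  cfg <- cohort_config(n = 100, seed = 1)
  probs <- implied_category_probs(cfg, "clinical")
  fp <- cfg$feature_probs
  p3 <- prod(fp[c("age_at_or_above_cutoff", "hypertension", "diabetes"),
                "significant"])
  expect_equal(probs["severe", "significant"] / cfg$p_wmh, p3,
               tolerance = 1e-12)
})

test_that("end-to-end design recovery matches the analytic value within 5%", {
  rec <- recover_design(cohort_config(n = 1, seed = 909), n_large = 1e5,
                        score_kind = "clinical", severity_range = "severe")
  expect_lt(abs(rec$pipeline$n_prescreen - rec$analytic$n_prescreen) /
              rec$analytic$n_prescreen, 0.05)
  expect_error(recover_design(cohort_config(n = 1, seed = 1),
                              n_large = 1000), "1e5")
})
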