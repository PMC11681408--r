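test_that("MRI-only design matches printed and trivial examples", {
  est <- mri_only_design(646, 0.099, 650)
  expect_equal(est$n_mri, 6526L)
  expect_equal(est$cost_total, 4241900)

  est2 <- mri_only_design(10, 1.0, 650)
  expect_equal(est2$n_mri, 10L)
  expect_equal(est2$cost_total, 6500)

  late <- mri_only_design(646, 0.60, 650)
  expect_equal(late$n_mri, 1077L)
  expect_equal(late$cost_total, 700050)

  expect_error(mri_only_design(646, 0, 650), "infeasible")
})

test_that("two-stage design reproduces the printed severe rows", {
  ret <- two_stage_design(646, 0.075, 0.23, 32.50, 650)
  expect_equal(ret$n_prescreen, 37450L)
  expect_equal(ret$cost_prescreen_total, 1217125)
  expect_equal(ret$n_mri, 2809L)
  expect_equal(ret$cost_mri_total, 1825850)
  expect_equal(ret$cost_total, 3042975)

  cli <- two_stage_design(646, 0.072, 0.17, 0, 650)
  expect_equal(cli$n_prescreen, 52778L)
  expect_equal(cli$n_mri, 3801L)
  expect_equal(cli$cost_total, 2470650)

  cr <- two_stage_design(646, 0.28, 0.17, 32.50, 650)
  expect_equal(cr$n_prescreen, 13572L)
  expect_equal(cr$cost_prescreen_total, 441090)
  expect_equal(cr$n_mri, 3801L)
  expect_equal(cr$cost_total, 2911740)
})

test_that("degenerate prescreen reduces exactly to MRI-only", {
  a <- two_stage_design(646, 1.0, 0.099, 0, 650)
  b <- mri_only_design(646, 0.099, 650)
  expect_equal(a$n_mri, b$n_mri)
  expect_equal(a$cost_total, b$cost_total)

  # property: holds across 1000 random valid inputs
  set.seed(3)
  for (i in 1:1000) {
    target <- sample(10:5000, 1)
    p <- runif(1, 0.01, 1)
    cost <- round(runif(1, 100, 2000), 2)
    ts <- two_stage_design(target, 1.0, p, 0, cost)
    mo <- mri_only_design(target, p, cost)
    expect_identical(ts$n_mri, mo$n_mri)
    expect_identical(ts$cost_total, mo$cost_total)
  }
})

test_that("staged computation equals the one-line formula (oracle)", {
  set.seed(17)
  for (i in 1:1000) {
    target <- sample(10:5000, 1)
    p1 <- runif(1, 0.01, 1)
    p2 <- runif(1, 0.01, 1)
    a <- runif(1, 0, 0.5)
    est <- two_stage_design(target, p1, p2, 32.50, 650, attrition = a)
    n_pre <- ceiling(round(target / (p1 * p2 * (1 - a)), 9))
    n_mri <- ceiling(round(p1 * n_pre, 9))
    expect_equal(est$n_prescreen, as.integer(n_pre))
    expect_equal(est$n_mri, as.integer(n_mri))
    expect_equal(est$cost_total, n_pre * 32.50 + n_mri * 650)
    # feasibility: expected eligible never below target
    expect_gte(est$expected_eligible, target - 1e-9)
    expect_lte(est$n_mri, est$n_prescreen)
  }
})

test_that("costs and sample sizes are monotone in both proportions", {
  grid <- seq(0.05, 0.95, by = 0.05)
  base <- 0.3
  n_in_p1 <- vapply(grid, function(p) {
    two_stage_design(646, p, base, 32.5, 650)$n_prescreen
  }, 0L)
  n_in_p2 <- vapply(grid, function(p) {
    two_stage_design(646, base, p, 32.5, 650)$n_prescreen
  }, 0L)
  cost_in_p2 <- vapply(grid, function(p) {
    two_stage_design(646, base, p, 32.5, 650)$cost_total
  }, 0)
  expect_true(all(diff(n_in_p1) <= 0))
  expect_true(all(diff(n_in_p2) <= 0))
  expect_true(all(diff(cost_in_p2) <= 0))
})

test_that("attrition inflates the pool by 1/(1-rate) before ceiling", {
  base <- apply_attrition(646, 1.0, 0.099, 0, 650, rates = 0)
  expect_equal(base[[1]]$n_prescreen,
               two_stage_design(646, 1.0, 0.099, 0, 650)$n_prescreen)

  est10 <- apply_attrition(646, 1.0, 0.099, 0, 650, rates = 0.10)[[1]]
  expect_equal(est10$n_prescreen, 7251L)  # ceil(646 / (0.099 * 0.9))

  est30 <- apply_attrition(646, 0.075, 0.23, 32.5, 650, rates = 0.30)[[1]]
  expect_equal(est30$n_prescreen, 53499L)  # ceil(37449.28 / 0.7)

  expect_error(apply_attrition(646, 0.5, 0.5, rates = 1), "\\[0, 1\\)")

  # identity: attrition r == inflating the target by 1/(1-r), within
  # one unit of ceiling slack
  set.seed(23)
  for (i in 1:200) {
    p1 <- runif(1, 0.05, 1); p2 <- runif(1, 0.05, 1)
    r <- runif(1, 0, 0.6)
    with_rate <- two_stage_design(646, p1, p2, 32.5, 650, attrition = r)
    inflated <- two_stage_design(646 / (1 - r), p1, p2, 32.5, 650)
    expect_lte(abs(with_rate$n_prescreen - inflated$n_prescreen), 1)
  }
})

test_that("design_from_crosstab in paper precision matches printed values", {
  cli <- design_from_crosstab(aric_midlife_crosstab("clinical"), "severe",
                              cost_prescreen = 0, precision = "paper")
  expect_equal(cli$n_prescreen, 52778L)
  expect_equal(cli$params$p_prescreen, 0.072)
  expect_equal(cli$params$p_wmh_given_positive, 0.17)

  ret <- design_from_crosstab(aric_midlife_crosstab("retinal"), "severe",
                              precision = "paper")
  expect_equal(ret$cost_total, 3042975)

  # exact precision uses the raw count ratios instead
  exact <- design_from_crosstab(aric_midlife_crosstab("clinical"), "severe",
                                cost_prescreen = 0, precision = "exact")
  expect_equal(exact$params$p_prescreen, 94 / 1311)
  expect_equal(exact$params$p_wmh_given_positive, 16 / 94)
})

test_that("mild-severe proportions exclude the none category", {
  ct <- aric_midlife_crosstab("clinical")
  props <- crosstab_proportions(ct, "mild_severe")
  expect_equal(props$n_range, 554 + 426 + 94)
  expect_equal(props$p_prescreen, (554 + 426 + 94) / 1311)

  empty_severe <- crosstab(cbind(c(10, 5, 0, 0), c(2, 1, 0, 0)))
  expect_error(crosstab_proportions(empty_severe, "severe"), "infeasible")
})

test_that("two-group design balances eligibility and favors the rarer group", {
  sym <- two_group_design(323, c(0.1, 0.1), c(0.2, 0.2))
  expect_equal(sym$groups[[1]]$n_prescreen, sym$groups[[2]]$n_prescreen)

  asym <- two_group_design(323, c(0.10, 0.05), c(0.2, 0.2))
  nA <- asym$groups[[1]]$n_prescreen
  nB <- asym$groups[[2]]$n_prescreen
  expect_gt(nB, nA)
  expect_lte(abs(nB - 2 * nA), 2)  # ceiling slack on each side
  expect_equal(asym$totals$n_prescreen, nA + nB)

  expect_error(two_group_design(323, c(0, 0.05), c(0.2, 0.2)), "infeasible")
})
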