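new_design_estimate <- function(design, n_prescreen, cost_prescreen_cents,
                                n_mri, cost_mri_cents, expected_eligible,
                                target_n, params) {
  structure(list(
    design = design,
    n_prescreen = n_prescreen,
    cost_prescreen_total = cents_to_dollars(cost_prescreen_cents),
    n_mri = n_mri,
    cost_mri_total = cents_to_dollars(cost_mri_cents),
    cost_total = cents_to_dollars(cost_prescreen_cents + cost_mri_cents),
    expected_eligible = expected_eligible,
    target_n = target_n,
    params = params
  ), class = "design_estimate")
}

check_proportion <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    stop(name, " must lie in (0, 1]: infeasible design", call. = FALSE)
  }
}

#' MRI-only recruitment design
#'
#' Single-stage design: everyone recruited receives a screening MRI, and
#' the fraction `p_wmh` with significant WMH burden is eligible for
#' enrollment. The recruitment size is the trial target divided by that
#' fraction, rounded up to the next whole participant.
#'
#' @param target_n Trial enrollment goal (default 646, a published
#'   phase-2 target for small-vessel-disease trials).
#' @param p_wmh Population fraction with significant WMH, in (0, 1].
#' @param cost_mri Cost per screening MRI in dollars (default 650).
#' @param attrition Fraction of eligible participants expected not to
#'   enroll, in [0, 1).
#' @return A `design_estimate` with stage sizes and exact dollar costs.
#' @export
mri_only_design <- function(target_n = 646, p_wmh, cost_mri = 650,
                            attrition = 0) {
  check_proportion(p_wmh, "p_wmh")
  if (attrition < 0 || attrition >= 1) stop("attrition must be in [0, 1)",
                                            call. = FALSE)
  stopifnot(target_n >= 1)
  n_mri <- ceil_units(target_n / (p_wmh * (1 - attrition)))
  mri_cents <- n_mri * dollars_to_cents(cost_mri)
  new_design_estimate(
    design = "mri_only",
    n_prescreen = n_mri, cost_prescreen_cents = 0,
    n_mri = n_mri, cost_mri_cents = mri_cents,
    expected_eligible = n_mri * p_wmh * (1 - attrition),
    target_n = target_n,
    params = list(p_wmh = p_wmh, cost_mri = cost_mri, attrition = attrition))
}

#' Two-stage prescreen-MRI recruitment design
#'
#' The recruitment pool is prescreened with a cheap test; the fraction
#' `p_prescreen` that is positive proceeds to MRI, and among those the
#' fraction `p_wmh_given_positive` has significant WMH and is eligible.
#' The prescreening sample size is
#' `ceil(target_n / (p_prescreen * p_wmh_given_positive * (1 - attrition)))`
#' and the MRI stage receives `ceil(p_prescreen * n_prescreen)`
#' participants; rounding up at both stages guarantees the expected number
#' of eligible participants never falls below the target.
#'
#' @inheritParams mri_only_design
#' @param p_prescreen Fraction positive at the prescreen, in (0, 1].
#' @param p_wmh_given_positive Fraction with significant WMH among
#'   prescreen-positives, in (0, 1].
#' @param cost_prescreen Cost per prescreen in dollars (default 32.50, a
#'   standard retinal fundus photograph; use 0 for a clinical prescreen
#'   drawn from routine care).
#' @return A `design_estimate`.
#' @export
two_stage_design <- function(target_n = 646, p_prescreen,
                             p_wmh_given_positive, cost_prescreen = 32.50,
                             cost_mri = 650, attrition = 0) {
  check_proportion(p_prescreen, "p_prescreen")
  check_proportion(p_wmh_given_positive, "p_wmh_given_positive")
  if (attrition < 0 || attrition >= 1) stop("attrition must be in [0, 1)",
                                            call. = FALSE)
  stopifnot(target_n >= 1)
  p_eligible <- p_prescreen * p_wmh_given_positive * (1 - attrition)
  n_prescreen <- ceil_units(target_n / p_eligible)
  n_mri <- ceil_units(p_prescreen * n_prescreen)
  pre_cents <- n_prescreen * dollars_to_cents(cost_prescreen)
  mri_cents <- n_mri * dollars_to_cents(cost_mri)
  new_design_estimate(
    design = "two_stage",
    n_prescreen = n_prescreen, cost_prescreen_cents = pre_cents,
    n_mri = n_mri, cost_mri_cents = mri_cents,
    expected_eligible = n_prescreen * p_eligible,
    target_n = target_n,
    params = list(p_prescreen = p_prescreen,
                  p_wmh_given_positive = p_wmh_given_positive,
                  cost_prescreen = cost_prescreen, cost_mri = cost_mri,
                  attrition = attrition))
}

#' Attrition-adjusted two-stage designs
#'
#' Recomputes a two-stage design for each attrition rate: the proportion
#' eventually enrolling, `1 - rate`, enters the eligibility product, so the
#' recruitment pool is inflated by `1 / (1 - rate)` before rounding.
#'
#' @inheritParams two_stage_design
#' @param rates Numeric vector of attrition fractions, each in [0, 1).
#' @return List of `design_estimate`, one per rate, named by rate.
#' @export
apply_attrition <- function(target_n = 646, p_prescreen,
                            p_wmh_given_positive, cost_prescreen = 32.50,
                            cost_mri = 650, rates = c(0.1, 0.2, 0.3)) {
  if (any(rates < 0 | rates >= 1)) stop("attrition rates must be in [0, 1)",
                                        call. = FALSE)
  out <- lapply(rates, function(r) {
    two_stage_design(target_n, p_prescreen, p_wmh_given_positive,
                     cost_prescreen, cost_mri, attrition = r)
  })
  names(out) <- format(rates)
  out
}

#' Two-stage design from a contingency table
#'
#' Derives the two screening proportions from a severity-by-WMH
#' [crosstab()] at the chosen severity range and feeds them to
#' [two_stage_design()]. With `precision = "paper"` the proportions are
#' first rounded to two significant figures, reproducing calculations made
#' from a printed summary table rather than from raw counts.
#'
#' @inheritParams two_stage_design
#' @param x A `wmh_crosstab`.
#' @param severity_range `"severe"`, `"moderate_severe"` or
#'   `"mild_severe"`.
#' @param precision `"exact"` (default) or `"paper"`; see
#'   [crosstab_proportions()].
#' @return A `design_estimate` (its `params` carry the proportions used).
#' @export
design_from_crosstab <- function(x, severity_range = "severe",
                                 target_n = 646, cost_prescreen = 32.50,
                                 cost_mri = 650,
                                 precision = c("exact", "paper"),
                                 attrition = 0) {
  props <- crosstab_proportions(x, severity_range, precision = precision)
  est <- two_stage_design(target_n, props$p_prescreen,
                          props$p_wmh_given_positive, cost_prescreen,
                          cost_mri, attrition = attrition)
  est$design <- paste0("two_stage_", severity_range)
  est$params$severity_range <- severity_range
  est$params$precision <- match.arg(precision)
  est
}

#' Balanced two-group two-stage design
#'
#' Plans recruitment when two groups (for example male and female) must be
#' equally represented among MRI-eligible enrollees but differ in
#' prescreen-positive prevalence and WMH prevalence. Each group gets its
#' own two-stage computation toward the same per-group eligibility target,
#' so the group with the lower prescreen prevalence is automatically
#' recruited in larger numbers.
#'
#' @param target_n_per_group Eligible participants required from each
#'   group (e.g. half the trial target).
#' @param p_prescreen Length-2 vector of prescreen-positive fractions.
#' @param p_wmh_given_positive Length-2 vector (recycled if length 1).
#' @param cost_prescreen,cost_mri Per-person dollar costs shared by both
#'   groups.
#' @param attrition Attrition fraction shared by both groups.
#' @param group_names Labels for the two groups.
#' @return List with per-group `design_estimate`s (`groups`) and combined
#'   `totals` (n_prescreen, n_mri, cost_total in dollars).
#' @export
two_group_design <- function(target_n_per_group = 323,
                             p_prescreen, p_wmh_given_positive,
                             cost_prescreen = 32.50, cost_mri = 650,
                             attrition = 0,
                             group_names = c("group_A", "group_B")) {
  stopifnot(length(p_prescreen) == 2, length(group_names) == 2)
  if (length(p_wmh_given_positive) == 1)
    p_wmh_given_positive <- rep(p_wmh_given_positive, 2)
  groups <- lapply(1:2, function(i) {
    est <- two_stage_design(target_n_per_group, p_prescreen[i],
                            p_wmh_given_positive[i], cost_prescreen,
                            cost_mri, attrition = attrition)
    est$design <- paste0("two_stage_", group_names[i])
    est
  })
  names(groups) <- group_names
  list(groups = groups,
       totals = list(
         n_prescreen = sum(vapply(groups, `[[`, 0, "n_prescreen")),
         n_mri = sum(vapply(groups, `[[`, 0, "n_mri")),
         cost_total = sum(vapply(groups, `[[`, 0, "cost_total"))))
}

#' @export
print.design_estimate <- function(x, ...) {
  cat(sprintf("<design_estimate: %s> target eligible n = %d\n",
              x$design, as.integer(x$target_n)))
  cat(sprintf("  prescreen stage: %7d participants  %s\n", x$n_prescreen,
              format_dollars(dollars_to_cents(x$cost_prescreen_total))))
  cat(sprintf("  MRI stage:       %7d participants  %s\n", x$n_mri,
              format_dollars(dollars_to_cents(x$cost_mri_total))))
  cat(sprintf("  total cost: %s   expected eligible: %.2f\n",
              format_dollars(dollars_to_cents(x$cost_total)),
              x$expected_eligible))
  invisible(x)
}

#' @export
as.data.frame.design_estimate <- function(x, ...) {
  data.frame(design = x$design, n_prescreen = x$n_prescreen,
             cost_prescreen_total = x$cost_prescreen_total,
             n_mri = x$n_mri, cost_mri_total = x$cost_mri_total,
             cost_total = x$cost_total,
             expected_eligible = x$expected_eligible,
             target_n = x$target_n)
}
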