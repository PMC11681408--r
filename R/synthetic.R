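#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the
#' joint structure of the published ARIC late-midlife analysis: 9.9%
#' prevalence of significant WMH and, conditional on WMH status, the
#' published feature prevalences (e.g. retinopathy 17% among significant
#' vs 6.2% among no/low WMH). Features are drawn conditionally independent
#' given WMH status -- only the margins are published, so no correlation
#' structure is asserted; see the methods vignette for what that does and
#' does not make the generator good for.
#'
#' @param n Cohort size.
#' @param seed Integer seed; mandatory so every cohort is reproducible.
#' @param p_wmh Prevalence of significant WMH.
#' @param feature_probs 7x2 named matrix of conditional probabilities
#'   P(feature present | WMH status), columns `no_low`, `significant`;
#'   rows retinopathy, av_nicking, focal_narrowing, generalized_narrowing,
#'   age_at_or_above_cutoff, hypertension, diabetes.
#' @param age_cutoff_years Age threshold the age row refers to.
#' @param chs_probs_no_low,chs_probs_significant Grade distributions
#'   within status; names are grades. Grades must respect the cutoff
#'   (grade > `chs_cutoff` iff significant).
#' @param chs_cutoff CHS cutoff defining significance.
#' @param map Quadratic `chs_volume_map` used as the generator's true
#'   grade-to-volume relationship.
#' @param sigma_volume Gaussian noise (cm^3) on the baseline volumetric
#'   measure around the mapped grade.
#' @param progression_effects Mean 10-year volume increase (cm^3) per
#'   retinal severity category none/mild/moderate/severe.
#' @param sigma_progression Gaussian noise (cm^3) on follow-up volume.
#' @return A `synthetic_cohort_config`.
#' @export
cohort_config <- function(n = 1311, seed,
                          p_wmh = 0.099,
                          feature_probs = default_feature_probs(),
                          age_cutoff_years = 60,
                          chs_probs_no_low = c("0" = 0.30, "1" = 0.45,
                                               "2" = 0.25),
                          chs_probs_significant = c("3" = 0.60, "4" = 0.30,
                                                    "5" = 0.10),
                          chs_cutoff = 2,
                          map = chs_volume_map(0.8, 1.0, 0.65),
                          sigma_volume = 2.0,
                          progression_effects = c(none = 1, mild = 2,
                                                  moderate = 3, severe = 5),
                          sigma_progression = 2.0) {
  if (missing(seed)) stop("seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(n >= 1)
  probs <- c(p_wmh, feature_probs, chs_probs_no_low, chs_probs_significant)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]",
                                       call. = FALSE)
  stopifnot(abs(sum(chs_probs_no_low) - 1) < 1e-8,
            abs(sum(chs_probs_significant) - 1) < 1e-8)
  if (any(as.numeric(names(chs_probs_no_low)) > chs_cutoff) ||
      any(as.numeric(names(chs_probs_significant)) <= chs_cutoff)) {
    stop("CHS grade distributions must respect the significance cutoff",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), p_wmh = p_wmh,
                 feature_probs = feature_probs,
                 age_cutoff_years = age_cutoff_years,
                 chs_probs_no_low = chs_probs_no_low,
                 chs_probs_significant = chs_probs_significant,
                 chs_cutoff = chs_cutoff, map = map,
                 sigma_volume = sigma_volume,
                 progression_effects = progression_effects,
                 sigma_progression = sigma_progression),
            class = "synthetic_cohort_config")
}

#' Default conditional feature prevalences
#'
#' The published ARIC late-midlife feature prevalences by WMH status.
#'
#' @return 7x2 matrix of P(feature | WMH status).
#' @export
default_feature_probs <- function() {
  m <- rbind(retinopathy = c(0.062, 0.17),
             av_nicking = c(0.050, 0.15),
             focal_narrowing = c(0.11, 0.19),
             generalized_narrowing = c(0.25, 0.25),
             age_at_or_above_cutoff = c(0.63, 0.82),
             hypertension = c(0.45, 0.66),
             diabetes = c(0.16, 0.21))
  colnames(m) <- c("no_low", "significant")
  m
}

#' Simulate a synthetic cohort
#'
#' WMH status is Bernoulli(`p_wmh`); each binary feature is drawn
#' independently given status from its conditional probability; age is
#' drawn by sampling the at-or-above-cutoff indicator at its conditional
#' probability and then a uniform age within the matching 10-year band
#' (so the conditional age-category probability is met exactly, with no
#' truncation bias); the CHS grade is drawn from the within-status grade
#' distribution, so grade > cutoff holds iff status is significant; the
#' baseline volumetric measure is the mapped grade plus Gaussian noise;
#' and the follow-up volume adds the retinal-severity progression effect
#' plus noise. The same seed always yields the identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A `wmh_cohort` of `config$n` participants.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  n <- config$n
  sig <- stats::runif(n) < config$p_wmh
  col <- ifelse(sig, "significant", "no_low")
  draw <- function(feature) {
    stats::runif(n) < config$feature_probs[feature, col]
  }
  age_hi <- draw("age_at_or_above_cutoff")
  cutoff <- config$age_cutoff_years
  age <- ifelse(age_hi,
                stats::runif(n, cutoff, cutoff + 10),
                stats::runif(n, cutoff - 10, cutoff - 1e-9))
  grade <- integer(n)
  if (any(!sig)) {
    grade[!sig] <- as.integer(sample(names(config$chs_probs_no_low),
                                     sum(!sig), replace = TRUE,
                                     prob = config$chs_probs_no_low))
  }
  if (any(sig)) {
    grade[sig] <- as.integer(sample(names(config$chs_probs_significant),
                                    sum(sig), replace = TRUE,
                                    prob = config$chs_probs_significant))
  }
  mapped <- as.numeric(grade_to_volume(config$map, grade))
  volume <- pmax(0, mapped + stats::rnorm(n, 0, config$sigma_volume))
  df <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    age_years = age,
    retinopathy = draw("retinopathy"),
    av_nicking = draw("av_nicking"),
    focal_narrowing = draw("focal_narrowing"),
    generalized_narrowing = draw("generalized_narrowing"),
    hypertension = draw("hypertension"),
    diabetes = draw("diabetes"),
    chs_grade = grade,
    wmh_volume_cm3 = volume,
    stringsAsFactors = FALSE
  )
  ret_cat <- as.integer(retinal_score(df, score_definition("retinal"))$score)
  df$followup_wmh_volume_cm3 <- pmax(
    0, mapped + config$progression_effects[ret_cat + 1L] +
      stats::rnorm(n, 0, config$sigma_progression))
  as_cohort(df)
}

#' Score-category distribution implied by a generator config
#'
#' Closed-form severity-by-status probabilities under the generator's
#' conditional-independence structure, by enumerating all feature
#' combinations. Serves as the analytic oracle for end-to-end recovery
#' checks.
#'
#' @param config A [cohort_config()].
#' @param score_kind `"retinal"`, `"clinical"` or `"combined"`.
#' @return 4x2 matrix of P(severity category, WMH status) summing to 1.
#' @export
implied_category_probs <- function(config,
                                   score_kind = c("retinal", "clinical",
                                                  "combined")) {
  score_kind <- match.arg(score_kind)
  definition <- score_definition(score_kind,
                                 age_cutoff_years = config$age_cutoff_years)
  feats <- names(definition$feature_points)
  combos <- as.matrix(expand.grid(rep(list(0:1), length(feats))))
  colnames(combos) <- feats
  raw <- drop(combos %*% definition$feature_points)
  cat_idx <- pmin(definition$max_score, raw) + 1L
  out <- matrix(0, 4, 2, dimnames = list(SEVERITY_LEVELS,
                                         c("no_low", "significant")))
  for (status in colnames(out)) {
    p_feat <- config$feature_probs[feats, status]
    combo_prob <- apply(combos, 1, function(z) {
      prod(ifelse(z == 1, p_feat, 1 - p_feat))
    })
    p_status <- if (status == "significant") config$p_wmh else 1 - config$p_wmh
    for (k in 1:4) {
      out[k, status] <- sum(combo_prob[cat_idx == k]) * p_status
    }
  }
  out
}

#' Analytic screening proportions implied by a config
#'
#' @param config A [cohort_config()].
#' @param score_kind Prescreen kind.
#' @param severity_range Severity range.
#' @return List with `p_prescreen` and `p_wmh_given_positive` computed
#'   from the generator's probabilities (no simulation).
#' @export
implied_proportions <- function(config, score_kind, severity_range) {
  probs <- implied_category_probs(config, score_kind)
  thr <- range_threshold(severity_range)
  rows <- (thr + 1L):4L
  p_pre <- sum(probs[rows, ])
  list(p_prescreen = p_pre,
       p_wmh_given_positive = sum(probs[rows, "significant"]) / p_pre)
}

#' End-to-end design recovery from a simulated cohort
#'
#' Validation harness: simulates a large cohort, scores and tabulates it,
#' derives a two-stage design at exact precision, and returns it alongside
#' the design computed from the config's closed-form proportions. At large
#' n the two must agree (the testable claim being that the whole pipeline
#' preserves the generator's margins).
#'
#' @param config A [cohort_config()]; its `n` is overridden by `n_large`.
#' @param n_large Simulation size, at least 1e5.
#' @param score_kind Prescreen kind.
#' @param severity_range Severity range.
#' @param target_n,cost_prescreen,cost_mri Design parameters.
#' @return List with `pipeline` and `analytic` `design_estimate`s.
#' @export
recover_design <- function(config, n_large = 1e5,
                           score_kind = "clinical",
                           severity_range = "severe", target_n = 646,
                           cost_prescreen = 32.50, cost_mri = 650) {
  if (n_large < 1e5) stop("n_large must be at least 1e5 for a stable recovery",
                          call. = FALSE)
  big <- config
  big$n <- as.integer(n_large)
  cohort <- simulate_cohort(big)
  ct <- cross_tabulate(cohort, score_kind, wmh_basis = "chs",
                       chs_cutoff = config$chs_cutoff,
                       age_cutoff_years = config$age_cutoff_years)
  pipeline <- design_from_crosstab(ct, severity_range, target_n,
                                   cost_prescreen, cost_mri,
                                   precision = "exact")
  ip <- implied_proportions(config, score_kind, severity_range)
  analytic <- two_stage_design(target_n, ip$p_prescreen,
                               ip$p_wmh_given_positive, cost_prescreen,
                               cost_mri)
  list(pipeline = pipeline, analytic = analytic)
}

#' @export
print.synthetic_cohort_config <- function(x, ...) {
  cat(sprintf("<synthetic_cohort_config> n = %d, seed = %d, P(significant WMH) = %.3f\n",
              x$n, x$seed, x$p_wmh))
  cat("  conditional feature prevalences P(feature | status):\n")
  print(round(x$feature_probs, 3))
  invisible(x)
}
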