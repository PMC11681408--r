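#' Prescreening score definition
#'
#' Point tables for the 0-3 unweighted prescreening scores. The retinal
#' score awards 3 points for retinopathy (end-stage retinal disease) and 1
#' point each for arteriovenous nicking, focal arteriolar narrowing and
#' generalized arteriolar narrowing, truncated at 3. The clinical score
#' awards 1 point each for age at or above the cutoff, hypertension and
#' diabetes. The combined score is the truncated sum of the two. The age
#' cutoff defaults to 60 years (late midlife); use 78 for a late-life
#' cohort, and `age_operator = ">"` for a strict comparison.
#'
#' @param kind `"retinal"`, `"clinical"` or `"combined"`.
#' @param age_cutoff_years Age threshold contributing a clinical point.
#' @param age_operator `">="` (default) or `">"`.
#' @param max_score Truncation cap (default 3).
#' @param feature_points Named numeric vector overriding the default point
#'   table for the relevant features.
#' @return A `score_definition` object.
#' @export
score_definition <- function(kind = c("retinal", "clinical", "combined"),
                             age_cutoff_years = 60,
                             age_operator = c(">=", ">"),
                             max_score = 3L,
                             feature_points = NULL) {
  kind <- match.arg(kind)
  age_operator <- match.arg(age_operator)
  points <- c(retinopathy = 3, av_nicking = 1, focal_narrowing = 1,
              generalized_narrowing = 1,
              age_at_or_above_cutoff = 1, hypertension = 1, diabetes = 1)
  if (!is.null(feature_points)) {
    unknown <- setdiff(names(feature_points), names(points))
    if (length(unknown)) stop("unknown features: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    if (any(feature_points <= 0)) stop("all points must be > 0", call. = FALSE)
    points[names(feature_points)] <- feature_points
  }
  keep <- switch(kind,
                 retinal = RETINAL_FEATURES,
                 clinical = c("age_at_or_above_cutoff", "hypertension",
                              "diabetes"),
                 combined = names(points))
  if (max_score < max(points[keep])) {
    stop("max_score must be at least the largest single-feature points",
         call. = FALSE)
  }
  structure(list(kind = kind, feature_points = points[keep],
                 age_cutoff_years = age_cutoff_years,
                 age_operator = age_operator,
                 max_score = as.integer(max_score)),
            class = "score_definition")
}

# Binary feature matrix (participants x score features) for a definition.
feature_matrix <- function(cohort, definition) {
  feats <- names(definition$feature_points)
  m <- matrix(NA, nrow(cohort), length(feats), dimnames = list(NULL, feats))
  for (f in feats) {
    m[, f] <- if (f == "age_at_or_above_cutoff") {
      if (definition$age_operator == ">=")
        cohort$age_years >= definition$age_cutoff_years
      else cohort$age_years > definition$age_cutoff_years
    } else {
      cohort[[f]]
    }
  }
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    stop("unresolved prescreen feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  storage.mode(m) <- "numeric"
  m
}

score_from_definition <- function(cohort, definition) {
  m <- feature_matrix(cohort, definition)
  raw <- drop(m %*% definition$feature_points)
  score <- as.integer(pmin(definition$max_score, raw))
  data.frame(score = score, category = severity_category(score))
}

#' Retinal prescreening score
#'
#' @param cohort A `wmh_cohort` (or data.frame with resolved retinal
#'   features).
#' @param definition A retinal [score_definition()].
#' @return Data.frame with integer `score` (0-3) and severity `category`
#'   (none/mild/moderate/severe), one row per participant.
#' @export
retinal_score <- function(cohort, definition = score_definition("retinal")) {
  stopifnot(definition$kind == "retinal")
  score_from_definition(cohort, definition)
}

#' Clinical prescreening score
#'
#' One point each for age at/above the cutoff, hypertension and diabetes.
#'
#' @inheritParams retinal_score
#' @param definition A clinical [score_definition()].
#' @return As [retinal_score()].
#' @export
clinical_score <- function(cohort, definition = score_definition("clinical")) {
  stopifnot(definition$kind == "clinical")
  score_from_definition(cohort, definition)
}

#' Combined clinical-retinal prescreening score
#'
#' Sum of the clinical and retinal scores, truncated at the cap so the
#' combined scale stays comparable with its components.
#'
#' @inheritParams retinal_score
#' @param definition A combined [score_definition()].
#' @return As [retinal_score()].
#' @export
combined_score <- function(cohort, definition = score_definition("combined")) {
  stopifnot(definition$kind == "combined")
  ret <- retinal_score(cohort, score_definition(
    "retinal", max_score = definition$max_score))
  cli <- clinical_score(cohort, score_definition(
    "clinical", age_cutoff_years = definition$age_cutoff_years,
    age_operator = definition$age_operator,
    max_score = definition$max_score))
  score <- pmin(definition$max_score, ret$score + cli$score)
  data.frame(score = as.integer(score), category = severity_category(score))
}

#' Score a cohort with any prescreen
#'
#' Dispatch helper used by the tabulation, CLI and simulation layers.
#'
#' @inheritParams retinal_score
#' @param kind `"retinal"`, `"clinical"` or `"combined"`.
#' @param age_cutoff_years Passed to [score_definition()].
#' @param ... Further arguments to [score_definition()].
#' @return As [retinal_score()].
#' @export
score_cohort <- function(cohort, kind = c("retinal", "clinical", "combined"),
                         age_cutoff_years = 60, ...) {
  kind <- match.arg(kind)
  definition <- score_definition(kind, age_cutoff_years = age_cutoff_years,
                                 ...)
  switch(kind,
         retinal = retinal_score(cohort, definition),
         clinical = clinical_score(cohort, definition),
         combined = combined_score(cohort, definition))
}
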