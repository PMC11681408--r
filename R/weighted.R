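#' Fit a data-driven weighted prescreening score
#'
#' Secondary-analysis variant of the prescreening scores: instead of fixed
#' integer points, each binary feature receives a weight learned from its
#' association with significant WMH status. The estimator is
#' L2-regularized (ridge) logistic regression at a fixed penalty, fitted
#' per predictor set; the normalized weight of a feature is its shrunken
#' coefficient on the odds-ratio scale, `exp(beta)` -- 1 for an
#' uninformative feature, above 1 for a risk feature -- and a rescaling
#' maps the maximum attainable weighted sum onto the 0-3 scale shared
#' with the unweighted scores. The exact normalization published
#' alongside such weights is not fully specified, so this scheme is this
#' package's documented interpretation (see the methods vignette for why
#' the odds-ratio scale was chosen over normalized absolute
#' coefficients).
#'
#' @param cohort A `wmh_cohort` with resolved features and WMH measures.
#' @param predictor_set `"retinal"` (4 retinal signs), `"clinical"` (age
#'   indicator, hypertension, diabetes) or `"combined"` (all 7).
#' @param wmh_basis,chs_cutoff,volume_cutoff Passed to [wmh_status()].
#' @param age_cutoff_years Age threshold for the clinical age indicator.
#' @param lambda Ridge penalty (fixed, default 1.0, for determinism; no
#'   cross-validation).
#' @param max_score Cap of the rescaled score (default 3).
#' @return A `weighted_score_model` with `normalized_weights`,
#'   `rescale_factor`, `category_bins` description, and fit metadata.
#' @export
fit_weighted_model <- function(cohort,
                               predictor_set = c("retinal", "clinical",
                                                 "combined"),
                               wmh_basis = "auto", chs_cutoff = 2,
                               volume_cutoff = 9.3, age_cutoff_years = 60,
                               lambda = 1.0, max_score = 3) {
  predictor_set <- match.arg(predictor_set)
  definition <- score_definition(predictor_set,
                                 age_cutoff_years = age_cutoff_years)
  xm <- feature_matrix(cohort, definition)
  st <- wmh_status(cohort, basis = wmh_basis, chs_cutoff = chs_cutoff,
                   volume_cutoff = volume_cutoff)
  keep <- !is.na(st$significant)
  xm <- xm[keep, , drop = FALSE]
  y <- st$significant[keep]
  if (sum(keep) < 50) stop("need at least 50 classified records",
                           call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; weights are not estimable",
         call. = FALSE)
  }
  if (any(apply(xm, 2, stats::sd) == 0)) {
    stop("degenerate design: constant predictor(s) ",
         paste(colnames(xm)[apply(xm, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (qr(cbind(1, xm))$rank < ncol(xm) + 1) {
    stop("degenerate design: collinear predictors", call. = FALSE)
  }
  fit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  coefs <- as.numeric(stats::coef(fit))[-1]
  names(coefs) <- colnames(xm)
  weights <- exp(coefs)  # odds-ratio scale: fully shrunk features get 1
  structure(list(
    predictor_set = predictor_set,
    normalized_weights = weights,
    rescale_factor = max_score / sum(weights),
    max_score = max_score,
    category_bins = "round half-up of the rescaled score to 0..3",
    age_cutoff_years = age_cutoff_years,
    lambda = lambda,
    n = sum(keep),
    n_significant = sum(y)
  ), class = "weighted_score_model")
}

round_half_up <- function(x) floor(x + 0.5)

#' Weighted prescreening score
#'
#' Applies a fitted [fit_weighted_model()] to a cohort: the weighted sum
#' of present features times the rescale factor gives a continuous score
#' in [0, max_score]; the severity category is the score rounded half-up
#' to the nearest integer (configurable interpretation, recorded in the
#' model object).
#'
#' @param cohort A `wmh_cohort`.
#' @param model A `weighted_score_model`.
#' @return Data.frame with continuous `score`, integer `binned_score` and
#'   severity `category`.
#' @export
weighted_score <- function(cohort, model) {
  stopifnot(inherits(model, "weighted_score_model"))
  definition <- score_definition(model$predictor_set,
                                 age_cutoff_years = model$age_cutoff_years)
  xm <- feature_matrix(cohort, definition)
  if (!setequal(colnames(xm), names(model$normalized_weights))) {
    stop("cohort features do not match the fitted model", call. = FALSE)
  }
  raw <- drop(xm[, names(model$normalized_weights), drop = FALSE] %*%
                model$normalized_weights)
  score <- raw * model$rescale_factor
  binned <- as.integer(round_half_up(score))
  data.frame(score = score, binned_score = binned,
             category = severity_category(binned))
}

#' @export
print.weighted_score_model <- function(x, ...) {
  cat(sprintf("<weighted_score_model: %s> n = %d (%d significant WMH), ridge lambda = %g\n",
              x$predictor_set, x$n, x$n_significant, x$lambda))
  cat("  normalized weights (odds-ratio scale; 1 = uninformative):\n")
  for (f in names(x$normalized_weights))
    cat(sprintf("    %-24s %.3f\n", f, x$normalized_weights[f]))
  cat(sprintf("  rescale factor: %.4f (max weighted sum -> %d)\n",
              x$rescale_factor, x$max_score))
  invisible(x)
}

#' Serialize a score definition or weighted model to JSON
#'
#' @param x A `score_definition` or `weighted_score_model`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
score_model_to_json <- function(x, path = NULL) {
  payload <- unclass(x)
  payload$class <- class(x)[1]
  # named numeric vectors serialize as JSON objects so names survive
  for (k in c("normalized_weights", "feature_points")) {
    if (!is.null(payload[[k]])) payload[[k]] <- as.list(payload[[k]])
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore a score definition or weighted model from JSON
#'
#' @param path File written by [score_model_to_json()] (or a JSON string).
#' @return The restored object.
#' @export
score_model_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  cls <- payload$class
  payload$class <- NULL
  if (!is.null(payload$normalized_weights))
    payload$normalized_weights <- unlist(payload$normalized_weights)
  if (!is.null(payload$feature_points))
    payload$feature_points <- unlist(payload$feature_points)
  structure(payload, class = cls)
}
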