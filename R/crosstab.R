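#' Severity-by-WMH contingency table
#'
#' Construct a 4x2 contingency table of prescreening severity category
#' (none/mild/moderate/severe) against significant-WMH status. This is the
#' summary object the whole recruitment calculator runs on: screening
#' proportions, performance metrics and design estimates are all derived
#' from it, so a published table of counts is as good an input as
#' participant-level data.
#'
#' @param counts 4x2 non-negative integer matrix; rows none/mild/moderate/
#'   severe, columns no-or-low WMH then significant WMH (row/column names
#'   optional, order is what counts).
#' @return A `wmh_crosstab`.
#' @export
crosstab <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 2))) {
    stop("counts must be a 4x2 matrix (severity x WMH status)", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(severity = SEVERITY_LEVELS,
                           wmh = c("no_low", "significant"))
  structure(counts, class = c("wmh_crosstab", "matrix"))
}

#' Cross-tabulate a scored cohort
#'
#' Scores every participant with the chosen prescreen, classifies WMH
#' status, and counts the severity-by-status partition.
#'
#' @param cohort A `wmh_cohort`.
#' @param score_kind `"retinal"`, `"clinical"` or `"combined"`.
#' @param wmh_basis Passed to [wmh_status()] (`"auto"`, `"chs"`,
#'   `"volume"`).
#' @param chs_cutoff,volume_cutoff Passed to [wmh_status()].
#' @param age_cutoff_years Passed to the score definition.
#' @param ... Further arguments to [score_definition()].
#' @return A `wmh_crosstab`; participants lacking both WMH measures are
#'   dropped with a warning.
#' @export
cross_tabulate <- function(cohort,
                           score_kind = c("retinal", "clinical", "combined"),
                           wmh_basis = "auto", chs_cutoff = 2,
                           volume_cutoff = 9.3, age_cutoff_years = 60, ...) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  score_kind <- match.arg(score_kind)
  sc <- score_cohort(cohort, score_kind,
                     age_cutoff_years = age_cutoff_years, ...)
  st <- wmh_status(cohort, basis = wmh_basis, chs_cutoff = chs_cutoff,
                   volume_cutoff = volume_cutoff)
  keep <- !is.na(st$significant)
  if (!all(keep)) {
    warning(sum(!keep), " participant(s) lack any WMH measure; dropped",
            call. = FALSE)
  }
  if (!any(keep)) stop("no participant has a WMH measure", call. = FALSE)
  tab <- table(factor(sc$category[keep], levels = SEVERITY_LEVELS),
               factor(ifelse(st$significant[keep], "significant", "no_low"),
                      levels = c("no_low", "significant")))
  crosstab(unclass(tab))
}

#' Screening proportions from a contingency table
#'
#' For a severity range (severe = score 3; moderate-severe = 2-3;
#' mild-severe = 1-3) returns the prescreen-positive fraction of the cohort
#' and the significant-WMH fraction among prescreen-positives -- the two
#' proportions the two-stage recruitment formula consumes.
#'
#' @param x A `wmh_crosstab`.
#' @param severity_range `"severe"`, `"moderate_severe"` or `"mild_severe"`.
#' @param precision `"exact"` keeps full-precision count ratios;
#'   `"paper"` rounds each proportion to two significant figures, the
#'   precision at which such tables are conventionally printed, so
#'   published summary tables can be reproduced from their printed
#'   percentages.
#' @return List with `p_prescreen`, `p_wmh_given_positive`, and the counts
#'   behind them.
#' @export
crosstab_proportions <- function(x, severity_range,
                                 precision = c("exact", "paper")) {
  stopifnot(inherits(x, "wmh_crosstab"))
  precision <- match.arg(precision)
  thr <- range_threshold(severity_range)
  total <- sum(x)
  if (total == 0) stop("empty crosstab", call. = FALSE)
  rows <- (thr + 1L):4L
  n_range <- sum(x[rows, ])
  if (n_range == 0) {
    stop("no participants in severity range '", severity_range,
         "': infeasible design", call. = FALSE)
  }
  n_sig <- sum(x[rows, "significant"])
  p_pre <- n_range / total
  p_wmh <- n_sig / n_range
  if (precision == "paper") {
    p_pre <- signif(p_pre, 2)
    p_wmh <- signif(p_wmh, 2)
  }
  list(p_prescreen = p_pre, p_wmh_given_positive = p_wmh,
       n_total = total, n_range = n_range, n_significant = n_sig)
}

#' @export
print.wmh_crosstab <- function(x, ...) {
  cat(sprintf("<wmh_crosstab> n = %d, significant WMH = %d (%.1f%%)\n",
              sum(x), sum(x[, "significant"]),
              100 * sum(x[, "significant"]) / sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Published ARIC late-midlife summary tables
#'
#' The severity-by-WMH contingency tables for the three unweighted
#' prescreening scores in the published ARIC late-midlife analysis
#' (N = 1311, of whom 130 had significant WMH burden, CHS grade > 2).
#' Shipped as reference inputs: the participant-level data are restricted,
#' but every recruitment and screening-performance quantity in that
#' analysis is a function of these counts.
#'
#' @param score_kind `"retinal"`, `"clinical"` or `"combined"`.
#' @return A `wmh_crosstab`.
#' @export
aric_midlife_crosstab <- function(score_kind = c("retinal", "clinical",
                                                 "combined")) {
  score_kind <- match.arg(score_kind)
  counts <- switch(score_kind,
    retinal  = cbind(no_low = c(721, 325, 60, 75),
                     significant = c(60, 38, 9, 23)),
    clinical = cbind(no_low = c(231, 509, 363, 78),
                     significant = c(6, 45, 63, 16)),
    combined = cbind(no_low = c(169, 367, 341, 304),
                     significant = c(2, 29, 37, 62)))
  crosstab(counts)
}
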