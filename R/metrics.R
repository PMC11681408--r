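#' Screening performance at a severity range
#'
#' Collapses a severity-by-WMH [crosstab()] to a 2x2 table at the range's
#' score threshold and reports the true-positive rate (sensitivity),
#' false-positive rate, positive predictive value and negative predictive
#' value, with the underlying counts. Rates are returned at full precision;
#' rounding is a presentation concern. A zero denominator yields `NA` with
#' a note rather than silent NaN.
#'
#' @param x A `wmh_crosstab`.
#' @param severity_range `"severe"`, `"moderate_severe"` or
#'   `"mild_severe"`.
#' @return A `metric_report` list: `severity_range`, `tp_rate`, `fp_rate`,
#'   `ppv`, `npv`, `counts` (tp, fp, fn, tn), `undefined` (character vector
#'   of rates with zero denominators).
#' @export
metrics_at_range <- function(x, severity_range) {
  stopifnot(inherits(x, "wmh_crosstab"))
  thr <- range_threshold(severity_range)
  rows <- (thr + 1L):4L
  tp <- sum(x[rows, "significant"])
  fp <- sum(x[rows, "no_low"])
  fn <- sum(x[, "significant"]) - tp
  tn <- sum(x[, "no_low"]) - fp
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  rates <- list(tp_rate = safe_ratio(tp, tp + fn),
                fp_rate = safe_ratio(fp, fp + tn),
                ppv = safe_ratio(tp, tp + fp),
                npv = safe_ratio(tn, tn + fn))
  structure(c(list(severity_range = severity_range), rates,
              list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
                   undefined = names(rates)[vapply(rates, is.na, TRUE)])),
            class = "metric_report")
}

#' Performance sweep across all severity thresholds
#'
#' Convenience table of the screening metrics at every severity range
#' (ROC-style operating points; no area summary is computed).
#'
#' @param x A `wmh_crosstab`.
#' @return Data.frame, one row per severity range.
#' @export
metrics_sweep <- function(x) {
  do.call(rbind, lapply(c("mild_severe", "moderate_severe", "severe"),
                        function(r) as.data.frame(metrics_at_range(x, r))))
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(severity_range = x$severity_range, tp_rate = x$tp_rate,
             fp_rate = x$fp_rate, ppv = x$ppv, npv = x$npv,
             tp = x$counts["tp"], fp = x$counts["fp"],
             fn = x$counts["fn"], tn = x$counts["tn"], row.names = NULL)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> range: %s\n", x$severity_range))
  cat(sprintf("  TP rate (sensitivity): %.2f   FP rate: %.2f\n",
              x$tp_rate, x$fp_rate))
  cat(sprintf("  PPV: %.2f   NPV: %.2f\n", x$ppv, x$npv))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = "  "), "\n")
  if (length(x$undefined))
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
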