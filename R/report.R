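#' Comparison table of recruitment designs
#'
#' Assembles design estimates across prescreening modalities and severity
#' ranges into one table sorted by total cost (ties broken by modality
#' label, stably), the tabular analogue of comparing all screening
#' approaches at once.
#'
#' @param estimates Named list of `design_estimate`s; names label the
#'   modality/range.
#' @return Data.frame, one row per design, sorted ascending by
#'   `cost_total`.
#' @export
design_report <- function(estimates) {
  if (length(estimates) < 1) stop("need at least one design estimate",
                                  call. = FALSE)
  stopifnot(all(vapply(estimates, inherits, TRUE, "design_estimate")))
  labels <- names(estimates) %||%
    vapply(estimates, `[[`, "", "design")
  rows <- do.call(rbind, lapply(estimates, as.data.frame))
  rows$modality <- labels
  rows <- rows[c("modality", setdiff(names(rows), "modality"))]
  rows <- rows[order(rows$cost_total, rows$modality), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' All-designs report from the three score crosstabs
#'
#' Builds the nine two-stage designs (3 modalities x 3 severity ranges)
#' plus the MRI-only design from one crosstab per modality, the standard
#' comparison a recruitment planner starts from.
#'
#' @param tabs Named list of `wmh_crosstab`s: `retinal`, `clinical`,
#'   `combined`.
#' @param target_n Trial target.
#' @param cost_retinal Prescreen cost for the retinal modality (also used
#'   for the combined modality, whose prescreen includes the photograph).
#' @param cost_clinical Prescreen cost for the clinical modality (default
#'   0: routine-care information).
#' @param cost_mri MRI cost.
#' @param precision `"exact"` or `"paper"` (see
#'   [crosstab_proportions()]).
#' @return Data.frame from [design_report()].
#' @export
full_design_report <- function(tabs, target_n = 646, cost_retinal = 32.50,
                               cost_clinical = 0, cost_mri = 650,
                               precision = "exact") {
  stopifnot(all(c("retinal", "clinical", "combined") %in% names(tabs)))
  ranges <- c("severe", "moderate_severe", "mild_severe")
  ests <- list()
  for (mod in c("retinal", "clinical", "combined")) {
    cost_pre <- if (mod == "clinical") cost_clinical else cost_retinal
    for (r in ranges) {
      ests[[paste(mod, r, sep = "_")]] <-
        design_from_crosstab(tabs[[mod]], r, target_n, cost_pre, cost_mri,
                             precision = precision)
    }
  }
  any_tab <- tabs[[1]]
  p_wmh <- sum(any_tab[, "significant"]) / sum(any_tab)
  if (precision == "paper") p_wmh <- signif(p_wmh, 2)
  ests[["mri_only"]] <- mri_only_design(target_n, p_wmh, cost_mri)
  design_report(ests)
}

#' Render a design report as markdown
#'
#' @param report Data.frame from [design_report()].
#' @return Character vector of markdown lines (currency formatted with
#'   thousands separators; the data.frame itself stays unformatted).
#' @export
report_to_markdown <- function(report) {
  fmt <- function(x) format_dollars(dollars_to_cents(x))
  header <- "| Design | Prescreened | Prescreen cost | MRI scans | MRI cost | Total cost |"
  sep <- "|---|---:|---:|---:|---:|---:|"
  rows <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    sprintf("| %s | %s | %s | %s | %s | %s |", r$modality,
            formatC(r$n_prescreen, big.mark = ","),
            fmt(r$cost_prescreen_total),
            formatC(r$n_mri, big.mark = ","), fmt(r$cost_mri_total),
            fmt(r$cost_total))
  }, "")
  c(header, sep, rows)
}
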