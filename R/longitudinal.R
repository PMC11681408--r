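#' Compare WMH progression across prescreening categories
#'
#' Kruskal-Wallis omnibus test (rank-based, tie-corrected, chi-square
#' reference) of volume change across score categories, with planned post
#' hoc rank-sum contrasts of each severity category against the "none"
#' category (default) or all pairwise, multiplicity-adjusted.
#'
#' @param change Numeric vector of per-participant volume changes (cm^3).
#' @param category Severity categories (factor or character;
#'   none/mild/moderate/severe), same length.
#' @param posthoc `"vs_none"` (default, the 3 planned contrasts) or
#'   `"all_pairwise"`.
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return A `group_comparison` list: `H`, `df`, `p_value`, `degenerate`
#'   flag, per-group summary (`groups`), and a `posthoc` data.frame with
#'   raw and adjusted p-values.
#' @export
kruskal_wallis_by_category <- function(change, category,
                                       posthoc = c("vs_none",
                                                   "all_pairwise"),
                                       adjust = "bonferroni") {
  posthoc <- match.arg(posthoc)
  ok <- !is.na(change) & !is.na(category)
  change <- change[ok]
  category <- factor(as.character(category)[ok],
                     levels = SEVERITY_LEVELS)
  category <- droplevels(category)
  if (nlevels(category) < 2) stop("need at least 2 nonempty groups",
                                  call. = FALSE)
  groups <- data.frame(
    category = levels(category),
    n = as.integer(table(category)),
    median_change = as.numeric(tapply(change, category, stats::median))
  )
  degenerate <- length(unique(change)) < 2
  if (degenerate) {
    H <- 0; p <- 1; df <- nlevels(category) - 1L
  } else {
    kt <- stats::kruskal.test(change, category)
    H <- unname(kt$statistic); p <- kt$p.value; df <- unname(kt$parameter)
  }
  pairs <- if (posthoc == "vs_none") {
    ref <- levels(category)[1]  # lowest available severity acts as reference
    others <- setdiff(levels(category), ref)
    lapply(others, function(g) c(ref, g))
  } else {
    utils::combn(levels(category), 2, simplify = FALSE)
  }
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    a <- change[category == pr[1]]; b <- change[category == pr[2]]
    if (degenerate) {
      data.frame(group1 = pr[1], group2 = pr[2], W = NA_real_, p_raw = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(b, a, exact = FALSE,
                                                correct = TRUE))
      data.frame(group1 = pr[1], group2 = pr[2],
                 W = unname(wt$statistic), p_raw = wt$p.value)
    }
  }))
  ph$p_adjusted <- stats::p.adjust(ph$p_raw, method = adjust)
  structure(list(H = H, df = df, p_value = p, degenerate = degenerate,
                 groups = groups, posthoc = ph, posthoc_method = posthoc,
                 adjust = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H = %.3f (df = %d), p = %.4g%s\n",
              x$H, x$df, x$p_value,
              if (x$degenerate) "  [degenerate: all values identical]" else ""))
  print(x$groups, row.names = FALSE)
  cat(sprintf("post hoc (%s, %s-adjusted):\n", x$posthoc_method, x$adjust))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}
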