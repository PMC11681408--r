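#' Cohort CSV schema
#'
#' Column names of the versioned participant-level cohort table. One row per
#' participant: four retinal signs graded from fundus photographs, two
#' clinical risk factors, age in years, the ordinal CHS white-matter
#' hyperintensity grade and/or a volumetric WMH measure (cm^3, assumed
#' already standardized to a total intracranial volume of 1500 cm^3), and an
#' optional follow-up volume for progression analyses. Empty cells are
#' missing values.
#'
#' @return Character vector of column names, in canonical order.
#' @export
cohort_schema <- function() {
  c("id", "age_years", "retinopathy", "av_nicking", "focal_narrowing",
    "generalized_narrowing", "hypertension", "diabetes", "chs_grade",
    "wmh_volume_cm3", "followup_wmh_volume_cm3")
}

FEATURE_COLUMNS <- c("retinopathy", "av_nicking", "focal_narrowing",
                     "generalized_narrowing", "hypertension", "diabetes")
RETINAL_FEATURES <- c("retinopathy", "av_nicking", "focal_narrowing",
                      "generalized_narrowing")

#' Read a participant cohort from CSV
#'
#' Parses and validates a cohort table against [cohort_schema()]. Boolean
#' features accept the dialects `0/1`, `true/false` and `yes/no`
#' (case-insensitive); any other coding is an error naming the row. Rows
#' with unresolved prescreen features are, under the default policy,
#' excluded and counted (mirroring the exclusion of participants with
#' ungradable retinal photographs in the source cohort); under
#' `missing_policy = "impute_mode"` each missing boolean is replaced by the
#' column's most frequent value. Multivariate imputation is deliberately not
#' offered.
#'
#' @param path Path to a CSV file with a header row.
#' @param missing_policy `"exclude"` (default) or `"impute_mode"`.
#' @return A `wmh_cohort`: a data.frame of retained records in input order,
#'   with an `exclusions` attribute (see [exclusion_report()]).
#' @export
read_cohort <- function(path, missing_policy = c("exclude", "impute_mode")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(cohort_schema(), names(raw))
  # follow-up volume is optional in files that predate progression analyses
  missing_cols <- setdiff(missing_cols, "followup_wmh_volume_cm3")
  if (length(missing_cols)) {
    stop("cohort CSV is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), cohort_schema())
  if (length(unknown)) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[cohort_schema()[cohort_schema() %in% names(raw)]]
  }
  if (!"followup_wmh_volume_cm3" %in% names(raw)) {
    raw$followup_wmh_volume_cm3 <- NA_character_
  }
  as_cohort(raw, missing_policy = missing_policy)
}

num_or_na <- function(x, column) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': non-numeric value '%s' in row %d",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Construct a cohort from a data.frame
#'
#' Applies the same typing, validation and missing-feature policy as
#' [read_cohort()] to an in-memory table.
#'
#' @param x A data.frame with the [cohort_schema()] columns.
#' @param missing_policy `"exclude"` or `"impute_mode"`.
#' @return A `wmh_cohort` data.frame.
#' @export
as_cohort <- function(x, missing_policy = c("exclude", "impute_mode")) {
  missing_policy <- match.arg(missing_policy)
  x <- as.data.frame(x)
  out <- data.frame(
    id = as.character(x$id),
    age_years = num_or_na(x$age_years, "age_years"),
    stringsAsFactors = FALSE
  )
  for (col in FEATURE_COLUMNS) {
    out[[col]] <- if (is.logical(x[[col]])) x[[col]]
                  else parse_boolean_column(x[[col]], col)
  }
  out$chs_grade <- num_or_na(x$chs_grade, "chs_grade")
  if (any(!is.na(out$chs_grade) &
          (out$chs_grade != round(out$chs_grade) | out$chs_grade < 0 |
           out$chs_grade > 9))) {
    stop("chs_grade must be an integer in 0..9", call. = FALSE)
  }
  out$wmh_volume_cm3 <- num_or_na(x$wmh_volume_cm3, "wmh_volume_cm3")
  out$followup_wmh_volume_cm3 <-
    num_or_na(x$followup_wmh_volume_cm3, "followup_wmh_volume_cm3")
  if (any(!is.na(out$age_years) & out$age_years < 0) ||
      any(!is.na(out$wmh_volume_cm3) & out$wmh_volume_cm3 < 0)) {
    stop("age_years and wmh_volume_cm3 must be non-negative", call. = FALSE)
  }

  prescreen <- c(RETINAL_FEATURES, "hypertension", "diabetes", "age_years")
  missing_any <- Reduce(`|`, lapply(prescreen, function(f) is.na(out[[f]])))
  exclusions <- data.frame(reason = character(), n = integer())
  if (missing_policy == "impute_mode" && any(missing_any)) {
    for (col in FEATURE_COLUMNS) {
      if (anyNA(out[[col]])) {
        mode_val <- mean(out[[col]], na.rm = TRUE) > 0.5  # tie -> absent
        out[[col]][is.na(out[[col]])] <- mode_val
      }
    }
    missing_any <- is.na(out$age_years)  # age cannot be mode-imputed
  }
  if (any(missing_any)) {
    by_reason <- vapply(prescreen, function(f) sum(is.na(out[[f]]) & missing_any),
                        integer(1))
    by_reason <- by_reason[by_reason > 0]
    exclusions <- data.frame(reason = paste0("missing ", names(by_reason)),
                             n = unname(by_reason))
    out <- out[!missing_any, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, exclusions = exclusions,
            n_excluded = if (nrow(exclusions)) sum(missing_any) else 0L,
            class = c("wmh_cohort", "data.frame"))
}

#' Exclusion report for a cohort
#'
#' @param cohort A `wmh_cohort` from [read_cohort()] or [as_cohort()].
#' @return List with `n_excluded` and a per-reason count table.
#' @export
exclusion_report <- function(cohort) {
  list(n_excluded = attr(cohort, "n_excluded") %||% 0L,
       reasons = attr(cohort, "exclusions") %||%
         data.frame(reason = character(), n = integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans written as `1`/`0`, missing values
#' as empty cells, columns in canonical schema order.
#'
#' @param cohort A `wmh_cohort` or compatible data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, cohort_schema()]
  for (col in FEATURE_COLUMNS) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify significant WMH burden
#'
#' A participant has significant white-matter-hyperintensity burden when the
#' ordinal CHS grade exceeds `chs_cutoff` (default >2, the convention for
#' graded midlife scans) or, where only a volumetric measure exists, when
#' WMH volume is at or above `volume_cutoff` (default 9.3 cm^3, the
#' published volumetric equivalent of CHS >2 used for late-life scans).
#'
#' @param cohort A `wmh_cohort`.
#' @param basis `"auto"` (CHS grade when present, else volume), `"chs"`, or
#'   `"volume"`.
#' @param chs_cutoff Grade strictly above which WMH is significant.
#' @param volume_cutoff Volume (cm^3) at or above which WMH is significant.
#' @return Data.frame with columns `significant` (logical, NA when the
#'   required measure is absent) and `basis` (factor).
#' @export
wmh_status <- function(cohort, basis = c("auto", "chs", "volume"),
                       chs_cutoff = 2, volume_cutoff = 9.3) {
  basis <- match.arg(basis)
  grade <- cohort$chs_grade
  vol <- cohort$wmh_volume_cm3
  use_chs <- switch(basis,
                    auto = !is.na(grade),
                    chs = rep(TRUE, nrow(cohort)),
                    volume = rep(FALSE, nrow(cohort)))
  significant <- rep(NA, nrow(cohort))
  significant[use_chs] <- grade[use_chs] > chs_cutoff
  significant[!use_chs] <- vol[!use_chs] >= volume_cutoff
  data.frame(
    significant = as.logical(significant),
    basis = factor(ifelse(use_chs, "chs_threshold", "volume_threshold"),
                   levels = c("chs_threshold", "volume_threshold"))
  )
}

#' @export
print.wmh_cohort <- function(x, ...) {
  cat(sprintf("<wmh_cohort> %d participants", nrow(x)))
  excl <- exclusion_report(x)
  if (excl$n_excluded > 0)
    cat(sprintf(" (%d excluded at load)", excl$n_excluded))
  cat("\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
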