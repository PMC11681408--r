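#' Fit the CHS-grade to WMH-volume quadratic map
#'
#' Ordinary least-squares fit of `volume = a0 + a1*grade + a2*grade^2` on
#' paired observations where a scan was both graded on the ordinal CHS
#' scale and measured volumetrically. Used to convert graded baseline
#' scans to estimated volumes for progression analyses. Volumes are
#' assumed already standardized to a total intracranial volume of
#' 1500 cm^3; no re-standardization is performed.
#'
#' @param chs_grade Integer CHS grades (at least 3 distinct values).
#' @param volume_cm3 Non-negative WMH volumes, same length.
#' @return A `chs_volume_map` with `coefficients` (a0, a1, a2),
#'   `r_squared`, `n` and the fitted grade range.
#' @export
fit_chs_volume_map <- function(chs_grade, volume_cm3) {
  stopifnot(length(chs_grade) == length(volume_cm3))
  ok <- !is.na(chs_grade) & !is.na(volume_cm3)
  chs_grade <- chs_grade[ok]; volume_cm3 <- volume_cm3[ok]
  if (length(unique(chs_grade)) < 3) {
    stop("need at least 3 distinct CHS grades to fit a quadratic",
         call. = FALSE)
  }
  if (any(volume_cm3 < 0)) stop("volumes must be non-negative", call. = FALSE)
  if (stats::var(volume_cm3) == 0) {
    # flat response: summary.lm's R^2 is 0/0 noise here, define it as 0
    co <- c(volume_cm3[1], 0, 0)
    r2 <- 0
  } else {
    fit <- stats::lm(volume_cm3 ~ chs_grade + I(chs_grade^2))
    co <- unname(stats::coef(fit))
    # summary.lm warns on noiseless interpolation; R^2 = 1 is still right
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  map <- structure(list(coefficients = c(a0 = co[1], a1 = co[2], a2 = co[3]),
                        r_squared = r2, n = length(chs_grade),
                        grade_range = range(chs_grade)),
                   class = "chs_volume_map")
  if (co[2] < -1e-8 || co[3] < -1e-8) {
    warning("fitted map is not guaranteed monotone over the grade range ",
            "(a1 or a2 negative); inspect diagnostics", call. = FALSE)
  }
  map
}

#' Construct a map from externally supplied coefficients
#'
#' For reusing a previously published quadratic conversion whose
#' coefficients are known.
#'
#' @param a0,a1,a2 Quadratic coefficients (volume in cm^3 as a function of
#'   CHS grade).
#' @param grade_range Grades over which the coefficients are considered
#'   interpolation rather than extrapolation.
#' @return A `chs_volume_map`.
#' @export
chs_volume_map <- function(a0, a1, a2, grade_range = c(0, 9)) {
  structure(list(coefficients = c(a0 = a0, a1 = a1, a2 = a2),
                 r_squared = NA_real_, n = NA_integer_,
                 grade_range = grade_range),
            class = "chs_volume_map")
}

#' Predict WMH volume from CHS grade
#'
#' Evaluates the quadratic map; negative predictions are clipped to zero
#' (volumes are physical quantities) with an attribute flag, and grades
#' outside the fitted range trigger an extrapolation warning.
#'
#' @param map A `chs_volume_map`.
#' @param grade CHS grades.
#' @return Numeric volumes (cm^3) with attribute `clipped` (logical
#'   vector).
#' @export
grade_to_volume <- function(map, grade) {
  stopifnot(inherits(map, "chs_volume_map"))
  if (any(grade < map$grade_range[1] | grade > map$grade_range[2],
          na.rm = TRUE)) {
    warning("grade(s) outside the fitted range ", map$grade_range[1], "..",
            map$grade_range[2], "; prediction is extrapolation",
            call. = FALSE)
  }
  co <- map$coefficients
  v <- co["a0"] + co["a1"] * grade + co["a2"] * grade^2
  clipped <- !is.na(v) & v < 0
  v[clipped] <- 0
  structure(unname(v), clipped = clipped)
}

#' Volume cutoff equivalent to a CHS cutoff
#'
#' The volumetric threshold corresponding to "CHS grade > cutoff": the
#' mapped volume of the first grade above the cutoff. With no map
#' supplied, returns the published late-life default of 9.3 cm^3
#' (equivalent to CHS > 2).
#'
#' @param map A `chs_volume_map`, or `NULL` for the fixed default.
#' @param chs_cutoff CHS cutoff (default 2).
#' @return Volume threshold in cm^3.
#' @export
volume_threshold_equivalent <- function(map = NULL, chs_cutoff = 2) {
  if (is.null(map)) return(9.3)
  as.numeric(grade_to_volume(map, chs_cutoff + 1))
}

#' Ten-year WMH volume progression
#'
#' Per-participant change between the follow-up volumetric measurement and
#' the volume imputed from the baseline CHS grade via the quadratic map.
#' Participants missing either measurement are skipped and counted.
#'
#' @param cohort A `wmh_cohort` with `chs_grade` and
#'   `followup_wmh_volume_cm3`.
#' @param map A `chs_volume_map`.
#' @return Data.frame (`id`, `baseline_volume_cm3`, `followup_volume_cm3`,
#'   `change_cm3`) for analyzable participants, with attribute `n_skipped`.
#' @export
ten_year_progression <- function(cohort, map) {
  ok <- !is.na(cohort$chs_grade) & !is.na(cohort$followup_wmh_volume_cm3)
  base <- grade_to_volume(map, cohort$chs_grade[ok])
  out <- data.frame(id = cohort$id[ok],
                    baseline_volume_cm3 = as.numeric(base),
                    followup_volume_cm3 = cohort$followup_wmh_volume_cm3[ok])
  out$change_cm3 <- out$followup_volume_cm3 - out$baseline_volume_cm3
  structure(out, n_skipped = sum(!ok))
}

#' @export
print.chs_volume_map <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<chs_volume_map> volume = %.4f + %.4f*grade + %.4f*grade^2\n",
              co["a0"], co["a1"], co["a2"]))
  if (!is.na(x$r_squared))
    cat(sprintf("  fit: R^2 = %.3f on n = %d (grades %g..%g)\n",
                x$r_squared, x$n, x$grade_range[1], x$grade_range[2]))
  invisible(x)
}
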