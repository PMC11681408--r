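# Internal helpers shared across modules.

SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe")

# Ceiling with a guard against binary representation error: a product of
# decimal proportions that is mathematically integral must not be bumped a
# whole participant upward.  Nine decimals is far below any meaningful
# resolution of a sample-size ratio and far above double-precision noise.
ceil_units <- function(x) as.integer(ceiling(round(x, 9)))

# Currency is held internally in integer cents so stage costs and totals are
# exact; dollars appear only at the interface.
dollars_to_cents <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  cents <- round(x * 100)
  if (any(abs(x * 100 - cents) > 1e-6)) {
    stop("costs must be specified to whole cents", call. = FALSE)
  }
  as.numeric(cents)  # numeric: totals can exceed .Machine$integer.max cents
}

cents_to_dollars <- function(x) x / 100

# Severity category for an integer (or binned) score in 0..3.
severity_category <- function(score) {
  factor(SEVERITY_LEVELS[pmin(pmax(score, 0L), 3L) + 1L],
         levels = SEVERITY_LEVELS)
}

# Score threshold implied by a severity-range label.
range_threshold <- function(severity_range) {
  switch(match.arg(severity_range,
                   c("severe", "moderate_severe", "mild_severe")),
         severe = 3L, moderate_severe = 2L, mild_severe = 1L)
}

# Parse a CSV column of booleans in the accepted dialects {0/1, true/false,
# yes/no}, case-insensitive.  Empty cells are missing; anything else is a
# hard error naming the offending row.
parse_boolean_column <- function(x, column) {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  lower <- tolower(x)
  out[lower %in% c("1", "true", "yes")] <- TRUE
  out[lower %in% c("0", "false", "no")] <- FALSE
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf(
      "column '%s': unrecognized boolean value '%s' in row %d (accepted: 0/1, true/false, yes/no)",
      column, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

format_dollars <- function(cents) {
  paste0("$", formatC(cents_to_dollars(cents), format = "f", digits = 2,
                      big.mark = ","))
}
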