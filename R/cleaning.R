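#' Cleaning thresholds for axon-myelin measurements
#'
#' Bundles the biologically informed exclusion thresholds applied before
#' g-ratio analysis.  Axons thinner than `axon_min` are considered below the
#' resolution at which myelination is physiologically meaningful, and myelin
#' sheaths thinner than `myelin_min` are unlikely to provide effective
#' insulation; both defaults come from the ultrastructural literature.
#' G-ratios outside `[g_low, g_high]` fall outside the expected physiological
#' range and are treated as likely segmentation artifacts.
#'
#' Comparisons are strict: a measurement exactly equal to a threshold is
#' retained.
#'
#' @param axon_min Minimum axon diameter in micrometers (default 0.15).
#' @param myelin_min Minimum myelin thickness in micrometers, applied to the
#'   analysis-ready two-sided myelin column (default 0.03).
#' @param g_low,g_high Physiological g-ratio range (defaults 0.5 and 0.9).
#' @param enabled If `FALSE`, threshold and g-range filters are bypassed;
#'   rows with missing or non-finite/non-positive values are still removed.
#' @return An object of class `cleaning_thresholds`.
#' @export
cleaning_thresholds <- function(axon_min = 0.15, myelin_min = 0.03,
                                g_low = 0.5, g_high = 0.9, enabled = TRUE) {
  stopifnot(is.numeric(axon_min), length(axon_min) == 1L, axon_min > 0,
            is.numeric(myelin_min), length(myelin_min) == 1L, myelin_min > 0,
            is.numeric(g_low), is.numeric(g_high), length(g_low) == 1L,
            length(g_high) == 1L, is.logical(enabled), length(enabled) == 1L)
  if (!(0 < g_low && g_low < g_high && g_high < 1))
    stop("g-ratio range must satisfy 0 < g_low < g_high < 1")
  structure(list(axon_min = axon_min, myelin_min = myelin_min,
                 g_low = g_low, g_high = g_high, enabled = enabled),
            class = "cleaning_thresholds")
}

#' @export
print.cleaning_thresholds <- function(x, ...) {
  cat(sprintf(
    "cleaning thresholds: axon >= %g um, myelin >= %g um, g in [%g, %g]%s\n",
    x$axon_min, x$myelin_min, x$g_low, x$g_high,
    if (x$enabled) "" else " [bypassed]"))
  invisible(x)
}

exclusion_reasons <- c("missing", "nonfinite_or_nonpositive",
                       "axon_below_min", "myelin_below_min", "g_out_of_range")

empty_exclusion_log <- function() {
  tibble::tibble(source_row = integer(), sample_id = character(),
                 axon_diameter = numeric(), myelin_total = numeric(),
                 reason = character())
}

make_exclusion_log <- function(records, reason) {
  tibble::tibble(source_row = records$source_row,
                 sample_id = records$sample_id,
                 axon_diameter = records$axon_diameter,
                 myelin_total = records$myelin_total,
                 reason = rep_len(reason, nrow(records)))
}

#' Apply measurement-level cleaning filters
#'
#' Removes rows with missing values, non-finite or non-positive measurements,
#' and (unless bypassed) measurements below the axon and myelin thresholds.
#' Every removed row is logged with exactly one reason code, assigned in the
#' fixed priority order `missing`, `nonfinite_or_nonpositive`,
#' `axon_below_min`, `myelin_below_min`, so the retained and logged row
#' counts always sum to the input count.
#'
#' @param records Measurement tibble as returned by [load_measurements()].
#' @param thresholds A [cleaning_thresholds()] object.
#' @return A list with elements `retained` (tibble) and `log` (exclusion
#'   tibble with columns `source_row`, `sample_id`, `axon_diameter`,
#'   `myelin_total`, `reason`).
#' @export
clean_measurements <- function(records, thresholds = cleaning_thresholds()) {
  stopifnot(inherits(thresholds, "cleaning_thresholds"))
  a <- records$axon_diameter
  m <- records$myelin_total
  reason <- rep(NA_character_, nrow(records))
  is_missing <- is.na(a) | is.na(m)
  reason[is_missing] <- "missing"
  bad <- !is_missing & (!is.finite(a) | !is.finite(m) | a <= 0 | m <= 0)
  reason[bad] <- "nonfinite_or_nonpositive"
  if (thresholds$enabled) {
    ax <- is.na(reason) & a < thresholds$axon_min
    reason[ax] <- "axon_below_min"
    my <- is.na(reason) & m < thresholds$myelin_min
    reason[my] <- "myelin_below_min"
  }
  drop <- !is.na(reason)
  list(retained = records[!drop, , drop = FALSE],
       log = make_exclusion_log(records[drop, , drop = FALSE], reason[drop]))
}

#' Remove fibers with non-physiological g-ratios
#'
#' Retains fibers with `g_low <= g <= g_high` (full-precision g); removals
#' are logged with reason `g_out_of_range`.  A no-op when the thresholds
#' object has `enabled = FALSE`.
#'
#' @param records Fiber tibble from [compute_fiber_and_g()].
#' @inheritParams clean_measurements
#' @return A list with elements `retained` and `log`.
#' @export
filter_physiological_g <- function(records, thresholds = cleaning_thresholds()) {
  stopifnot(inherits(thresholds, "cleaning_thresholds"),
            "g_ratio" %in% names(records))
  if (!thresholds$enabled) {
    return(list(retained = records, log = empty_exclusion_log()))
  }
  keep <- records$g_ratio >= thresholds$g_low & records$g_ratio <= thresholds$g_high
  list(retained = records[keep, , drop = FALSE],
       log = make_exclusion_log(records[!keep, , drop = FALSE], "g_out_of_range"))
}
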