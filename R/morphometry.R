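# Fiber diameter and g-ratio computation.
#
# The g-ratio of a myelinated fiber is g = a / f, where a is the inner axon
# diameter and f = a + My the outer fiber diameter (My being the two-sided
# myelin contribution, i.e. twice the radial sheath thickness m).  Healthy
# mammalian fibers sit near g ~ 0.6-0.8 regardless of caliber, which is what
# makes the g-ratio a sensitive readout of de- and remyelination.

#' Round half away from zero
#'
#' Decimal rounding where exact halves round away from zero (so 0.125 at two
#' decimals gives 0.13), the convention used for reported g-ratios.  Base R's
#' `round()` rounds halves to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  z <- abs(x) * p
  # snap away binary representation noise before testing the half boundary
  z <- round(z, 9)
  sign(x) * floor(z + 0.5) / p
}

#' Compute fiber diameter and g-ratio
#'
#' Adds `fiber_diameter = axon_diameter + myelin_total`, full-precision
#' `g_ratio = axon_diameter / fiber_diameter`, and the two-decimal
#' `g_reported` column (rounded half away from zero).  All downstream
#' statistics use the full-precision column; the rounded column exists only
#' for reporting, since rounding before averaging would bias means by up to
#' 0.005.
#'
#' @param records Cleaned measurement tibble: no missing, non-finite or
#'   non-positive values (enforced; violations are an error because they
#'   indicate cleaning was skipped).
#' @return The tibble with `fiber_diameter`, `g_ratio`, `g_reported` and an
#'   unset `bin_index` column appended.
#' @export
compute_fiber_and_g <- function(records) {
  a <- records$axon_diameter
  m <- records$myelin_total
  if (any(is.na(a) | is.na(m) | !is.finite(a) | !is.finite(m) | a <= 0 | m <= 0))
    stop("non-positive or missing measurements; run clean_measurements() first")
  records$fiber_diameter <- a + m
  records$g_ratio <- a / records$fiber_diameter
  records$g_reported <- round_half_away(records$g_ratio, 2)
  if (!"bin_index" %in% names(records)) records$bin_index <- NA_integer_
  records
}

#' Flag an unexpected fiber-diameter/g-ratio correlation
#'
#' Under the axomyelin unit model the g-ratio is approximately constant
#' across fiber calibers in healthy tissue, so a strong correlation between
#' fiber diameter and g-ratio suggests a methodological artifact
#' (segmentation bias, resolution limits, sampling error) rather than
#' biology.  This diagnostic computes the Pearson correlation between fiber
#' diameter and full-precision g-ratio and raises a flag when both
#' `|r| >= r_threshold` and `p < alpha`.  It never modifies the data.
#'
#' @param records Fiber tibble with at least 3 rows.
#' @param alpha Significance level (default 0.05).
#' @param r_threshold Correlation magnitude considered worth flagging
#'   (default 0.3).
#' @return A list with `r`, `p_value`, `flagged`, `n`.  With zero variance in
#'   either variable `r` is `NA` and the flag is `FALSE`.
#' @export
flag_g_vs_fiber_correlation <- function(records, alpha = 0.05, r_threshold = 0.3) {
  if (nrow(records) < 3L) stop("need at least 3 records for the correlation check")
  f <- records$fiber_diameter
  g <- records$g_ratio
  degenerate <- function(v) stats::sd(v) <= sqrt(.Machine$double.eps) * max(abs(mean(v)), 1e-12)
  if (degenerate(f) || degenerate(g)) {
    return(list(r = NA_real_, p_value = NA_real_, flagged = FALSE,
                n = nrow(records)))
  }
  ct <- stats::cor.test(f, g, method = "pearson")
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(r = r, p_value = p,
       flagged = is.finite(r) && abs(r) >= r_threshold && p < alpha,
       n = nrow(records))
}
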