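#' Derive a six-interval diameter binning scheme from a control dataset
#'
#' Stratifying fibers into diameter bins derived from the control group's
#' distribution lets size-dependent myelination changes be compared on a
#' common scale: the same edges are applied to every group.  Six bins balance
#' resolution against per-bin sample size.
#'
#' @param control Fiber tibble for the designated control dataset.
#' @param variable Which diameter to bin on: `"fiber_diameter"` (default) or
#'   `"axon_diameter"`.
#' @param method `"equal_width"` partitions the control range into six equal
#'   intervals; `"quantile"` places edges at the 0, 1/6, ..., 1 empirical
#'   quantiles so control bins hold equal counts.
#' @param source Free-text identifier of the control dataset recorded in the
#'   scheme for provenance.
#' @return A `bin_scheme` object: 7 strictly ascending edges defining 6
#'   intervals, half-open below the last edge, with the last interval closed.
#' @export
derive_bins <- function(control,
                        variable = c("fiber_diameter", "axon_diameter"),
                        method = c("equal_width", "quantile"),
                        source = "control") {
  variable <- match.arg(variable)
  method <- match.arg(method)
  v <- control[[variable]]
  if (length(v) < 6L)
    stop("need at least 6 control records to derive bins")
  if (length(unique(v)) < 2L)
    stop(sprintf("degenerate control: all %s values are equal", variable))
  edges <- switch(method,
    equal_width = seq(min(v), max(v), length.out = 7L),
    quantile = unname(stats::quantile(v, probs = 0:6 / 6, type = 7)))
  if (any(diff(edges) <= 0))
    stop(sprintf("%s binning of %s produced non-ascending edges; %s",
                 method, variable,
                 "the control distribution is too concentrated for 6 bins"))
  new_bin_scheme(edges, variable, method, source)
}

new_bin_scheme <- function(edges, variable, method, source) {
  stopifnot(is.numeric(edges), length(edges) == 7L, all(diff(edges) > 0))
  structure(list(edges = as.numeric(edges), variable = variable,
                 method = method, source = source),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("6-bin %s scheme on %s (from %s):\n", x$method, x$variable,
              x$source))
  cat(" ", paste(formatC(x$edges, digits = 4, format = "g"), collapse = " | "),
      "\n")
  invisible(x)
}

#' Assign fibers to diameter bins
#'
#' Sets `bin_index` (1-6) by interval membership of the scheme's variable.
#' Bins are half-open `[e_i, e_{i+1})` except the last, which is closed at
#' the top.  Values outside the control-derived range (possible for
#' experimental groups) are clamped into the first or last bin rather than
#' dropped, and counted in the out-of-range log so the clamping is visible.
#'
#' @param records Fiber tibble.
#' @param scheme A `bin_scheme` from [derive_bins()].
#' @return A list: `records` with `bin_index` set, and `out_of_range`, a
#'   tibble of clamped rows (`source_row`, `sample_id`, `value`, `side`).
#' @export
assign_bins <- function(records, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  v <- records[[scheme$variable]]
  idx <- findInterval(v, scheme$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  records$bin_index <- as.integer(idx)
  low <- v < scheme$edges[1]
  high <- v > scheme$edges[7]
  out <- low | high
  oor <- tibble::tibble(
    source_row = records$source_row[out],
    sample_id = records$sample_id[out],
    value = v[out],
    side = ifelse(v[out] < scheme$edges[1], "below", "above"))
  list(records = records, out_of_range = oor)
}
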