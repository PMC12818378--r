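# Hartigan's dip test for multimodality.
#
# The dip statistic of a sample is the smallest sup-norm distance between
# its empirical CDF and any unimodal CDF.  It is computed exactly (to 1e-14)
# in compiled code by bisection on that distance; feasibility of a given
# distance is decided by propagating the reachable set of (value, slope)
# states of the convex rising branch along the sorted sample and matching it
# against the mirrored concave branch at every possible mode position,
# including modes carrying an atom at a tied value.

the <- new.env(parent = emptyenv())

dip_null_table <- function() {
  if (is.null(the$dip_tab)) {
    path <- system.file("extdata", "dip_null_quantiles.tsv", package = "gratio")
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    the$dip_tab <- list(
      n = tab$n,
      probs = as.numeric(sub("^p", "", colnames(tab)[-1])),
      # quantiles on the sqrt(n)-stabilized scale for interpolation across n
      q = as.matrix(tab[, -1]) * sqrt(tab$n))
  }
  the$dip_tab
}

#' Dip statistic
#'
#' @param x Numeric vector (at least one finite value).
#' @return The dip statistic, the minimal sup-norm distance between the
#'   empirical CDF of `x` and the closest unimodal CDF.  Always in
#'   `[0, 0.25]`; at least `1/(2n)` for samples with distinct values.
#' @export
dip_stat <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) stop("need at least one finite value")
  dip_stat_cpp(as.numeric(x))
}

#' Hartigan's dip test for multimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution.  The default p-value interpolates a table of null
#' quantiles, simulated once from uniform samples (the asymptotically least
#' favorable unimodal null) on the \eqn{\sqrt{n}}-stabilized scale;
#' `method = "bootstrap"` instead simulates `B` uniform samples of the same
#' size at call time.
#'
#' @param x Numeric vector; at least 4 finite values are required for a
#'   p-value (fewer yield `NA` statistics, since multimodality is
#'   meaningless at such sizes).
#' @param method `"table"` (default) or `"bootstrap"`.
#' @param B Number of bootstrap null samples when `method = "bootstrap"`.
#' @return A list with `statistic`, `p_value`, `n`, `method`.
#' @export
dip_test <- function(x, method = c("table", "bootstrap"), B = 500) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                method = method))
  }
  d <- dip_stat_cpp(as.numeric(x))
  p <- switch(method,
    table = dip_pvalue_table(d, n),
    bootstrap = {
      null <- vapply(seq_len(B),
                     function(i) dip_stat_cpp(stats::runif(n), tol = 1e-7),
                     numeric(1))
      (1 + sum(null >= d)) / (B + 1)
    })
  list(statistic = d, p_value = p, n = n, method = method)
}

dip_pvalue_table <- function(d, n) {
  tab <- dip_null_table()
  ns <- tab$n
  i <- findInterval(n, ns)
  if (i < 1L) i <- 1L
  if (i >= length(ns)) {
    qn <- tab$q[length(ns), ]
  } else if (ns[i] == n) {
    qn <- tab$q[i, ]
  } else {
    w <- (log(n) - log(ns[i])) / (log(ns[i + 1]) - log(ns[i]))
    qn <- (1 - w) * tab$q[i, ] + w * tab$q[i + 1, ]
  }
  qn <- cummax(qn)                      # enforce monotone quantile function
  z <- sqrt(n) * d
  if (z <= qn[1]) return(1)
  if (z >= qn[length(qn)]) return(0)
  cdf <- stats::approx(qn, tab$probs, xout = z, ties = "ordered")$y
  max(0, min(1, 1 - cdf))
}
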