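#' Per-bin descriptive and distributional statistics
#'
#' For each of the six bins: count, mean, median and sample (n-1) standard
#' deviation of the full-precision g-ratio, a Shapiro-Wilk normality test
#' (when 3 <= n <= 5000 and the values are not constant), and Hartigan's dip
#' test for multimodality (when n >= 4).  Empty bins produce a row with
#' `n = 0` and `NA` statistics, so the result always has six rows.
#'
#' Per-bin Shapiro-Wilk p-values are reported raw, without multiplicity
#' correction: they are descriptive profiling, and at large per-bin n the
#' test flags trivial departures from normality.
#'
#' @param records Fiber tibble with `bin_index` assigned.
#' @param scheme The `bin_scheme` used for assignment.
#' @param dip Compute dip statistics (default `TRUE`; the table-based
#'   p-value is cheap, but `FALSE` skips the dip entirely).
#' @return A tibble with one row per bin: `bin_index`, `n`, `mean_g`,
#'   `median_g`, `sd_g`, `shapiro_W`, `shapiro_p`, `dip_stat`, `dip_p`.
#' @export
summarize_bins <- function(records, scheme, dip = TRUE) {
  stopifnot(inherits(scheme, "bin_scheme"), "bin_index" %in% names(records))
  rows <- lapply(1:6, function(b) {
    g <- records$g_ratio[records$bin_index == b]
    g <- g[!is.na(g)]
    n <- length(g)
    out <- tibble::tibble(
      bin_index = b, n = n,
      mean_g = if (n > 0) mean(g) else NA_real_,
      median_g = if (n > 0) stats::median(g) else NA_real_,
      sd_g = if (n > 1) stats::sd(g) else if (n == 1) 0 else NA_real_,
      shapiro_W = NA_real_, shapiro_p = NA_real_,
      dip_stat = NA_real_, dip_p = NA_real_)
    if (n >= 3 && n <= 5000 && stats::sd(g) > 0) {
      sw <- stats::shapiro.test(g)
      out$shapiro_W <- unname(sw$statistic)
      out$shapiro_p <- sw$p.value
    }
    if (dip && n >= 4) {
      dt <- dip_test(g)
      out$dip_stat <- dt$statistic
      out$dip_p <- dt$p_value
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Grand mean g-ratio from bin means
#'
#' The constant-g model treats the g-ratio as a single constant across fiber
#' calibers; fitting it to the six bin means by least squares yields their
#' arithmetic mean (`method = "unweighted"`, the default, which weights each
#' diameter cohort equally regardless of how many fibers it holds).  The
#' `"n_weighted"` variant weights bins by their counts and therefore equals
#' the pooled mean over all records.
#'
#' @param summaries Six-row tibble from [summarize_bins()].
#' @param method `"unweighted"` or `"n_weighted"`.
#' @return A list with `value`, `method`, `bin_means_used`, `bin_n`.
#' @export
grand_mean_g <- function(summaries, method = c("unweighted", "n_weighted")) {
  method <- match.arg(method)
  nonempty <- summaries$n > 0
  if (!any(nonempty)) stop("all bins are empty; cannot fit a grand mean")
  m <- summaries$mean_g[nonempty]
  n <- summaries$n[nonempty]
  value <- switch(method,
    unweighted = mean(m),
    n_weighted = sum(m * n) / sum(n))
  list(value = value, method = method, bin_means_used = m, bin_n = n)
}

#' Two-way group-by-bin analysis of variance
#'
#' Fixed-effects factorial ANOVA of the full-precision g-ratio on group,
#' diameter bin and their interaction.  The interaction term asks whether a
#' treatment effect differs across fiber calibers.  Sums of squares are
#' Type II (each main effect adjusted for the other, the interaction
#' adjusted for both), which is well defined for the unbalanced per-bin
#' counts this design always produces; for balanced data it coincides with
#' the classical decomposition.
#'
#' @param records Fiber tibble containing at least two `group_label` levels,
#'   with `bin_index` assigned under one shared scheme.
#' @param scheme The shared `bin_scheme` (used for validation only).
#' @return A tibble with rows `group`, `bin`, `group:bin`, `residual` and
#'   columns `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(records, scheme = NULL) {
  if (!is.null(scheme)) stopifnot(inherits(scheme, "bin_scheme"))
  d <- data.frame(g = records$g_ratio,
                  group = factor(records$group_label),
                  bin = factor(records$bin_index))
  if (nlevels(d$group) < 2L) stop("need at least 2 groups")
  if (nlevels(d$bin) < 2L) stop("need at least 2 non-empty bins")
  cells <- table(d$group, d$bin)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty group x bin cells: ",
         paste(sprintf("%s x bin %s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  n <- nrow(d)
  df_res <- n - nlevels(d$group) * nlevels(d$bin)
  if (df_res <= 0) stop("zero residual degrees of freedom")
  fit <- stats::lm(g ~ group * bin, data = d)
  a2 <- car::Anova(fit, type = 2)
  ss <- a2[["Sum Sq"]]
  df <- a2[["Df"]]
  fv <- a2[["F value"]]
  pv <- a2[["Pr(>F)"]]
  tibble::tibble(
    term = c("group", "bin", "group:bin", "residual"),
    df = df, sum_sq = ss, mean_sq = ss / df,
    F = fv, p = pv)
}
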