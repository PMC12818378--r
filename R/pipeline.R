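# End-to-end orchestration: the analysis workflow for a single group and the
# two-group comparison workflow.  Every stage's input and output row counts
# are recorded in a run manifest so row conservation can be audited.

stage_counts <- function(manifest, stage, n_in, n_out, n_logged = n_in - n_out) {
  rbind(manifest, data.frame(stage = stage, rows_in = n_in, rows_out = n_out,
                             rows_logged = n_logged))
}

write_manifest <- function(manifest, config_lines, files, out_dir) {
  path <- file.path(out_dir, "run_manifest.txt")
  lines <- c(
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "", "configuration:", paste0("  ", config_lines), "", "stages:",
    sprintf("  %-22s in=%6d out=%6d logged=%5d", manifest$stage,
            manifest$rows_in, manifest$rows_out, manifest$rows_logged),
    "", "outputs:", paste0("  ", names(files), ": ", unlist(files)))
  writeLines(lines, path)
  path
}

#' Run the single-group g-ratio analysis workflow
#'
#' Executes load, clean, fiber/g computation, physiological-g filtering,
#' bin derivation (or application of a supplied scheme), per-bin summaries,
#' grand mean, and the fiber-diameter/g correlation diagnostic; writes the
#' cleaned-data, summary and exclusion workbooks plus optional plots and a
#' run manifest into `out_dir`.
#'
#' @param input Path to the input workbook.
#' @param group_label Label for this dataset (e.g. "CTL").
#' @param out_dir Output directory.
#' @param thresholds A [cleaning_thresholds()] object.
#' @param scheme A `bin_scheme` to apply; `NULL` (default) derives one from
#'   this dataset, which is the control-group workflow.
#' @param variable,method Passed to [derive_bins()] when `scheme` is `NULL`.
#' @param myelin Input myelin convention, see [load_measurements()].
#' @param grand_method Grand-mean method, see [grand_mean_g()].
#' @param plots Emit figures (default `TRUE`).
#' @param dip Compute per-bin dip statistics (default `TRUE`).
#' @return A list: `records` (analysis-ready fibers with bins),
#'   `summaries`, `grand_g`, `correlation`, `scheme`, `exclusions`,
#'   `out_of_range`, `files`, `manifest`.
#' @export
run_analysis <- function(input, group_label, out_dir,
                         thresholds = cleaning_thresholds(), scheme = NULL,
                         variable = c("fiber_diameter", "axon_diameter"),
                         method = c("equal_width", "quantile"),
                         myelin = c("two-sided", "one-sided"),
                         grand_method = c("unweighted", "n_weighted"),
                         plots = TRUE, dip = TRUE) {
  variable <- match.arg(variable); method <- match.arg(method)
  myelin <- match.arg(myelin); grand_method <- match.arg(grand_method)
  manifest <- NULL
  raw <- load_measurements(input, group_label, myelin = myelin)
  manifest <- stage_counts(manifest, "load", nrow(raw), nrow(raw), 0L)
  cl <- clean_measurements(raw, thresholds)
  manifest <- stage_counts(manifest, "clean", nrow(raw), nrow(cl$retained))
  fib <- compute_fiber_and_g(cl$retained)
  gf <- filter_physiological_g(fib, thresholds)
  manifest <- stage_counts(manifest, "g_range_filter", nrow(fib),
                           nrow(gf$retained))
  fib <- gf$retained
  exclusions <- dplyr::bind_rows(cl$log, gf$log)
  if (is.null(scheme))
    scheme <- derive_bins(fib, variable = variable, method = method,
                          source = group_label)
  ab <- assign_bins(fib, scheme)
  fib <- ab$records
  manifest <- stage_counts(manifest, "bin_assignment", nrow(fib), nrow(fib),
                           nrow(ab$out_of_range))
  summaries <- summarize_bins(fib, scheme, dip = dip)
  gg <- grand_mean_g(summaries, method = grand_method)
  corr <- if (nrow(fib) >= 3) flag_g_vs_fiber_correlation(fib) else NULL
  files <- write_outputs(fib, summaries, exclusions, out_dir,
                         scheme = scheme, grand_g = gg, correlation = corr)
  if (plots) {
    pf <- make_plots(fib, out_dir = out_dir, prefix = group_label)
    files <- c(files, pf)
  }
  cfg <- c(sprintf("input: %s", input),
           sprintf("group: %s", group_label),
           sprintf("myelin convention: %s", myelin),
           sprintf("thresholds: axon>=%g myelin>=%g g=[%g,%g] enabled=%s",
                   thresholds$axon_min, thresholds$myelin_min,
                   thresholds$g_low, thresholds$g_high, thresholds$enabled),
           sprintf("bins: %s %s [%s]", scheme$method, scheme$variable,
                   paste(formatC(scheme$edges, format = "g"), collapse = ", ")))
  files["manifest"] <- write_manifest(manifest, cfg, files, out_dir)
  list(records = fib, summaries = summaries, grand_g = gg,
       correlation = corr, scheme = scheme, exclusions = exclusions,
       out_of_range = ab$out_of_range, files = files, manifest = manifest)
}

#' Run the two-group comparison workflow
#'
#' Derives the bin scheme from the control workbook, applies it to both
#' groups, summarizes each group per bin, and tests for group, bin and
#' group-by-bin effects with a two-way ANOVA.  Comparison figures overlay
#' the two groups.
#'
#' @param control,experimental Paths to the two input workbooks.
#' @param out_dir Output directory.
#' @param control_label,experimental_label Group labels.
#' @param thresholds,variable,method,myelin,grand_method,plots,dip As in
#'   [run_analysis()].
#' @return A list: `control`, `experimental` (each as from
#'   [run_analysis()], without files), `anova`, `scheme`, `files`.
#' @export
run_comparison <- function(control, experimental, out_dir,
                           control_label = "CTL",
                           experimental_label = "EXP",
                           thresholds = cleaning_thresholds(),
                           variable = c("fiber_diameter", "axon_diameter"),
                           method = c("equal_width", "quantile"),
                           myelin = c("two-sided", "one-sided"),
                           grand_method = c("unweighted", "n_weighted"),
                           plots = TRUE, dip = TRUE) {
  variable <- match.arg(variable); method <- match.arg(method)
  myelin <- match.arg(myelin); grand_method <- match.arg(grand_method)
  ctl_dir <- file.path(out_dir, control_label)
  ctl <- run_analysis(control, control_label, ctl_dir,
                      thresholds = thresholds, variable = variable,
                      method = method, myelin = myelin,
                      grand_method = grand_method, plots = plots, dip = dip)
  exp_dir <- file.path(out_dir, experimental_label)
  exp <- run_analysis(experimental, experimental_label, exp_dir,
                      thresholds = thresholds, scheme = ctl$scheme,
                      myelin = myelin, grand_method = grand_method,
                      plots = plots, dip = dip)
  both <- dplyr::bind_rows(ctl$records, exp$records)
  aov_tab <- two_way_anova(both, ctl$scheme)
  paired <- dplyr::bind_rows(
    dplyr::mutate(ctl$summaries, group = control_label, .before = 1),
    dplyr::mutate(exp$summaries, group = experimental_label, .before = 1))
  files <- c()
  f <- file.path(out_dir, "comparison.xlsx")
  write_xlsx(list(bin_summary = paired, anova = aov_tab,
                  grand_g = tibble::tibble(
                    group = c(control_label, experimental_label),
                    method = grand_method,
                    grand_g = c(ctl$grand_g$value, exp$grand_g$value))), f)
  files["comparison"] <- f
  if (plots) {
    pf <- make_comparison_plots(both, out_dir)
    files <- c(files, pf)
  }
  list(control = ctl, experimental = exp, anova = aov_tab,
       scheme = ctl$scheme, summaries = paired, files = files)
}
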