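# Workbook input/output.
#
# Input contract: XLS/XLSX workbooks, header in row 1, per-sample paired
# numeric columns named <Sample>_Ax (axon diameter, um) and <Sample>_My
# (myelin thickness, um, two-sided).  Columns pair by exact shared prefix;
# the suffix match is case-sensitive.

#' Load paired axon/myelin measurements from a workbook
#'
#' Reads every sheet, pairs `<prefix>_Ax` with `<prefix>_My` columns by
#' exact prefix, and stacks them into one record per row.  Cells that do not
#' parse as numbers (and trailing rows of a shorter column in a ragged
#' sheet) become missing values: they are retained here and removed -- with
#' logging -- by [clean_measurements()], so that the exclusion log accounts
#' for every input row.
#'
#' If the myelin columns hold one-sided (radial) sheath thicknesses, set
#' `myelin = "one-sided"` to double them at load; all analysis assumes the
#' two-sided convention.  There is no auto-detection.
#'
#' @param path Path to an .xlsx/.xls workbook.
#' @param group_label Group label stored on every record (e.g. "CTL").
#' @param myelin `"two-sided"` (default) or `"one-sided"`.
#' @return A tibble with columns `sample_id`, `group_label`,
#'   `axon_diameter`, `myelin_total`, `source_row` (1-based row in the
#'   source sheet, header row included).
#' @export
load_measurements <- function(path, group_label,
                              myelin = c("two-sided", "one-sided")) {
  myelin <- match.arg(myelin)
  if (!file.exists(path)) stop("workbook not found: ", path)
  sheets <- readxl::excel_sheets(path)
  out <- list()
  found_any <- FALSE
  for (sh in sheets) {
    df <- suppressWarnings(
      readxl::read_excel(path, sheet = sh, .name_repair = "minimal"))
    nms <- names(df)
    ax_cols <- nms[endsWith(nms, "_Ax")]
    my_cols <- nms[endsWith(nms, "_My")]
    ax_pref <- sub("_Ax$", "", ax_cols)
    my_pref <- sub("_My$", "", my_cols)
    lonely <- c(setdiff(ax_pref, my_pref), setdiff(my_pref, ax_pref))
    if (length(lonely))
      stop("missing counterpart column for sample(s): ",
           paste(lonely, collapse = ", "), " in sheet '", sh, "'")
    as_num <- function(col) {
      if (is.numeric(col)) return(as.numeric(col))
      suppressWarnings(as.numeric(as.character(col)))
    }
    for (p in ax_pref) {
      found_any <- TRUE
      a <- as_num(df[[paste0(p, "_Ax")]])
      m <- as_num(df[[paste0(p, "_My")]])
      keep <- seq_len(max(which(!is.na(a) | !is.na(m)), 0L))
      if (length(keep) == 0L) next
      a <- a[keep]; m <- m[keep]
      if (myelin == "one-sided") m <- 2 * m
      out[[length(out) + 1L]] <- tibble::tibble(
        sample_id = p, group_label = group_label,
        axon_diameter = a, myelin_total = m,
        source_row = keep + 1L)
    }
  }
  if (!found_any)
    stop("empty workbook: no paired <Sample>_Ax / <Sample>_My columns found")
  dplyr::bind_rows(out)
}

#' Write pipeline outputs
#'
#' Writes up to three workbooks into `out_dir`:
#' `cleaned_data.xlsx` (one sheet per sample with full-precision `_Ax` and
#' `_My` columns plus the reported two-decimal g-ratio), `bin_summary.xlsx`
#' (per-bin statistics, grand mean, bin scheme, and optional correlation
#' diagnostic and ANOVA sheets), and `exclusions.xlsx` (one row per removed
#' record with its reason code).  Re-loading `cleaned_data.xlsx` with
#' [load_measurements()] reproduces the retained records exactly.
#'
#' @param records Fiber tibble of retained records.
#' @param summaries Per-bin summary tibble (or `NULL`).
#' @param log Exclusion log tibble.
#' @param out_dir Output directory (created if needed).
#' @param scheme,grand_g,correlation,anova Optional extra results to embed
#'   in the summary workbook.
#' @return Named character vector of the files written.
#' @export
write_outputs <- function(records, summaries, log, out_dir,
                          scheme = NULL, grand_g = NULL, correlation = NULL,
                          anova = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  cleaned <- list()
  for (sid in unique(records$sample_id)) {
    r <- records[records$sample_id == sid, ]
    df <- tibble::tibble(r$axon_diameter, r$myelin_total)
    names(df) <- paste0(sid, c("_Ax", "_My"))
    if (!is.null(r$g_ratio)) {
      df[[paste0(sid, "_G")]] <- round_half_away(r$g_ratio, 2)
    }
    cleaned[[sid]] <- df
  }
  if (length(cleaned)) {
    f <- file.path(out_dir, "cleaned_data.xlsx")
    write_xlsx(cleaned, f)
    files["cleaned_data"] <- f
  }
  summary_sheets <- list()
  if (!is.null(summaries)) summary_sheets$bin_summary <- summaries
  if (!is.null(grand_g))
    summary_sheets$grand_g <- tibble::tibble(
      method = grand_g$method, grand_g = grand_g$value)
  if (!is.null(scheme))
    summary_sheets$bin_scheme <- tibble::tibble(
      edge = scheme$edges, variable = scheme$variable,
      method = scheme$method, source = scheme$source)
  if (!is.null(correlation))
    summary_sheets$correlation <- tibble::tibble(
      r = correlation$r, p_value = correlation$p_value,
      flagged = correlation$flagged, n = correlation$n)
  if (!is.null(anova)) summary_sheets$anova <- anova
  if (length(summary_sheets)) {
    f <- file.path(out_dir, "bin_summary.xlsx")
    write_xlsx(summary_sheets, f)
    files["bin_summary"] <- f
  }
  f <- file.path(out_dir, "exclusions.xlsx")
  write_xlsx(list(exclusions = as.data.frame(log)), f)
  files["exclusions"] <- f
  files
}
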