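# Figures: per-sample axon-vs-fiber scatter with an ordinary least-squares
# line (the axomyelin unit model predicts a straight line), per-sample
# g-ratio histograms on a frequency-% scale, and two-group overlays.

plot_device_ext <- function() {
  if (capabilities("png")) "png" else "pdf"
}

save_plot <- function(p, path_base, width = 6, height = 4.5) {
  ext <- plot_device_ext()
  path <- paste0(path_base, ".", ext)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  path
}

#' Diagnostic plots for one analyzed group
#'
#' Writes, per sample, an axon-versus-fiber-diameter scatter plot with a
#' linear fit and a g-ratio histogram normalized to frequency percent
#' (20 bins).  Samples with fewer than 2 points are skipped with a warning.
#'
#' @param records Fiber tibble.
#' @param out_dir Output directory.
#' @param prefix File-name prefix (typically the group label).
#' @return Named character vector of files written.
#' @export
make_plots <- function(records, out_dir, prefix = "group") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (sid in unique(records$sample_id)) {
    r <- records[records$sample_id == sid, ]
    if (nrow(r) < 2) {
      warning("too few points to plot for sample ", sid)
      next
    }
    p1 <- ggplot2::ggplot(r, ggplot2::aes(.data$axon_diameter,
                                          .data$fiber_diameter)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.6, color = "#c0392b") +
      ggplot2::labs(x = "axon diameter (µm)",
                    y = "fiber diameter (µm)",
                    title = paste0(sid, ": axon vs fiber diameter")) +
      ggplot2::theme_minimal()
    files[paste0(sid, "_scatter")] <-
      save_plot(p1, file.path(out_dir, paste0(prefix, "_", sid, "_scatter")))
    p2 <- ggplot2::ggplot(r, ggplot2::aes(.data$g_ratio)) +
      ggplot2::geom_histogram(ggplot2::aes(
        y = ggplot2::after_stat(count / sum(count) * 100)),
        bins = 20, fill = "#2980b9", color = "white") +
      ggplot2::labs(x = "g-ratio", y = "frequency (%)",
                    title = paste0(sid, ": g-ratio distribution")) +
      ggplot2::theme_minimal()
    files[paste0(sid, "_hist")] <-
      save_plot(p2, file.path(out_dir, paste0(prefix, "_", sid, "_hist")))
  }
  files
}

#' Two-group comparison figures
#'
#' Overlaid g-ratio histograms (frequency %) and a per-bin mean plot.
#'
#' @param records Combined fiber tibble for both groups with bins assigned.
#' @param out_dir Output directory.
#' @return Named character vector of files written.
#' @export
make_comparison_plots <- function(records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  p1 <- ggplot2::ggplot(records, ggplot2::aes(.data$g_ratio,
                                              fill = .data$group_label)) +
    ggplot2::geom_histogram(ggplot2::aes(
      y = ggplot2::after_stat(density)), bins = 20, alpha = 0.5,
      position = "identity") +
    ggplot2::labs(x = "g-ratio", y = "density", fill = "group") +
    ggplot2::theme_minimal()
  files["comparison_hist"] <- save_plot(p1, file.path(out_dir, "comparison_hist"))
  means <- dplyr::summarise(
    dplyr::group_by(records, .data$group_label, .data$bin_index),
    mean_g = mean(.data$g_ratio), sd_g = stats::sd(.data$g_ratio),
    .groups = "drop")
  p2 <- ggplot2::ggplot(means, ggplot2::aes(.data$bin_index, .data$mean_g,
                                            color = .data$group_label)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_g - .data$sd_g,
                                        ymax = .data$mean_g + .data$sd_g),
                           width = 0.15) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "fiber diameter bin", y = "mean g-ratio ± SD",
                  color = "group") +
    ggplot2::theme_minimal()
  files["comparison_bins"] <- save_plot(p2, file.path(out_dir, "comparison_bins"))
  files
}
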