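#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot condition means with standard-error bars
#'
#' Per-stimulus mean conditioned response with +/- 1 standard error,
#' faceted by group when a group column is present. Constant data yield
#' zero-height error bars.
#'
#' @inheritParams cs_descriptives
#' @return A ggplot object.
#' @examples
#' tbl <- simulate_cs(n = 30, mu1 = 5, mu2 = 3, sigma = 2, rho = 0.5, seed = 2)
#' plot_cs_means(tbl)
#' @export
plot_cs_means <- function(table) {
  desc <- cs_descriptives(table)
  desc$stimulus <- toupper(desc$stimulus)
  p <- ggplot2::ggplot(desc, ggplot2::aes(x = .data$stimulus, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.15
    ) +
    ggplot2::labs(
      x = "Stimulus", y = "Mean conditioned response (+/- 1 SE)"
    ) +
    ggplot2::theme_minimal()
  if ("group" %in% names(desc)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}

#' Robustness plot of the Bayes factor over the prior scale
#'
#' BF10 (log scale) against the Cauchy prior scale r, with a dashed
#' reference line at BF = 1 (equal support) and highlighted markers at
#' whichever of the conventional scales (0.707, 1, 1.414) appear in the
#' grid.
#'
#' @param object A `cs_sensitivity` tibble from [bf_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(bf_sensitivity(2.92, n1 = 40, scales = seq(0.1, 2, by = 0.1)))
#' @export
autoplot.cs_sensitivity <- function(object, ...) {
  df <- as_tibble(object)
  canon <- df[df$scale %in% canonical_scales(), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$bf10)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1)
  if (nrow(canon) > 0L) {
    p <- p + ggplot2::geom_point(data = canon, size = 2.5, shape = 21, fill = "white")
  }
  p +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Cauchy prior scale r", y = "BF10 (log scale)",
      title = "Robustness of the Bayes factor to the prior scale"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cs_sensitivity
#' @param curve A `cs_sensitivity` tibble.
#' @export
plot_robustness <- function(curve) autoplot(curve)

#' Write analysis plots to files
#'
#' Writes the condition-means plot (when the bundle carries raw data)
#' and the robustness plot (when it carries a sensitivity curve) into
#' `dir`, each as both PNG and SVG.
#'
#' @param x A `cs_analysis` bundle.
#' @param dir Output directory (created if absent).
#' @param width,height Device size in inches.
#' @return Character vector of files written, invisibly.
#' @export
write_cs_plots <- function(x, dir, width = 6, height = 4) {
  stopifnot(inherits(x, "cs_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  save_both <- function(plot, stem) {
    png_path <- file.path(dir, paste0(stem, ".png"))
    svg_path <- file.path(dir, paste0(stem, ".svg"))
    ggplot2::ggsave(png_path, plot,
      width = width, height = height, dpi = 150
    )
    ggplot2::ggsave(svg_path, plot,
      width = width, height = height, device = grDevices::svg
    )
    c(png_path, svg_path)
  }
  if (!is.null(x$table)) {
    written <- c(written, save_both(plot_cs_means(x$table), "means"))
  }
  if (!is.null(x$sensitivity)) {
    written <- c(written, save_both(autoplot(x$sensitivity), "robustness"))
  }
  invisible(written)
}
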