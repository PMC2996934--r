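#' Plot SNP density along chromosomes
#'
#' One panel per chromosome; undetermined (fully-N) windows are drawn in
#' grey at zero.
#'
#' @param object A `window_table` from [window_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$n_snps,
                                   fill = .data$undetermined)) +
    ggplot2::geom_col(width = attr(object, "window") / 1e6) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#2c7fb8", `TRUE` = "grey70"),
                               guide = "none") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)",
                  y = sprintf("SNPs per %s window",
                              format(attr(object, "window"), big.mark = ",")),
                  title = "SNP density in fixed windows")
}

#' Plot window-occupancy curves
#'
#' Fraction of windows holding at least one SNP against window size, one
#' line per site category when a `category` column is present.
#'
#' @param object An `occupancy_curve` from [occupancy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_curve <- function(object, ...) {
  df <- as_tibble(object)
  p <- if ("category" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$window_size, y = .data$fraction,
                                     colour = .data$category))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$window_size, y = .data$fraction))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10(labels = function(x) format(x, big.mark = ",")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Window size (bases)",
                  y = "Fraction of windows with ≥ 1 SNP",
                  colour = "Category",
                  title = "SNP window occupancy")
}

#' Plot a panel design's selections along the genome
#'
#' @param object A `panel_design` from [design_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panel_design <- function(object, ...) {
  df <- as_tibble(object$selected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$chrom,
                                   colour = .data$source)) +
    ggplot2::geom_point(shape = 124, size = 3) +
    ggplot2::labs(x = "Position (Mb)", y = NULL, colour = "Source category",
                  title = sprintf("Genotyping panel (%s-bp windows, %d assays)",
                                  format(object$spacing, big.mark = ","),
                                  nrow(df)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
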