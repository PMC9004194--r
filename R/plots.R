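#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean density profiles across window sizes
#'
#' Average density over all genes as a function of window length, one line
#' per TE grouping, faceted by direction — the standard way to eyeball how a
#' genome's TE landscape falls off with distance from genes.
#'
#' @param object A `density_data` accessor.
#' @param level `"order"` or `"superfamily"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_data <- function(object, level = c("order", "superfamily"), ...) {
  level <- rlang::arg_match(level)
  df <- tidy(object[[level]]) |>
    dplyr::group_by(.data$identity, .data$window, .data$direction) |>
    dplyr::summarise(mean_density = mean(.data$density), .groups = "drop") |>
    dplyr::mutate(direction = factor(.data$direction, levels = .DIRECTIONS_SWAPPED))
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$mean_density,
                                   colour = .data$identity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
    ggplot2::labs(
      x = "Window (bp)", y = "Mean TE density", colour = paste0("TE ", level),
      title = sprintf("Mean %s-level TE density, pseudomolecule %s",
                      level, object$pseudomolecule)
    ) +
    ggplot2::theme_minimal()
}

#' Plot gene counts per density bin
#'
#' @param object A `density_binning` from [bin_genes_by_density()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-bin gene counts.
#' @export
autoplot.density_binning <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(label = sprintf("[%.1f,%.1f%s", .data$bin_low, .data$bin_high,
                                  ifelse(.data$right_closed, "]", ")")))
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "TE density bin", y = "Number of genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of syntelog density differences
#'
#' Nonzero pairwise differences binned at 0.1 width, matching the binning
#' convention used for densities (all bins half-open except the last).
#'
#' @param object A `syntelog_differences` tibble.
#' @param ... Unused.
#' @return A ggplot histogram.
#' @export
autoplot.syntelog_differences <- function(object, ...) {
  df <- as_tibble(object) |> dplyr::filter(.data$difference != 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$difference)) +
    ggplot2::geom_histogram(breaks = seq(-1, 1, by = 0.1), closed = "left",
                            boundary = 0) +
    ggplot2::labs(x = "TE density difference (genome A - genome B)",
                  y = "Syntelog pairs") +
    ggplot2::theme_minimal()
}
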