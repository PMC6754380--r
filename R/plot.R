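#' Plot a windowed recombination map
#'
#' Columns show crossover counts (or cM) per window along each chromosome,
#' the standard genome-track view of a recombination landscape.
#'
#' @param object An `lr_map` from [build_map()].
#' @param value `"n_crossovers"` (default) or `"cM"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lr_map <- function(object, value = c("n_crossovers", "cM"), ...) {
  value <- match.arg(value)
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data[[value]])
  ) +
    ggplot2::geom_col(width = attr(object, "window_bp") / 1e6,
                      fill = "darkorange") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "position (Mb)",
      y = if (value == "cM") "recombination rate (cM)" else "crossovers per window"
    ) +
    ggplot2::theme_minimal()
}

#' Plot pipeline results: map plus molecule classes
#'
#' @param object An `lr_result` from [detect_recombinant_molecules()].
#' @param window_bp Window width for the crossover track (default 50 kb).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lr_result <- function(object, window_bp = 50000, ...) {
  map <- build_map(object$crossovers, object$molecules, window_bp = window_bp)
  autoplot.lr_map(map)
}

#' Histogram of crossover resolution
#'
#' Resolution is the distance between the two informative variants flanking
#' a crossover -- the physical uncertainty of its position.
#'
#' @param crossovers Crossover tibble from [call_crossovers()].
#' @param binwidth Histogram bin width in kb (default 2).
#' @return A ggplot object.
#' @export
plot_crossover_resolution <- function(crossovers, binwidth = 2) {
  ggplot2::ggplot(crossovers,
                  ggplot2::aes(x = .data$resolution_bp / 1e3)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "crossover resolution (kb)", y = "crossovers") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
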