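#' Plot the nearest-TSS distance histogram
#'
#' Renders the bin table from [distance_histogram()] (overflow rows
#' dropped) as a bar chart of peak counts per distance bin.
#'
#' @param bins A tibble from [distance_histogram()].
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(bins) {
  b <- filter(bins, .data$type == "bin")
  ggplot2::ggplot(b, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                  y = .data$count,
                                  width = .data$upper - .data$lower)) +
    ggplot2::geom_col(fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "Distance to nearest TSS (bases)", y = "Peaks") +
    ggplot2::theme_minimal()
}

#' Plot relative-position class counts
#'
#' Bar chart of the per-class peak counts from
#' [relative_position_counts()] (the tabular equivalent of the classic
#' pie chart of peak positions relative to the nearest gene).
#'
#' @param counts A tibble from [relative_position_counts()].
#' @return A ggplot object.
#' @export
plot_relative_positions <- function(counts) {
  lev <- c("upstream", "overlapStart", "inside", "includeFeature",
           "overlapEnd", "downstream")
  counts$insideFeature <- factor(counts$insideFeature,
                                 levels = intersect(lev, counts$insideFeature))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$insideFeature, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange", colour = "grey30") +
    ggplot2::labs(x = "Position relative to nearest gene", y = "Peaks") +
    ggplot2::theme_minimal()
}

#' @rdname plot_distance_histogram
#' @param object A `venn_report` object.
#' @param ... Unused.
#' @export
autoplot.venn_report <- function(object, ...) {
  ggplot2::ggplot(object$cell_counts,
                  ggplot2::aes(x = .data$pattern, y = .data$count)) +
    ggplot2::geom_col(fill = "seagreen", colour = "grey30") +
    ggplot2::labs(x = paste0("Membership pattern (",
                             paste(object$labels, collapse = "/"), ")"),
                  y = "Merged peaks") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
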