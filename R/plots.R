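#' Plot a sliding-window methylation profile
#'
#' One line per chromosome of percent methylation along the chromosome,
#' faceted by chromosome.
#'
#' @param profile Tibble from [window_methylation()].
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profile) {
  ggplot2::ggplot(profile |> filter(!.data$missing),
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2,
                               y = .data$percent_methylated)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "% methylated probes") +
    ggplot2::theme_minimal()
}

#' Plot metagene profiles by gene class
#'
#' Mean relative methylation along the metagene axis (upstream flank, gene
#' body rescaled to 1000 units, downstream flank), one curve per gene class.
#'
#' @param profile Tibble from [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$mean_value,
                               color = .data$gene_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 1000), linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "metagene position (flank bp / body per mil)",
                  y = "mean relative methylation", color = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of segment means with the fitted mixture overlaid
#'
#' Mirrors the standard diagnostic for segment classification: the observed
#' distribution of segment means with the mixture density (and its
#' components) on top.
#'
#' @param object A `tm_mixture`.
#' @param values The segment means the model was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tm_mixture <- function(object, values, ...) {
  grid <- seq(min(values), max(values), length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble(x = grid, component = factor(k),
           density = object$proportions[k] *
             dnorm(grid, object$means[k], sqrt(object$variances[k])))
  })
  total <- comp |> group_by(.data$x) |>
    summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_histogram(data = tibble(v = values),
                            ggplot2::aes(x = .data$v,
                                         y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey85", color = "grey70") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       linetype = "dashed", color = "red") +
    ggplot2::labs(x = "segment mean", y = "density", color = "component") +
    ggplot2::theme_minimal()
}
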