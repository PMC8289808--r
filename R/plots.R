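## ggplot2 views of the result types. These export plot-ready layers only;
## publication aesthetics are left to the caller.

SBS_CLASS_COLOURS <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
                       "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC5C4")

#' Rainfall plot
#'
#' Genomic position against log10 distance to the previous mutation, coloured
#' by substitution class; kataegis appears as a low band of points.
#'
#' @param rain Rainfall tibble from [rainfall()] (one sample, or facetted by
#'   sample if several are present).
#' @return A ggplot object.
#' @export
plot_rainfall <- function(rain) {
  dat <- dplyr::filter(rain, !is.na(.data$distance_to_prev))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos,
                                         y = .data$distance_to_prev,
                                         colour = .data$substitution_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = SBS_CLASS_COLOURS, name = NULL) +
    ggplot2::labs(x = "genomic position", y = "distance to previous mutation (bp)")
  facets <- intersect(c("sample_id", "chrom"), names(dat))
  if (length(unique(dat$sample_id)) > 1L || length(unique(dat$chrom)) > 1L) {
    p <- p + ggplot2::facet_grid(sample_id ~ chrom, scales = "free_x")
  }
  p
}

#' 96-channel catalog profile plot
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @return A ggplot object (channels on x, counts on y, facetted by
#'   substitution class and sample).
#' @export
plot_catalog <- function(catalog) {
  parts <- channel_parts()
  dat <- catalog |>
    dplyr::mutate(channel = as.character(.data$channel)) |>
    dplyr::left_join(parts, by = "channel") |>
    dplyr::mutate(context = paste0(.data$five_prime, ".", .data$three_prime))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$context, y = .data$count,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = SBS_CLASS_COLOURS, guide = "none") +
    ggplot2::facet_grid(sample_id ~ class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mutations") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' Plot relative signature contributions of a refit
#'
#' @param object A `sig_refit` object.
#' @param ... Unused.
#' @method autoplot sig_refit
#' @return A ggplot object (stacked contribution bars per sample).
#' @export
autoplot.sig_refit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample_id, y = .data$contribution,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative contribution", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
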