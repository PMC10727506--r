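#' Barcode-rank plot with knee and inflection landmarks
#'
#' @param stats A [barcode_rank_stats()] object.
#' @return A ggplot.
#' @export
plot_barcode_ranks <- function(stats) {
  stopifnot(inherits(stats, "barcode_rank_stats"))
  marks <- tibble::tibble(
    landmark = c("knee", "inflection"),
    log10_rank = log10(c(stats$knee_rank, stats$inflection_rank)),
    log10_total = log10(c(stats$knee_total, stats$inflection_total))
  )
  ggplot2::ggplot(stats$curve, ggplot2::aes(.data$log10_rank, .data$log10_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(color = .data$landmark), size = 3) +
    ggplot2::labs(x = "log10 barcode rank", y = "log10 total UMI",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.barcode_rank_stats <- function(object, ...) plot_barcode_ranks(object)

#' Heatmap of pattern weights by cluster
#'
#' Cells are ordered by cluster, patterns by their hierarchical leaf
#' order; tile fill is the (within-pattern max-scaled) weight.
#'
#' @param model A `pattern_model`.
#' @param clusters Per-cell labels.
#' @param max_cells Cap on displayed cells (evenly subsampled).
#' @return A ggplot.
#' @export
plot_pattern_weights <- function(model, clusters, max_cells = 2000) {
  P <- model$P
  cl <- cluster_vector(clusters, ncol(P))
  if (ncol(P) > max_cells) {
    keep <- sort(sample(ncol(P), max_cells))
    P <- P[, keep, drop = FALSE]; cl <- cl[keep]
  }
  ord_cells <- order(cl)
  ord_pat <- hcluster_patterns(P)
  scl <- apply(P, 1, max); scl[scl == 0] <- 1
  d <- tibble::tibble(
    pattern = factor(rep(rownames(P), ncol(P)),
                     levels = rownames(P)[ord_pat]),
    cell = rep(seq_len(ncol(P))[order(order(ord_cells))], each = nrow(P)),
    weight = as.numeric(P / scl)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$cell, .data$pattern,
                                  fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "cells (grouped by cluster)", y = NULL,
                  fill = "scaled\nweight") +
    ggplot2::theme_minimal()
}

#' Expression dynamics over cell-cycle position
#'
#' Scatter of a response over theta with the periodic loess curve.
#'
#' @param positions A [cc_position()] tibble.
#' @param y Per-cell response (e.g. a gene's normalized expression).
#' @param span Loess span.
#' @return A ggplot.
#' @export
plot_cc_dynamics <- function(positions, y, span = 0.3) {
  fit <- periodic_loess(positions$theta, y, span = span)
  d <- tibble::tibble(theta = positions$theta, y = y)
  ggplot2::ggplot(d, ggplot2::aes(.data$theta, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(.data$theta, .data$fitted),
                       linewidth = 1) +
    ggplot2::scale_x_continuous(
      breaks = c(0, 0.5, 1, 1.5, 2) * pi,
      labels = c("0", "0.5π", "π", "1.5π", "2π")) +
    ggplot2::labs(x = "cell-cycle position θ", y = "expression") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
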