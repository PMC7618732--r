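#' Plot a 2-D atlas embedding
#'
#' @param x An [atlas()] with `embedding_x` / `embedding_y` in
#'   `cell_meta`.
#' @param colour_by Name of a `cell_meta` column to colour by.
#' @return A ggplot.
#' @export
plot_embedding <- function(x, colour_by = "cluster") {
  cm <- x$cell_meta
  stopifnot(all(c("embedding_x", "embedding_y", colour_by) %in% names(cm)))
  ggplot2::ggplot(cm, ggplot2::aes(
    .data$embedding_x, .data$embedding_y,
    colour = .data[[colour_by]]
  )) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "embedding 1", y = "embedding 2", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score distributions per program
#'
#' @param object A [score_programs()] result.
#' @param ... Unused.
#' @return A ggplot of the raw score distribution per program.
#' @export
autoplot.score_table <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$raw, fill = .data$program)) +
    ggplot2::geom_histogram(bins = 50, alpha = 0.7, position = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$program), scales = "free_y") +
    ggplot2::labs(x = "module score", y = "cells") +
    ggplot2::theme_minimal()
}

#' Early-vs-late morphology metrics
#'
#' @param object A [morphology_report()].
#' @param ... Unused.
#' @return A ggplot: per-metric boxplots split by birth class, mirroring
#'   the punctate-vs-serpentine comparison.
#' @export
autoplot.morphology_report <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      c("mean_pairwise_distance", "fragmentation", "modularity_q"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    ggplot2::ggplot(ggplot2::aes(.data$birth_class, .data$value,
      fill = .data$birth_class
    )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Pseudotime expression profiles of selected genes
#'
#' Mean z-scored expression per pseudotime decile, one line per gene —
#' the standard view of a temporal cascade along a trajectory.
#'
#' @param expr Genes-x-cells matrix (log-normalised).
#' @param pseudotime_pct Per-cell pseudotime in `[0, 100]`.
#' @param genes Genes to show.
#' @return A ggplot.
#' @export
plot_pseudotime_profiles <- function(expr, pseudotime_pct, genes) {
  df <- pseudotime_decile_profile(expr, pseudotime_pct, genes)
  ggplot2::ggplot(df, ggplot2::aes(.data$decile, .data$mean_z,
    colour = .data$gene
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "pseudotime decile", y = "mean z-scored expression") +
    ggplot2::theme_minimal()
}

#' Mean z-scored expression per pseudotime decile
#'
#' @inheritParams plot_pseudotime_profiles
#' @return A tibble with `gene`, `decile` (1-10), `mean_z`.
#' @export
pseudotime_decile_profile <- function(expr, pseudotime_pct, genes) {
  expr <- as.matrix(expr)[genes, , drop = FALSE]
  decile <- pmin(10L, 1L + floor(pseudotime_pct / 10))
  z <- t(scale(t(expr)))
  z[is.nan(z)] <- 0
  levs <- sort(unique(decile))
  purrr::map_dfr(genes, function(g) {
    mz <- vapply(levs, function(d) mean(z[g, decile == d]), numeric(1))
    tibble::tibble(gene = g, decile = levs, mean_z = mz)
  })
}
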