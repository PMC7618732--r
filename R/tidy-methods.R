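#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a score table into long form
#'
#' @param x A [score_programs()] result.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `program`, `raw`, `l2norm`.
#' @export
tidy.score_table <- function(x, ...) {
  raw_long <- tibble::as_tibble(x$raw, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "program", values_to = "raw")
  l2_long <- tibble::as_tibble(x$l2norm, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "program", values_to = "l2norm")
  dplyr::left_join(raw_long, l2_long, by = c("cell_id", "program"))
}

#' One-row summary of a score table
#'
#' @param x A [score_programs()] result.
#' @param ... Unused.
#' @return A tibble with cell/program counts and the scoring parameters.
#' @export
glance.score_table <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$raw),
    n_programs = ncol(x$raw),
    n_bins = x$params$n_bins,
    n_ctrl = x$params$n_ctrl,
    direction = x$params$direction
  )
}

#' Tidy a label evaluation
#'
#' @param x An [evaluate_sexing()] result.
#' @param ... Unused.
#' @return The confusion tibble.
#' @export
tidy.label_eval <- function(x, ...) x$confusion

#' One-row summary of a label evaluation
#'
#' @param x An [evaluate_sexing()] result.
#' @param ... Unused.
#' @return A tibble with `positive_label`, `precision`, `recall`.
#' @export
glance.label_eval <- function(x, ...) {
  tibble::tibble(
    positive_label = x$positive_label,
    precision = x$precision,
    recall = x$recall
  )
}

#' One-row summary of a LISI result
#'
#' @param x A [lisi()] result.
#' @param ... Unused.
#' @return A tibble with `mean_lisi`, `n_cells`, `n_labels`, `perplexity`.
#' @export
glance.lisi_result <- function(x, ...) {
  tibble::tibble(
    mean_lisi = attr(x, "mean_lisi"),
    n_cells = nrow(x),
    n_labels = attr(x, "n_labels"),
    perplexity = attr(x, "perplexity")
  )
}
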