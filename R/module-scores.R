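#' Binned-control module score for a gene program
#'
#' Per-cell mean log-normalised expression of a gene set minus the mean of
#' expression-matched control genes. Genes are binned into `n_bins`
#' equal-frequency bins by their mean expression across cells; for each
#' program gene, `n_ctrl` control genes are sampled from its bin (with
#' replacement when the bin holds fewer than `n_ctrl` genes), and the
#' control term is the mean over the pooled control draws.
#'
#' @param x An [atlas()].
#' @param genes Character vector of program gene ids.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes sampled per program gene (default 100).
#' @param seed Integer seed for the control sampling.
#' @param expr Optional pre-computed log-normalised matrix (genes x cells);
#'   computed with [lognorm()] when `NULL`.
#' @return A named numeric vector of per-cell scores.
#' @export
module_score <- function(x, genes, n_bins = 24, n_ctrl = 100, seed = 0L,
                         expr = NULL) {
  if (length(genes) == 0) stop("empty gene program")
  if (is.null(expr)) expr <- lognorm(x)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop("program genes absent from atlas: ", paste(missing, collapse = ", "))
  }
  gene_means <- Matrix::rowMeans(expr)
  bins <- dplyr::ntile(gene_means, min(n_bins, nrow(expr)))
  ctrl <- with_seed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- which(bins == bins[match(g, rownames(expr))])
      if (length(pool) == 1) return(rep(pool, n_ctrl))
      sample(pool, n_ctrl, replace = n_ctrl > length(pool))
    }))
  })
  prog_mean <- Matrix::colMeans(expr[genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl, , drop = FALSE])
  as.numeric(prog_mean - ctrl_mean) |>
    stats::setNames(colnames(expr))
}

#' Score a set of gene programs and l2-normalise
#'
#' Computes the [module_score()] of every program and the l2-normalised
#' score matrix. Normalisation is per program across cells by default
#' (making score magnitudes comparable at the argmax); the per-cell
#' alternative is available via `direction`.
#'
#' @param x An [atlas()].
#' @param programs Named list of gene-id vectors, one per program.
#' @param direction `"program"` (default; each program's score vector is
#'   scaled to unit Euclidean norm across cells) or `"cell"`.
#' @inheritParams module_score
#' @return A `score_table`: list with `raw` and `l2norm` (cells x programs
#'   matrices) and `params`.
#' @export
score_programs <- function(x, programs, n_bins = 24, n_ctrl = 100, seed = 0L,
                           direction = c("program", "cell")) {
  direction <- match.arg(direction)
  stopifnot(length(programs) > 0, !is.null(names(programs)))
  expr <- lognorm(x)
  raw <- vapply(
    programs,
    function(g) module_score(x, g, n_bins, n_ctrl, seed, expr = expr),
    numeric(n_cells(x))
  )
  raw <- matrix(raw,
    nrow = n_cells(x),
    dimnames = list(x$cell_meta$cell_id, names(programs))
  )
  l2 <- switch(direction,
    program = l2_normalize_scores(raw),
    cell = t(l2_normalize_scores(t(raw)))
  )
  structure(
    list(
      raw = raw, l2norm = l2,
      params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                    direction = direction)
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "<score_table> %d cells x %d programs (l2 direction: %s)\n",
    nrow(x$raw), ncol(x$raw), x$params$direction
  ))
  invisible(x)
}

#' l2-normalise a score matrix
#'
#' Divides each column (program) by its Euclidean norm across cells;
#' all-zero columns are returned unchanged.
#'
#' @param raw Numeric matrix, cells x programs.
#' @return A matrix of the same shape with unit-norm columns.
#' @export
l2_normalize_scores <- function(raw) {
  raw <- as.matrix(raw)
  norms <- sqrt(colSums(raw^2))
  norms[norms == 0] <- 1
  sweep(raw, 2, norms, "/")
}

#' Classify cells by positive-and-argmax module scores
#'
#' A cell is labelled with a program iff that program's raw score is
#' positive and its l2-normalised score strictly exceeds every other
#' program's; otherwise the cell is `"unassigned"` (including exact ties).
#'
#' @param score_table A [score_programs()] result.
#' @return A tibble with `cell_id` and `label`.
#' @export
classify_by_scores <- function(score_table) {
  l2 <- score_table$l2norm
  raw <- score_table$raw
  labels <- apply(seq_len(nrow(l2)) |> as.matrix(), 1, function(i) {
    s <- l2[i, ]
    j <- which.max(s)
    if (raw[i, j] > 0 && sum(s == s[j]) == 1) colnames(l2)[j] else "unassigned"
  })
  tibble::tibble(cell_id = rownames(l2), label = labels)
}

#' Extrapolate per-cell labels to whole clusters
#'
#' Each cell receives the modal label among the assigned cells of its
#' cluster; clusters whose cells are all unassigned stay unassigned. Modal
#' ties are broken by lexicographic program name.
#'
#' @param labels A data frame with `cell_id` and `label` (as from
#'   [classify_by_scores()]).
#' @param clusters Character vector of cluster ids, aligned with `labels`
#'   rows (or named by cell_id).
#' @return A tibble with `cell_id`, `cluster` and the extrapolated `label`.
#' @export
extrapolate_by_cluster <- function(labels, clusters) {
  df <- tibble::as_tibble(labels)
  stopifnot(length(clusters) == nrow(df))
  df$cluster <- as.character(clusters)
  modal <- df |>
    dplyr::filter(.data$label != "unassigned") |>
    dplyr::count(.data$cluster, .data$label) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$n), .data$label) |>
    dplyr::distinct(.data$cluster, .keep_all = TRUE) |>
    dplyr::select("cluster", modal_label = "label")
  df |>
    dplyr::left_join(modal, by = "cluster") |>
    dplyr::mutate(label = dplyr::coalesce(.data$modal_label, "unassigned")) |>
    dplyr::select("cell_id", "cluster", "label")
}

#' Annotate birth order from early/late program scores
#'
#' A cell is early-born iff the l2-normalised early score is positive and
#' greater than the l2-normalised late score; late-born under the symmetric
#' condition; cells with both scores non-positive or equal are
#' `"unassigned"` (and are excluded from downstream morphology and
#' pseudotime stages).
#'
#' @param x An [atlas()].
#' @param early_genes,late_genes Gene-id vectors of the early and late
#'   programs.
#' @inheritParams module_score
#' @return A tibble with `cell_id`, l2 scores `early_l2` / `late_l2` and
#'   `birth_class` in `{"early", "late", "unassigned"}`.
#' @export
annotate_birth_order <- function(x, early_genes, late_genes, n_bins = 24,
                                 n_ctrl = 100, seed = 0L) {
  st <- score_programs(
    x, list(early = early_genes, late = late_genes),
    n_bins = n_bins, n_ctrl = n_ctrl, seed = seed
  )
  e <- st$l2norm[, "early"]
  l <- st$l2norm[, "late"]
  tibble::tibble(
    cell_id = rownames(st$l2norm),
    early_l2 = e,
    late_l2 = l,
    birth_class = dplyr::case_when(
      e > 0 & e > l ~ "early",
      l > 0 & l > e ~ "late",
      .default = "unassigned"
    )
  )
}
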