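#' Symmetrised kNN graph over cells
#'
#' Builds the undirected k-nearest-neighbour graph (union symmetrisation)
#' used both as the pseudotime backbone and as the binary weight matrix
#' for Moran's I.
#'
#' @param coords Numeric matrix, one row per cell (embedding or PCA
#'   coordinates).
#' @param k Neighbours per cell.
#' @return A list with `graph` (igraph, edges weighted by Euclidean
#'   length) and `w` (sparse symmetric binary adjacency).
#' @export
knn_graph <- function(coords, k = 15) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) k <- n - 1L
  nn <- FNN::get.knn(coords, k = k)
  i <- rep(seq_len(n), k)
  j <- as.vector(nn$nn.index)
  d <- as.vector(nn$nn.dist)
  w <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  w <- methods::as(((w + Matrix::t(w)) > 0) * 1, "CsparseMatrix")
  dist_m <- Matrix::sparseMatrix(i = i, j = j, x = d, dims = c(n, n))
  dist_m <- pmax_sparse(dist_m, Matrix::t(dist_m))
  g <- igraph::graph_from_adjacency_matrix(dist_m,
    mode = "undirected", weighted = TRUE
  )
  list(graph = g, w = w)
}

pmax_sparse <- function(a, b) {
  # elementwise max of two same-pattern-or-wider sparse matrices
  methods::as(pmax(as.matrix(a), as.matrix(b)), "CsparseMatrix")
}

#' Root-anchored pseudotime
#'
#' Pseudotime is the graph geodesic (Dijkstra over Euclidean edge
#' lengths) from the nearest root cell on a symmetrised kNN graph; root
#' cells sit at 0. If the graph is disconnected, `k` is doubled (with a
#' warning) until it connects.
#'
#' @param coords Numeric matrix of per-cell coordinates (one cluster's
#'   cells, in expression or embedding space).
#' @param roots Logical vector (or integer indices) marking the root
#'   cells, e.g. the cells positive for an early marker.
#' @param k Initial neighbourhood size (default 15).
#' @return Numeric pseudotime per cell.
#' @export
compute_pseudotime <- function(coords, roots, k = 15) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.logical(roots)) roots <- which(roots)
  if (length(roots) == 0) stop("root set is empty")
  repeat {
    g <- knn_graph(coords, k)$graph
    if (igraph::is_connected(g) || k >= n - 1) break
    k <- min(n - 1L, 2L * k)
    warning("kNN graph disconnected; raising k to ", k)
  }
  d <- igraph::distances(g, v = roots, algorithm = "dijkstra")
  apply(d, 2, min)
}

#' Normalise pseudotime to percent
#'
#' `(v - min) / (max - min) * 100`, making trajectories of different
#' clusters comparable; constant input collapses to all-zero with a
#' warning.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Values in `[0, 100]`.
#' @export
normalize_pseudotime <- function(values) {
  fin <- values[is.finite(values)]
  if (length(fin) == 0) stop("no finite pseudotime values")
  rng <- range(fin)
  if (rng[1] == rng[2]) {
    warning("constant pseudotime; returning zeros")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1]) * 100
}

#' Moran's I on a cell graph
#'
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with binary symmetric weights.
#'
#' @param x Numeric vector over graph vertices.
#' @param w Sparse symmetric weight matrix.
#' @return Moran's I; `NA` for constant `x`.
#' @export
morans_i <- function(x, w) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  w_sum <- sum(w)
  if (w_sum <= 0) stop("graph weight sum must be > 0")
  num <- as.numeric(xc %*% (w %*% xc))
  (n / w_sum) * num / denom
}

#' Permutation test of Moran's I for many genes
#'
#' Tests positive spatial autocorrelation of each gene's expression over a
#' cell-cell kNN graph. P-values are one-sided permutation p-values with
#' the add-one correction, `p = (1 + #\{I_perm >= I_obs\}) / (n_perm + 1)`;
#' q-values are Benjamini-Hochberg across the genes tested. A gene passes
#' iff `q < q_cut` and `I > i_cut` (defaults 0.05 and 0.1). Constant genes
#' are excluded with an `NA` flag.
#'
#' @param expr Numeric genes-x-cells matrix (typically log-normalised
#'   expression of one cluster's cells).
#' @param w Sparse symmetric binary weight matrix (as from [knn_graph()]).
#' @param n_permutations Number of permutations (default 999; smaller
#'   values trade p-value resolution for speed).
#' @param seed Integer seed.
#' @param q_cut,i_cut Pass thresholds.
#' @return A tibble with `gene`, `morans_i`, `p_value`, `q_value`,
#'   `passes`.
#' @export
morans_i_test <- function(expr, w, n_permutations = 999, seed = 0L,
                          q_cut = 0.05, i_cut = 0.1) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  stopifnot(nrow(w) == n)
  w_sum <- sum(w)
  if (w_sum <= 0) stop("graph weight sum must be > 0")
  xc <- expr - rowMeans(expr)
  denom <- rowSums(xc^2)
  constant <- denom == 0
  i_of <- function(m) {
    num <- rowSums(as.matrix(m %*% w) * m)
    (n / w_sum) * num / ifelse(denom == 0, 1, denom)
  }
  i_obs <- i_of(xc)
  exceed <- integer(nrow(expr))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      # the same vertex permutation is applied to every gene
      i_perm <- i_of(xc[, perm, drop = FALSE])
      exceed <- exceed + (i_perm >= i_obs - 1e-12)
    }
  })
  p <- (1 + exceed) / (n_permutations + 1)
  p[constant] <- NA_real_
  i_obs[constant] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!constant] <- stats::p.adjust(p[!constant], method = "BH")
  tibble::tibble(
    gene = rownames(expr) %||% paste0("gene", seq_len(nrow(expr))),
    morans_i = unname(i_obs),
    p_value = unname(p),
    q_value = unname(q),
    passes = unname(!constant & q < q_cut & i_obs > i_cut)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select clusters eligible for pseudotime analysis
#'
#' A cluster qualifies iff (1) its modal lineage type is an allowed
#' neuroblast type, (2) it is late-born dominant — the cluster mean
#' l2-normalised late score is positive and above the early score — and
#' (3) its cells positive for the mid-temporal marker form a single
#' DBSCAN sub-region of the embedding (exactly one non-noise subcluster).
#'
#' @param x An [atlas()] with `lineage_type`, `cluster` and embedding
#'   columns in `cell_meta`.
#' @param birth_scores An [annotate_birth_order()] tibble for the same
#'   cells.
#' @param mid_marker Gene id of the mid-temporal marker (br-like).
#' @param allowed_types Lineage types accepted by criterion (1).
#' @param eps,min_pts DBSCAN parameters for criterion (3).
#' @return A tibble with one row per cluster: the three criterion flags
#'   and `selected`.
#' @export
select_lineage_clusters <- function(x, birth_scores, mid_marker,
                                    allowed_types = c("type I", "type II"),
                                    eps = 0.5, min_pts = 5) {
  for (col in c("lineage_type", "cluster", "embedding_x", "embedding_y")) {
    if (!col %in% names(x$cell_meta)) stop("cell_meta lacks column: ", col)
  }
  if (!mid_marker %in% x$gene_meta$gene_id) {
    stop("mid_marker absent from atlas: ", mid_marker)
  }
  cm <- x$cell_meta |>
    dplyr::left_join(
      dplyr::select(birth_scores, "cell_id", "early_l2", "late_l2"),
      by = "cell_id"
    )
  mid_pos <- as.numeric(x$counts[mid_marker, ]) > 0
  cm$mid_pos <- mid_pos
  cm |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(g, key) {
      type_ok <- names(which.max(table(g$lineage_type))) %in% allowed_types
      late_ok <- mean(g$late_l2) > 0 && mean(g$late_l2) > mean(g$early_l2)
      pts <- cbind(g$embedding_x, g$embedding_y)[g$mid_pos, , drop = FALSE]
      n_regions <- if (nrow(pts) > 0) {
        fragmentation_score(pts, eps, min_pts)
      } else {
        0L
      }
      tibble::tibble(
        type_ok = type_ok, late_ok = late_ok,
        n_mid_regions = n_regions,
        single_region_ok = n_regions == 1L
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(selected = .data$type_ok & .data$late_ok & .data$single_region_ok)
}

#' Recurrent temporal transcription factors across lineages
#'
#' Given per-lineage Moran's I tables, keeps the transcription factors
#' that pass (q < 0.05 and I > 0.1) in at least `min_lineage_frac`
#' (inclusive) of the analysed lineages, sorted by occurrence fraction
#' then name.
#'
#' @param stat_tables Named list of [morans_i_test()] tibbles, one per
#'   lineage/cluster.
#' @param tf_genes Character vector of TF gene ids; only these are
#'   eligible.
#' @param min_lineage_frac Inclusive occurrence bound (default 0.5).
#' @return A tibble with `gene`, `n_lineages`, `n_passing`, `occurrence`.
#' @export
recurrent_temporal_tfs <- function(stat_tables, tf_genes,
                                   min_lineage_frac = 0.5) {
  if (length(stat_tables) < 2) stop("need >= 2 analysed lineages")
  n_lin <- length(stat_tables)
  passes <- dplyr::bind_rows(stat_tables, .id = "lineage") |>
    dplyr::filter(.data$gene %in% tf_genes, .data$passes) |>
    dplyr::count(.data$gene, name = "n_passing")
  passes |>
    dplyr::mutate(
      n_lineages = n_lin,
      occurrence = .data$n_passing / n_lin
    ) |>
    dplyr::filter(.data$occurrence >= min_lineage_frac) |>
    dplyr::arrange(dplyr::desc(.data$occurrence), .data$gene) |>
    dplyr::select("gene", "n_lineages", "n_passing", "occurrence")
}
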