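#' Mean pairwise distance of a point set
#'
#' Mean of all `n(n-1)/2` Euclidean distances between 2-D embedding
#' coordinates of the cells in a group.
#'
#' @param points Numeric matrix (or data frame) with one row per point.
#' @return A number; `NA` with a warning for fewer than 2 points.
#' @export
mean_pairwise_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) {
    warning("mean pairwise distance undefined for < 2 points")
    return(NA_real_)
  }
  mean(stats::dist(points))
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN on Euclidean distances: a core point has at least
#' `min_pts` points (itself included) within `eps`; clusters are the
#' connected components of core points under eps-reachability; border
#' points join the first core cluster that reaches them in point-index
#' order; remaining points are noise (label 0).
#'
#' @param points Numeric matrix, one row per point.
#' @param eps Neighbourhood radius (> 0).
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer labels, one per point; 0 marks noise.
#' @export
dbscan_points <- function(points, eps, min_pts) {
  points <- as.matrix(points)
  if (eps <= 0) stop("eps must be > 0")
  if (min_pts < 1) stop("min_pts must be >= 1")
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  within <- d <= eps
  core <- rowSums(within) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    core_idx <- which(core)
    adj <- within[core_idx, core_idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[core_idx] <- as.integer(comp)
    # Border points: assigned to the cluster of the lowest-index core
    # point within eps (deterministic tie-break).
    border <- which(!core)
    for (b in border) {
      reach <- core_idx[within[b, core_idx]]
      if (length(reach) > 0) labels[b] <- labels[min(reach)]
    }
    # Renumber clusters by first appearance for label stability.
    seen <- unique(labels[labels > 0])
    labels[labels > 0] <- match(labels[labels > 0], seen)
    labels <- as.integer(labels)
  }
  labels
}

#' Fragmentation score of a point set
#'
#' The number of distinct non-noise DBSCAN subclusters the points split
#' into at the given density parameters; an entirely-noise group scores 0.
#'
#' @inheritParams dbscan_points
#' @param eps Neighbourhood radius (default 0.5 embedding units).
#' @param min_pts Minimum neighbourhood members (default 5).
#' @return A non-negative integer count.
#' @export
fragmentation_score <- function(points, eps = 0.5, min_pts = 5) {
  labels <- dbscan_points(points, eps, min_pts)
  length(unique(labels[labels > 0]))
}

#' Graph modularity of a point set
#'
#' Builds a weighted similarity graph from the pairwise distances —
#' Gaussian kernel `w_ij = exp(-d_ij^2 / (2 sigma^2))` with `sigma` the
#' median pairwise distance, or inverse distance — detects communities by
#' fast-greedy modularity maximisation, and returns the weighted
#' modularity of that partition. Degenerate all-identical point sets fall
#' back to a complete unit-weight graph (flagged by a warning).
#'
#' @param points Numeric matrix, one row per point (>= 3 points).
#' @param kernel `"gaussian"` (default) or `"inverse"`.
#' @return A list with `membership` (integer community per point) and
#'   `q` (modularity).
#' @export
modularity_score <- function(points, kernel = c("gaussian", "inverse")) {
  kernel <- match.arg(kernel)
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("modularity needs >= 3 points")
  d <- as.matrix(stats::dist(points))
  sigma <- stats::median(d[upper.tri(d)])
  if (sigma == 0) {
    warning("all points identical; using complete unit-weight graph")
    w <- matrix(1, nrow(d), ncol(d))
  } else {
    w <- switch(kernel,
      gaussian = exp(-d^2 / (2 * sigma^2)),
      inverse = 1 / (d + stats::median(d[upper.tri(d)]) * 1e-6)
    )
  }
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w,
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
  graph_modularity(g)
}

#' Fast-greedy community modularity of a weighted graph
#'
#' The community-detection sub-step of [modularity_score()], exposed so a
#' graph can be supplied directly: greedy agglomerative modularity
#' maximisation followed by the weighted modularity of the resulting
#' partition.
#'
#' @param g An [igraph::graph] (undirected; edge weights used if present).
#' @return A list with `membership` and `q`.
#' @export
graph_modularity <- function(g) {
  w <- igraph::E(g)$weight
  comm <- igraph::cluster_fast_greedy(g, weights = w)
  list(
    membership = igraph::membership(comm),
    q = igraph::modularity(g, igraph::membership(comm), weights = w)
  )
}

#' Per-(cluster x birth class) morphology report
#'
#' Computes the three cluster-morphology statistics — mean pairwise
#' distance, DBSCAN fragmentation score and fast-greedy modularity — for
#' every (cluster, birth class) cell group in a 2-D embedding. Metrics are
#' reported only where defined: distance needs >= 2 cells, modularity
#' >= 3, fragmentation >= `min_pts`.
#'
#' @param cells A data frame with columns `cluster`, `birth_class`,
#'   `embedding_x`, `embedding_y` (e.g. an atlas `cell_meta` joined with
#'   [annotate_birth_order()] labels). Cells with `birth_class`
#'   `"unassigned"` are dropped.
#' @param eps,min_pts DBSCAN parameters (defaults 0.5 and 5).
#' @param kernel Modularity graph kernel, see [modularity_score()].
#' @return A `morphology_report` tibble with one row per
#'   (cluster, birth_class): `n_cells`, `mean_pairwise_distance`,
#'   `fragmentation`, `modularity_q`.
#' @export
morphology_report <- function(cells, eps = 0.5, min_pts = 5,
                              kernel = "gaussian") {
  df <- tibble::as_tibble(cells) |>
    dplyr::filter(.data$birth_class != "unassigned")
  res <- df |>
    dplyr::group_by(.data$cluster, .data$birth_class) |>
    dplyr::group_modify(function(g, key) {
      pts <- cbind(g$embedding_x, g$embedding_y)
      n <- nrow(pts)
      tibble::tibble(
        n_cells = n,
        mean_pairwise_distance = if (n >= 2) mean_pairwise_distance(pts) else NA_real_,
        fragmentation = if (n >= min_pts) {
          fragmentation_score(pts, eps, min_pts)
        } else {
          NA_integer_
        },
        modularity_q = if (n >= 3) modularity_score(pts, kernel)$q else NA_real_
      )
    }) |>
    dplyr::ungroup()
  class(res) <- c("morphology_report", class(res))
  attr(res, "params") <- list(eps = eps, min_pts = min_pts, kernel = kernel)
  res
}

#' Paired early-vs-late comparison of morphology metrics
#'
#' Pairs the early-born and late-born rows of a [morphology_report()]
#' within each cluster and runs a two-sided Wilcoxon signed-rank test
#' ([signed_rank_test()]) on the per-cluster differences for each metric,
#' Bonferroni-correcting over the number of metrics tested.
#'
#' @param report A [morphology_report()].
#' @param metrics Metric columns to compare.
#' @return A tibble with one row per metric: `n_pairs`, `statistic`,
#'   `p_value`, `p_bonferroni`, `median_early`, `median_late`.
#' @export
compare_early_late <- function(report,
                               metrics = c(
                                 "mean_pairwise_distance",
                                 "fragmentation", "modularity_q"
                               )) {
  wide <- tibble::as_tibble(report) |>
    dplyr::select("cluster", "birth_class", dplyr::all_of(metrics)) |>
    tidyr::pivot_wider(
      names_from = "birth_class",
      values_from = dplyr::all_of(metrics)
    )
  out <- purrr::map_dfr(metrics, function(m) {
    e <- wide[[paste0(m, "_early")]]
    l <- wide[[paste0(m, "_late")]]
    ok <- !is.na(e) & !is.na(l)
    n_pairs <- sum(ok)
    if (n_pairs < 6) {
      warning("fewer than 6 usable cluster pairs for ", m,
        "; exact signed-rank test only", call. = FALSE)
    }
    tst <- signed_rank_test(e[ok] - l[ok])
    tibble::tibble(
      metric = m,
      n_pairs = n_pairs,
      statistic = tst$statistic,
      p_value = tst$p_value,
      p_bonferroni = min(1, tst$p_value * length(metrics)),
      median_early = stats::median(e[ok]),
      median_late = stats::median(l[ok])
    )
  })
  out
}
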