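#' Local Inverse Simpson Index (LISI)
#'
#' For each cell, Gaussian kernel weights over its `3 * perplexity`
#' nearest neighbours are tuned by bisection so the weight entropy matches
#' `log(perplexity)`; the label distribution under those weights gives the
#' inverse Simpson index `1 / sum_l p_l^2` — the effective number of
#' labels (batches, cell types) in the cell's neighbourhood. Values range
#' from 1 (a single local label) to the number of distinct labels
#' (perfect local mixing).
#'
#' @param embedding Numeric matrix, one row per cell.
#' @param labels Character/factor labels per cell (e.g. batch).
#' @param perplexity Neighbourhood scale (default 30); must satisfy
#'   `3 * perplexity < n`.
#' @param tol Bisection tolerance on the entropy (default 1e-5).
#' @return A `lisi_result`: tibble with `cell`, `lisi`; attributes
#'   `mean_lisi`, `perplexity`, `label_column`.
#' @export
lisi <- function(embedding, labels, perplexity = 30, tol = 1e-5) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (n < 2) stop("need at least 2 cells")
  if (perplexity >= n - 1) stop("perplexity must be < n - 1")
  k <- min(n - 1, ceiling(3 * perplexity))
  nn <- FNN::get.knn(embedding, k = k)
  target_h <- log(perplexity)
  lab_int <- as.integer(factor(labels))
  n_lab <- max(lab_int)
  per_cell <- vapply(seq_len(n), function(i) {
    d2 <- nn$nn.dist[i, ]^2
    lo <- 1e-12
    hi <- 1e12
    beta <- 1
    for (iter in 1:64) {
      wt <- exp(-beta * d2)
      s <- sum(wt)
      if (s == 0) {
        hi <- beta
        beta <- (lo + hi) / 2
        next
      }
      p <- wt / s
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(h - target_h) < tol) break
      if (h > target_h) lo <- beta else hi <- beta
      beta <- (lo + hi) / 2
    }
    wt <- exp(-beta * d2)
    p <- wt / sum(wt)
    mass <- vapply(
      seq_len(n_lab),
      function(l) sum(p[lab_int[nn$nn.index[i, ]] == l]),
      numeric(1)
    )
    1 / sum(mass^2)
  }, numeric(1))
  structure(
    tibble::tibble(cell = seq_len(n), lisi = per_cell),
    mean_lisi = mean(per_cell),
    perplexity = perplexity,
    n_labels = n_lab,
    class = c("lisi_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting ARI from the contingency table: 1 for identical
#' partitions up to label renaming, expected 0 for independent random
#' partitions.
#'
#' @param labels_a,labels_b Label vectors over the same cells.
#' @return A number.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) == 0) stop("empty labels")
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  idx <- sum_comb(as.vector(tab))
  a <- sum_comb(rowSums(tab))
  b <- sum_comb(colSums(tab))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}

#' Atlas-vs-anatomy depth-of-coverage comparison
#'
#' Compares per-cell-type atlas counts with independent anatomical counts
#' (e.g. connectome-derived): the depth of coverage is the ratio of total
#' counts, and the correlation is Pearson on log10 counts (with a Fisher-z
#' 95% confidence interval). Types with zero anatomical count are excluded
#' and flagged.
#'
#' @param counts A data frame with columns `type`, `atlas_count`,
#'   `anatomical_count`.
#' @param log10_scale Correlate on log10 counts (default `TRUE`); set
#'   `FALSE` for the linear scale.
#' @return A `coverage_comparison`: one-row tibble with `depth`,
#'   `correlation`, `conf_low`, `conf_high`, `n_types`, `n_excluded`; the
#'   per-type table is attached as attribute `per_type`.
#' @export
coverage_correlation <- function(counts, log10_scale = TRUE) {
  df <- tibble::as_tibble(counts)
  stopifnot(all(c("type", "atlas_count", "anatomical_count") %in% names(df)))
  excluded <- df$anatomical_count <= 0
  if (any(excluded)) {
    warning(sum(excluded), " type(s) with zero anatomical count excluded")
  }
  use <- df[!excluded, ]
  if (nrow(use) < 3) stop("need at least 3 matched types")
  depth <- sum(use$atlas_count) / sum(use$anatomical_count)
  xa <- if (log10_scale) log10(use$atlas_count + (use$atlas_count == 0)) else use$atlas_count
  xb <- if (log10_scale) log10(use$anatomical_count) else use$anatomical_count
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    warning("correlation undefined (constant counts)")
    ct <- list(estimate = NA_real_, conf.int = c(NA_real_, NA_real_))
  } else {
    ct <- stats::cor.test(xa, xb)
    if (is.null(ct$conf.int)) ct$conf.int <- c(NA_real_, NA_real_)
  }
  out <- tibble::tibble(
    depth = depth,
    correlation = unname(ct$estimate),
    conf_low = ct$conf.int[1],
    conf_high = ct$conf.int[2],
    n_types = nrow(use),
    n_excluded = sum(excluded)
  )
  attr(out, "per_type") <- use
  class(out) <- c("coverage_comparison", class(out))
  out
}
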