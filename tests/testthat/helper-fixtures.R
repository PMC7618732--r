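# Shared fixtures: one small default-structure atlas, generated once per
# test run. All fixtures are built in code; nothing is read from disk.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_atlas(
        simulation_config(n_lineages = 4, cells_per_lineage = 150, seed = 101)
      )
    }
    cache
  }
})

# A tiny hand-built atlas for boundary tests: counts are fully controlled.
toy_atlas <- function(counts, datasets = NULL, clusters = NULL,
                      is_tf = NULL, is_mito = NULL, is_heatshock = NULL) {
  g <- nrow(counts)
  n <- ncol(counts)
  atlas(
    counts,
    cell_meta = tibble::tibble(
      cell_id = sprintf("c%03d", seq_len(n)),
      dataset = datasets %||% rep("ds1", n),
      batch = "batch1",
      cluster = clusters %||% rep("cl1", n)
    ),
    gene_meta = tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(g)),
      is_tf = is_tf %||% rep(FALSE, g),
      is_mito = is_mito %||% rep(FALSE, g),
      is_heatshock = is_heatshock %||% rep(FALSE, g)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force DBSCAN oracle, written independently of the package
# implementation: explicit point-by-point region queries and a BFS frontier
# expansion, following the textbook algorithm.
dbscan_oracle <- function(points, eps, min_pts) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbours, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (p in frontier) {
        for (q in neighbours[[p]]) {
          if (labels[q] == 0L) {
            labels[q] <- cl
            if (is_core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  labels
}

# Oracle Moran's I: literal double sum over all vertex pairs.
morans_i_oracle <- function(x, w) {
  w <- as.matrix(w)
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * xc[i] * xc[j]
    }
  }
  (n / sum(w)) * num / sum(xc^2)
}

# Exact permutation oracles for the two Wilcoxon tests.
rank_sum_perm_oracle <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  n1 <- length(x)
  e_w <- n1 * (length(v) + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(v), n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
}

signed_rank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  e_v <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - e_v) >= abs(v_obs - e_v) - 1e-12)
}

# Label-permutation-invariant partition comparison.
same_partition <- function(a, b) {
  ta <- outer(a, a, "==")
  tb <- outer(b, b, "==")
  identical(ta, tb)
}
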