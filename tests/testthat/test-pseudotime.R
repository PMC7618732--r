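test_that("pseudotime increases along a path from the root", {
  coords <- cbind(seq(0, 10, length.out = 60), 0)
  pt <- compute_pseudotime(coords, roots = c(TRUE, rep(FALSE, 59)), k = 3)
  expect_true(all(diff(pt) > 0))
  expect_equal(pt[1], 0)
  # all-root input sits at zero
  expect_equal(
    compute_pseudotime(coords, roots = rep(TRUE, 60), k = 3),
    rep(0, 60)
  )
  expect_error(compute_pseudotime(coords, roots = logical(60)), "empty")
})

test_that("pseudotime is translation-invariant and scale-equivariant", {
  set.seed(28)
  coords <- cbind(cumsum(runif(50, 0.5, 1)), rnorm(50, 0, 0.1))
  roots <- c(TRUE, rep(FALSE, 49))
  base <- compute_pseudotime(coords, roots, k = 5)
  shifted <- compute_pseudotime(coords + 100, roots, k = 5)
  expect_equal(base, shifted)
  scaled <- compute_pseudotime(coords * 3, roots, k = 5)
  expect_equal(scaled, base * 3)
  expect_equal(normalize_pseudotime(scaled), normalize_pseudotime(base))
})

test_that("percent normalisation maps to [0, 100] with degenerate handling", {
  expect_equal(normalize_pseudotime(c(0, 5, 10)), c(0, 50, 100))
  expect_warning(out <- normalize_pseudotime(7), "constant")
  expect_equal(out, 0)
  set.seed(29)
  v <- rexp(40)
  expect_equal(max(normalize_pseudotime(v)), 100)
  expect_equal(min(normalize_pseudotime(v)), 0)
})

test_that("Moran's I equals the brute-force double sum", {
  # 3-node path, x = (1, 2, 4): closed form -1/28
  w <- Matrix::sparseMatrix(
    i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1, dims = c(3, 3)
  )
  expect_equal(morans_i(c(1, 2, 4), w), -1 / 28)
  set.seed(30)
  for (trial in 1:25) {
    n <- sample(5:50, 1)
    adj <- matrix(rbinom(n * n, 1, 0.2), n)
    adj <- ((adj + t(adj)) > 0) * 1
    diag(adj) <- 0
    if (sum(adj) == 0) next
    x <- rnorm(n)
    expect_equal(
      morans_i(x, methods::as(adj, "CsparseMatrix")),
      morans_i_oracle(x, adj)
    )
  }
})

test_that("the permutation test flags smooth gradients and not noise", {
  n <- 80
  coords <- cbind(seq_len(n), 0)
  w <- knn_graph(coords, k = 2)$w
  grad <- seq_len(n) / n
  set.seed(31)
  noise <- sample(grad)
  res <- morans_i_test(rbind(gradient = grad, shuffled = noise), w,
    n_permutations = 199, seed = 7
  )
  expect_gt(res$morans_i[1], 0.9)
  expect_equal(res$p_value[1], 1 / 200)
  expect_lt(abs(res$morans_i[2]), 0.25)
  expect_gt(res$p_value[2], 0.05)
  # constant rows are excluded with NA
  res2 <- morans_i_test(rbind(flat = rep(1, n), gradient = grad), w,
    n_permutations = 99, seed = 1
  )
  expect_true(is.na(res2$morans_i[1]))
  expect_false(res2$passes[1])
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(32)
  n <- 60
  w <- knn_graph(cbind(runif(n), runif(n)), k = 5)$w
  x <- matrix(rnorm(40 * n), nrow = 40)
  res <- morans_i_test(x, w, n_permutations = 99, seed = 3)
  expect_gt(mean(res$p_value), 0.35)
  expect_lt(mean(res$p_value), 0.65)
  expect_lt(mean(res$p_value < 0.1), 0.3)
})

test_that("lineage-cluster selection applies the three criteria", {
  n <- 120
  mk_meta <- function(cluster, type) {
    tibble::tibble(
      cell_id = sprintf("%s_%03d", cluster, 1:n),
      dataset = "ds1", batch = "b1", cluster = cluster,
      lineage_type = type,
      embedding_x = NA_real_, embedding_y = NA_real_
    )
  }
  # three clusters: selected / early-dominant / split mid-marker region
  cm <- dplyr::bind_rows(
    mk_meta("ok", "type I"),
    mk_meta("earlyish", "type II"),
    mk_meta("split", "type I")
  )
  set.seed(33)
  cm$embedding_x <- rnorm(3 * n, 0, 0.2)
  cm$embedding_y <- rnorm(3 * n, 0, 0.2)
  # the split cluster's mid-positive cells sit in two distant blobs
  split_rows <- which(cm$cluster == "split")
  cm$embedding_x[split_rows] <- rep(c(0, 30), each = n / 2) + rnorm(n, 0, 0.2)
  counts <- matrix(0L, nrow = 2, ncol = 3 * n)
  counts[2, ] <- 1L # gene 2 ("br"-like) positive everywhere
  atl <- atlas(counts, cm, tibble::tibble(gene_id = c("g1", "g2")))
  scores <- tibble::tibble(
    cell_id = cm$cell_id,
    early_l2 = ifelse(cm$cluster == "earlyish", 0.5, 0.1),
    late_l2 = ifelse(cm$cluster == "earlyish", 0.1, 0.5)
  )
  sel <- select_lineage_clusters(atl, scores, mid_marker = "g2")
  expect_identical(sel$selected[sel$cluster == "ok"], TRUE)
  expect_identical(sel$late_ok[sel$cluster == "earlyish"], FALSE)
  expect_identical(sel$n_mid_regions[sel$cluster == "split"], 2L)
  expect_identical(sel$selected[sel$cluster == "split"], FALSE)
  expect_error(
    select_lineage_clusters(atl, scores, mid_marker = "nope"),
    "mid_marker"
  )
})

test_that("recurrence keeps TFs at or above half of the lineages", {
  mk_stats <- function(pass) {
    tibble::tibble(
      gene = "tfX", morans_i = 0.5, p_value = 0.001,
      q_value = 0.001, passes = pass
    )
  }
  tabs <- c(
    lapply(seq_len(38), function(i) mk_stats(TRUE)),
    lapply(seq_len(37), function(i) mk_stats(FALSE))
  )
  res <- recurrent_temporal_tfs(tabs, tf_genes = "tfX")
  expect_identical(res$gene, "tfX") # 38/75 = 50.7%: kept (inclusive)
  tabs2 <- c(
    lapply(seq_len(37), function(i) mk_stats(TRUE)),
    lapply(seq_len(38), function(i) mk_stats(FALSE))
  )
  res2 <- recurrent_temporal_tfs(tabs2, tf_genes = "tfX")
  expect_identical(nrow(res2), 0L) # 37/75 = 49.3%: dropped
})

test_that("cascade genes peak in birth order along pseudotime deciles", {
  sim <- small_sim()
  atl <- sim$atlas
  tr <- sim$truth
  atl$cell_meta <- generate_embedding(
    atl$cell_meta,
    serpentine_lineage_spec(unique(atl$cell_meta$lineage_id))
  )
  cm <- atl$cell_meta
  expr <- lognorm(atl)
  idx <- which(cm$cluster == "L01")
  coords <- cbind(cm$embedding_x[idx], cm$embedding_y[idx])
  roots <- as.numeric(atl$counts[tr$early_genes[1], idx]) > 0
  pct <- normalize_pseudotime(compute_pseudotime(coords, roots))
  cascade <- tr$temporal_cascade$gene
  prof <- pseudotime_decile_profile(as.matrix(expr[, idx]), pct, cascade)
  peaks <- vapply(cascade, function(g) {
    p <- prof[prof$gene == g, ]
    p$decile[which.max(p$mean_z)]
  }, numeric(1))
  # early cascade genes peak before mid, mid before late
  expect_lt(peaks[1], peaks[3])
  expect_lt(peaks[3], peaks[5])
  expect_true(all(diff(peaks) >= 0))
})
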