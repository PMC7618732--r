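test_that("lisi is 1 for a single label and near k for k mixed labels", {
  set.seed(34)
  emb <- matrix(rnorm(400), ncol = 2)
  one <- lisi(emb, rep("x", 200), perplexity = 20)
  expect_equal(one$lisi, rep(1, 200))
  # two labels perfectly interleaved along a dense line
  n <- 400
  line <- cbind(seq_len(n) * 0.01, 0)
  two <- lisi(line, rep(c("a", "b"), n / 2), perplexity = 30)
  expect_lt(abs(attr(two, "mean_lisi") - 2), 0.1)
  # k labels cycling along the line: every local window is balanced
  for (k in 3:5) {
    resk <- lisi(line, rep_len(letters[1:k], n), perplexity = 30)
    expect_lt(abs(attr(resk, "mean_lisi") - k), 0.2)
  }
  expect_error(lisi(emb[1:5, ], rep("x", 5), perplexity = 10), "perplexity")
})

test_that("lisi is invariant to rigid motions and label renaming", {
  set.seed(35)
  emb <- matrix(rnorm(300), ncol = 2)
  lab <- sample(c("a", "b", "c"), 150, TRUE)
  base <- lisi(emb, lab, perplexity = 15)$lisi
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(emb %*% rot, 2, c(3, -7), "+")
  expect_equal(lisi(moved, lab, perplexity = 15)$lisi, base, tolerance = 1e-6)
  renamed <- c(a = "z", b = "y", c = "x")[lab]
  expect_equal(lisi(emb, renamed, perplexity = 15)$lisi, base)
  # upper bound: never exceeds the number of distinct labels
  for (trial in 1:5) {
    k <- sample(2:6, 1)
    l <- sample(letters[1:k], 150, TRUE)
    expect_lte(max(lisi(emb, l, perplexity = 10)$lisi), length(unique(l)) + 1e-9)
  }
})

test_that("adjusted Rand index matches pair counting and label invariance", {
  a <- c("A", "A", "A", "B", "B", "B")
  b <- c("X", "X", "Y", "Y", "Z", "Z")
  # brute-force over all 15 pairs
  agree <- 0
  n <- 6
  pairs <- utils::combn(n, 2)
  s11 <- 0; s00 <- 0; s10 <- 0; s01 <- 0
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    if (!sa && !sb) s00 <- s00 + 1
    if (sa && !sb) s10 <- s10 + 1
    if (!sa && sb) s01 <- s01 + 1
  }
  expected <- (s11 + s10) * (s11 + s01) / choose(n, 2)
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  ari_oracle <- (s11 - expected) / (max_idx - expected)
  expect_equal(adjusted_rand_index(a, b), ari_oracle)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c("Q", "Q", "Q", "R", "R", "R")), 1)
  expect_error(adjusted_rand_index(character(0), character(0)), "empty")
  # symmetry and agreement with an independent implementation
  set.seed(36)
  for (trial in 1:10) {
    x <- sample(letters[1:4], 40, TRUE)
    y <- sample(letters[1:3], 40, TRUE)
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))
  }
})

test_that("coverage comparison computes depth and log-scale correlation", {
  counts <- tibble::tibble(
    type = paste0("t", 1:5),
    anatomical_count = c(4, 20, 100, 400, 2000),
    atlas_count = c(40, 200, 1000, 4000, 20000)
  )
  res <- coverage_correlation(counts)
  expect_equal(res$depth, 10)
  expect_equal(res$correlation, 1)
  # permuted counts: equals the closed-form Pearson on log10 values
  set.seed(37)
  counts2 <- counts
  counts2$atlas_count <- sample(counts$atlas_count)
  res2 <- coverage_correlation(counts2)
  la <- log10(counts2$atlas_count); lb <- log10(counts2$anatomical_count)
  r_direct <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(res2$correlation, r_direct)
  # zero anatomical counts are excluded with a flag
  counts3 <- counts
  counts3$anatomical_count[1] <- 0
  expect_warning(res3 <- coverage_correlation(counts3), "excluded")
  expect_identical(res3$n_types, 4L)
  expect_identical(res3$n_excluded, 1L)
  expect_error(
    coverage_correlation(counts[1:2, ]),
    "at least 3"
  )
})

test_that("batch mixing on the synthetic atlas yields sensible lisi scores", {
  sim <- small_sim()
  cm <- sim$atlas$cell_meta
  emb <- cbind(cm$embedding_x, cm$embedding_y)
  batch <- lisi(emb, cm$batch, perplexity = 30)
  # batches are assigned independently of geometry: near-perfect mixing
  expect_gt(attr(batch, "mean_lisi"), 1.8)
  cluster <- lisi(emb, cm$cluster, perplexity = 30)
  # lineage territories are separated: little local cluster mixing
  expect_lt(attr(cluster, "mean_lisi"), 1.5)
  expect_gt(attr(batch, "mean_lisi"), attr(cluster, "mean_lisi"))
})

test_that("tidy and glance methods return tibbles", {
  sim <- small_sim()
  st <- score_programs(
    sim$atlas,
    list(early = sim$truth$early_genes, late = sim$truth$late_genes)
  )
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), n_cells(sim$atlas) * 2L)
  expect_identical(glance(st)$n_programs, 2L)
  sx <- annotate_sex(sim$atlas, sim$truth$male_genes)
  ev <- evaluate_sexing(sx$sex_pred, sim$atlas$cell_meta$sex)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_identical(nrow(tidy(ev)), 4L)
  expect_true(glance(ev)$precision > 0.5)
})

test_that("plot constructors return ggplot objects", {
  sim <- small_sim()
  expect_s3_class(plot_embedding(sim$atlas), "ggplot")
  st <- score_programs(
    sim$atlas,
    list(early = sim$truth$early_genes, late = sim$truth$late_genes)
  )
  expect_s3_class(ggplot2::autoplot(st), "ggplot")
  rep <- morphology_report(sim$atlas$cell_meta)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
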