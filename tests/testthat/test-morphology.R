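test_that("mean pairwise distance matches the quadratic-loop oracle", {
  expect_equal(mean_pairwise_distance(rbind(c(0, 0), c(3, 0))), 3)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(mean_pairwise_distance(tri), 1)
  set.seed(15)
  pts <- matrix(rnorm(100), ncol = 2)
  acc <- 0
  for (i in 1:49) {
    for (j in (i + 1):50) acc <- acc + sqrt(sum((pts[i, ] - pts[j, ])^2))
  }
  expect_equal(mean_pairwise_distance(pts), acc / choose(50, 2))
  expect_warning(out <- mean_pairwise_distance(rbind(c(1, 1))), "undefined")
  expect_true(is.na(out))
})

test_that("dbscan handles canonical density configurations", {
  set.seed(16)
  blobs <- rbind(
    matrix(rnorm(60, 0, 0.05), ncol = 2),
    matrix(rnorm(60, 10, 0.05), ncol = 2),
    matrix(rnorm(60, 20, 0.05), ncol = 2)
  )
  lab <- dbscan_points(blobs, eps = 0.5, min_pts = 5)
  expect_identical(length(setdiff(unique(lab), 0L)), 3L)
  # 4 co-located points below the density requirement: all noise
  expect_identical(
    dbscan_points(matrix(1, 4, 2), eps = 0.5, min_pts = 5),
    rep(0L, 4)
  )
  # everything mutually within eps: one cluster
  expect_identical(
    unique(dbscan_points(matrix(runif(20, 0, 0.1), ncol = 2), 0.5, 5)),
    1L
  )
})

test_that("dbscan agrees with an independent implementation on random instances", {
  set.seed(17)
  for (trial in 1:100) {
    n <- sample(20:200, 1)
    pts <- cbind(runif(n, 0, 4), runif(n, 0, 4))
    eps <- runif(1, 0.2, 0.8)
    min_pts <- sample(3:8, 1)
    a <- dbscan_points(pts, eps, min_pts)
    b <- dbscan_oracle(pts, eps, min_pts)
    expect_identical(a == 0L, b == 0L)
    # core points must partition identically; border ties are free
    core <- rowSums(as.matrix(stats::dist(pts)) <= eps) >= min_pts
    expect_true(same_partition(a[core], b[core]))
  }
})

test_that("fragmentation counts non-noise subclusters and shrinks with eps", {
  expect_identical(fragmentation_score(matrix(1, 4, 2), 0.5, 5), 0L)
  set.seed(18)
  pts <- cbind(runif(150, 0, 6), runif(150, 0, 6))
  grid <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  frags <- vapply(grid, function(e) fragmentation_score(pts, e, 4), integer(1))
  expect_true(all(diff(frags[frags > 0]) <= 0))
})

test_that("fast-greedy modularity reproduces the two-clique closed form", {
  el <- rbind(t(utils::combn(1:5, 2)), t(utils::combn(6:10, 2)), c(5, 6))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 1
  res <- graph_modularity(g)
  expect_equal(res$q, 19 / 42)
  expect_true(same_partition(
    as.integer(res$membership),
    rep(1:2, each = 5)
  ))
  # the trivial single-community partition has modularity zero by
  # definition of Q
  comp <- igraph::make_full_graph(6)
  expect_equal(igraph::modularity(comp, rep(1, 6)), 0)
  # degenerate all-identical point sets fall back to a unit-weight graph
  expect_warning(deg <- modularity_score(matrix(1, 5, 2)), "identical")
  expect_lte(deg$q, 0)
})

test_that("point-set modularity agrees with a reference community detector", {
  set.seed(19)
  pts <- rbind(
    matrix(rnorm(80, 0, 0.3), ncol = 2),
    matrix(rnorm(80, 8, 0.3), ncol = 2)
  )
  got <- modularity_score(pts)
  d <- as.matrix(stats::dist(pts))
  sigma <- stats::median(d[upper.tri(d)])
  w <- exp(-d^2 / (2 * sigma^2))
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  ref <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  q_ref <- igraph::modularity(g, igraph::membership(ref), weights = igraph::E(g)$weight)
  expect_lt(abs(got$q - q_ref), 0.05)
})

test_that("morphology metrics are invariant under rigid motions", {
  set.seed(20)
  pts <- cbind(runif(80, 0, 3), runif(80, 0, 3))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% rot, 2, c(5, -2), "+")
  expect_equal(mean_pairwise_distance(pts), mean_pairwise_distance(moved))
  expect_identical(
    fragmentation_score(pts, 0.4, 4),
    fragmentation_score(moved, 0.4, 4)
  )
  expect_equal(modularity_score(pts)$q, modularity_score(moved)$q,
    tolerance = 1e-10
  )
})

test_that("signed-rank p-values match exact sign-pattern enumeration", {
  expect_equal(signed_rank_test(rep(0, 6))$p_value, 1)
  expect_equal(signed_rank_test(1:6)$p_value, 1 / 32)
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(signed_rank_test(d)$p_value, signed_rank_enum_oracle(d))
  }
})

test_that("the early/late morphology report and paired comparison assemble", {
  sim <- small_sim()
  rep <- morphology_report(sim$atlas$cell_meta)
  expect_s3_class(rep, "morphology_report")
  expect_identical(nrow(rep), 8L) # 4 lineages x 2 classes
  expect_true(all(rep$fragmentation[rep$birth_class == "early"] == 3))
  # every cluster: punctate early cells fragment more than serpentine late
  wide <- tidyr::pivot_wider(rep[, c("cluster", "birth_class", "fragmentation")],
    names_from = "birth_class", values_from = "fragmentation"
  )
  expect_true(all(wide$early > wide$late))
  cmp <- suppressWarnings(compare_early_late(rep))
  expect_identical(cmp$metric, c(
    "mean_pairwise_distance", "fragmentation", "modularity_q"
  ))
  expect_true(all(cmp$p_bonferroni >= cmp$p_value))
  expect_true(all(cmp$p_bonferroni <= 1))
  # early punctate groups fragment more than late serpentine groups
  frag <- cmp[cmp$metric == "fragmentation", ]
  expect_gt(frag$median_early, frag$median_late)
})
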