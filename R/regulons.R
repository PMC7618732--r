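#' Expression prefilter for network inference
#'
#' Keeps genes expressed in more than 1% of cells and with a summed count
#' greater than `3 * 0.01 * n_cells`.
#'
#' @param x An [atlas()].
#' @return Character vector of gene ids passing the filter.
#' @export
grn_gene_filter <- function(x) {
  n <- n_cells(x)
  frac <- Matrix::rowMeans(x$counts > 0)
  total <- Matrix::rowSums(x$counts)
  x$gene_meta$gene_id[frac > 0.01 & total > 3 * 0.01 * n]
}

#' One stochastic network-inference run (correlation backend)
#'
#' A pluggable stand-in for an external gene-regulatory-network inference
#' tool: per transcription factor, target genes are those whose absolute
#' Spearman correlation with the TF — computed on a bootstrap resample of
#' cells — exceeds a permutation-null threshold estimated on the same
#' resample. The bootstrap makes runs stochastic under different seeds, as
#' the consensus layer requires; constant genes never become targets.
#'
#' @param x An [atlas()].
#' @param tfs TF gene ids; defaults to the `is_tf` flags intersected with
#'   the [grn_gene_filter()] survivors.
#' @param seed Integer seed for the run.
#' @param n_null Number of permuted null genes for the threshold.
#' @param null_quantile Quantile of the absolute null correlations used as
#'   the target threshold.
#' @param min_corr Floor on the absolute correlation a target must reach.
#'   The permutation null controls chance correlation but not indirect
#'   co-expression (genes linked through a shared covariate rather than
#'   the TF); external inference pipelines remove such indirect targets by
#'   motif pruning, and this floor is the correlation backend's crude
#'   equivalent.
#' @return A `regulon_run`: list with `run_id` and `regulons` (named list
#'   TF -> character vector of targets, never containing the TF itself).
#' @export
infer_grn_once <- function(x, tfs = NULL, seed = 0L, n_null = 200,
                           null_quantile = 0.999, min_corr = 0.35) {
  keep <- grn_gene_filter(x)
  if (is.null(tfs)) tfs <- intersect(x$gene_meta$gene_id[x$gene_meta$is_tf], keep)
  if (length(tfs) == 0) stop("no transcription factors available for inference")
  expr <- lognorm(x)[keep, , drop = FALSE]
  # genes with zero count variance carry no signal; their log-normalised
  # values track sequencing depth only and are never reported as targets
  count_constant <- apply(as.matrix(x$counts[keep, , drop = FALSE]), 1, function(v) {
    length(unique(v)) == 1
  })
  with_seed(seed, {
    n <- ncol(expr)
    boot <- sample.int(n, n, replace = TRUE)
    m <- as.matrix(expr[, boot, drop = FALSE])
    constant <- count_constant |
      apply(m, 1, function(v) length(unique(v)) == 1)
    r <- t(apply(m, 1, rank))
    r <- r - rowMeans(r)
    norms <- sqrt(rowSums(r^2))
    norms[norms == 0] <- 1
    r <- r / norms
    tf_rows <- match(tfs, keep)
    rho <- r[tf_rows, , drop = FALSE] %*% t(r)
    # Null: correlations of the TFs with cell-permuted copies of randomly
    # chosen genes.
    null_rows <- sample.int(nrow(r), min(n_null, nrow(r)), replace = n_null > nrow(r))
    null_mat <- r[null_rows, sample.int(n), drop = FALSE]
    null_rho <- r[tf_rows, , drop = FALSE] %*% t(null_mat)
    threshold <- max(
      stats::quantile(abs(null_rho), null_quantile, names = FALSE),
      min_corr
    )
    regs <- lapply(seq_along(tfs), function(i) {
      hits <- keep[abs(rho[i, ]) > threshold & !constant]
      setdiff(hits, tfs[i])
    })
    names(regs) <- tfs
    structure(
      list(run_id = seed, regulons = regs[lengths(regs) > 0]),
      class = "regulon_run"
    )
  })
}

#' Consensus regulons across repeated inference runs
#'
#' A TF is kept iff it appears (with a non-empty regulon) in strictly more
#' than `min_run_frac` of the runs; its high-confidence targets are the
#' genes found in that TF's regulon in strictly more than `min_run_frac`
#' of all runs; the consensus regulon is kept iff it retains at least
#' `min_targets` such targets.
#'
#' @param runs List of `regulon_run` objects (or plain named lists
#'   TF -> targets), length >= 2.
#' @param min_run_frac Strict frequency bound (default 0.5, i.e. ">50%").
#' @param min_targets Inclusive minimum target count (default 5).
#' @return A tibble with one row per consensus regulon: `tf`,
#'   `run_frequency`, `n_targets` and a `targets` list-column of tibbles
#'   (`gene`, `frequency`).
#' @export
consensus_regulons <- function(runs, min_run_frac = 0.5, min_targets = 5) {
  if (length(runs) < 2) stop("need at least 2 runs")
  regs <- lapply(runs, function(r) if (inherits(r, "regulon_run")) r$regulons else r)
  n_runs <- length(regs)
  tfs <- unique(unlist(lapply(regs, names)))
  rows <- lapply(tfs, function(tf) {
    present <- vapply(regs, function(r) tf %in% names(r), logical(1))
    tf_freq <- sum(present) / n_runs
    if (tf_freq <= min_run_frac) return(NULL)
    target_counts <- table(unlist(lapply(regs[present], function(r) unique(r[[tf]]))))
    target_freq <- as.numeric(target_counts) / n_runs
    keep <- target_freq > min_run_frac
    if (sum(keep) < min_targets) return(NULL)
    tibble::tibble(
      tf = tf,
      run_frequency = tf_freq,
      n_targets = sum(keep),
      targets = list(tibble::tibble(
        gene = names(target_counts)[keep],
        frequency = target_freq[keep]
      ) |> dplyr::arrange(dplyr::desc(.data$frequency), .data$gene))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      tf = character(), run_frequency = numeric(),
      n_targets = integer(), targets = list()
    )
  }
  dplyr::arrange(out, dplyr::desc(.data$run_frequency), .data$tf)
}

#' AUCell: rank-based per-cell gene-set activity
#'
#' For each cell, genes are ranked by decreasing expression (ties broken
#' by a seeded shuffle); the recovery curve accumulates the fraction of
#' the gene set found up to rank `r` for `r <= T = ceiling(top_fraction *
#' n_genes)`; the score is the area under that curve divided by the
#' maximal possible area for a set of that size, so a set occupying the
#' top ranks scores exactly 1 and a set entirely below the rank threshold
#' scores 0. Being rank-based, the score is invariant to monotone
#' transforms of a cell's expression vector.
#'
#' @param x An [atlas()] or a numeric genes-x-cells matrix.
#' @param gene_set Character vector of gene ids; genes absent from the
#'   matrix are ignored (error if none remain).
#' @param top_fraction Rank threshold as a fraction of genes (default
#'   0.05).
#' @param seed Integer seed for tie-breaking.
#' @return A named numeric vector of per-cell scores in `[0, 1]`.
#' @export
aucell <- function(x, gene_set, top_fraction = 0.05, seed = 0L) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)")
  }
  expr <- if (inherits(x, "atlas")) x$counts else x
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) stop("gene_set entirely absent from the matrix")
  n_gene <- nrow(expr)
  t_rank <- ceiling(top_fraction * n_gene)
  g <- length(present)
  max_area <- sum(t_rank - seq_len(min(g, t_rank)) + 1)
  set_rows <- match(present, rownames(expr))
  m <- as.matrix(expr)
  with_seed(seed, {
    scores <- vapply(seq_len(ncol(m)), function(j) {
      rk <- rank(-m[, j], ties.method = "random")[set_rows]
      in_top <- rk <= t_rank
      sum(t_rank - rk[in_top] + 1) / max_area
    }, numeric(1))
    stats::setNames(scores, colnames(m))
  })
}

#' Binarise AUCell scores
#'
#' Activity call per cell: `score > cutoff` (strict). With
#' `cutoff = "auto"`, a two-component Gaussian mixture is fitted to the
#' scores and the cutoff is the minimum-density point between the two
#' component means; if the fit is unavailable (e.g. near-constant scores)
#' the fallback `mean + 2 sd` is used. The cutoff and method are attached
#' as attributes.
#'
#' @param scores Numeric vector of scores in `[0, 1]`.
#' @param cutoff A number, or `"auto"`.
#' @return A logical vector with attributes `cutoff` and `method`.
#' @export
binarize_auc <- function(scores, cutoff = "auto") {
  if (identical(cutoff, "auto")) {
    method <- "gmm_valley"
    cut_val <- NA_real_
    if (length(unique(scores)) >= 3 && stats::sd(scores) > 0) {
      fit <- fit_gmm2(scores)
      if (!is.null(fit) && abs(diff(fit$mu)) > 1e-8) {
        grid <- seq(min(fit$mu), max(fit$mu), length.out = 512)
        dens <- fit$pro[1] * stats::dnorm(grid, fit$mu[1], fit$sigma[1]) +
          fit$pro[2] * stats::dnorm(grid, fit$mu[2], fit$sigma[2])
        cut_val <- grid[which.min(dens)]
      }
    }
    if (is.na(cut_val)) {
      method <- "mean_plus_2sd"
      cut_val <- mean(scores) + 2 * stats::sd(scores)
      if (is.na(cut_val)) cut_val <- mean(scores)
      warning("mixture cutoff unavailable; falling back to mean + 2 sd")
    }
  } else {
    method <- "fixed"
    cut_val <- cutoff
  }
  structure(scores > cut_val, cutoff = cut_val, method = method)
}

# EM fit of a two-component 1-D Gaussian mixture, initialised at the
# lower/upper score quartiles. Returns NULL on degenerate fits.
fit_gmm2 <- function(x, max_iter = 200, tol = 1e-8) {
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sigma <- rep(max(stats::sd(x) / 2, 1e-6), 2)
  pro <- c(0.5, 0.5)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- pro[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- pro[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(!is.finite(tot)) || any(tot <= 0)) return(NULL)
    r <- d1 / tot
    pro <- c(mean(r), 1 - mean(r))
    if (any(pro < 1e-6)) return(NULL)
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sigma <- sqrt(c(
      sum(r * (x - mu[1])^2) / sum(r),
      sum((1 - r) * (x - mu[2])^2) / sum(1 - r)
    ))
    sigma <- pmax(sigma, 1e-6)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], pro = pro[ord])
}

#' Cluster-enriched regulons
#'
#' Marker testing of an AUCell activity matrix: delegates to
#' [find_markers()] on the activity values without a log transform, so
#' regulons enriched in a cluster surface exactly as genes do.
#'
#' @param auc_matrix Numeric regulons-x-cells matrix.
#' @param clusters Cluster ids per cell.
#' @param ... Passed to [find_markers()].
#' @return A [find_markers()] tibble (rows are regulons).
#' @export
regulon_markers <- function(auc_matrix, clusters, ...) {
  find_markers(auc_matrix, clusters = clusters, log_input = FALSE, ...)
}
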