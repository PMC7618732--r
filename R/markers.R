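#' One-vs-rest marker testing
#'
#' For every cluster and gene, a two-sided Wilcoxon rank-sum test of the
#' cluster's cells against all other cells, on log-normalised expression.
#' Large samples use the normal approximation with tie correction and
#' continuity correction; tiny toy inputs (combined n <= `exact_max`) take
#' the exact-enumeration path of [rank_sum_test()]. The average log fold
#' change is the natural log of the ratio of mean de-logged normalised
#' expression, with pseudocount 1:
#' `avg_logfc = ln((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#' P-values are Bonferroni-adjusted over the genes tested per cluster.
#'
#' @param x An [atlas()], or a numeric features-x-cells matrix (e.g. an
#'   AUCell activity matrix) used as-is.
#' @param clusters Cluster ids per cell; defaults to
#'   `cell_meta$cluster` for an atlas.
#' @param log_input Is the expression log1p-scale? (`TRUE` for atlases;
#'   set `FALSE` for activity matrices, where the fold change is computed
#'   on the raw values with pseudocount 1.)
#' @param min_cells Clusters with fewer cells are skipped with a warning.
#' @param exact_max Passed to [rank_sum_test()].
#' @return A tibble with `gene`, `cluster`, `avg_logfc`, `p_value`,
#'   `p_adj`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(x, clusters = NULL, log_input = TRUE, min_cells = 3,
                         exact_max = 12) {
  if (inherits(x, "atlas")) {
    if (is.null(clusters)) clusters <- x$cell_meta$cluster
    expr <- as.matrix(lognorm(x))
  } else {
    expr <- as.matrix(x)
  }
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(expr))
  if (length(unique(clusters)) < 2) stop("need at least 2 clusters")
  n <- ncol(expr)
  de_log <- if (log_input) expm1(expr) else expr
  detected <- expr > 0

  small <- n <= exact_max
  if (!small) {
    ranks <- t(apply(expr, 1, rank))
    tie_terms <- apply(ranks, 1, function(r) {
      tb <- table(r)
      sum(tb^3 - tb)
    })
  }

  out <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    n1 <- sum(in_cl)
    n2 <- n - n1
    if (n1 < min_cells) {
      warning("cluster ", cl, " has fewer than ", min_cells, " cells; skipped")
      next
    }
    if (small) {
      p <- apply(expr, 1, function(v) {
        rank_sum_test(v[in_cl], v[!in_cl], exact_max = exact_max)$p_value
      })
    } else {
      w <- rowSums(ranks[, in_cl, drop = FALSE])
      e_w <- n1 * (n + 1) / 2
      v_w <- n1 * n2 / 12 * ((n + 1) - tie_terms / (n * (n - 1)))
      z <- ifelse(v_w > 0, (w - e_w - sign(w - e_w) * 0.5) / sqrt(v_w), 0)
      p <- pmin(1, 2 * stats::pnorm(-abs(z)))
      p[v_w <= 0] <- 1
    }
    mean_in <- rowMeans(de_log[, in_cl, drop = FALSE])
    mean_out <- rowMeans(de_log[, !in_cl, drop = FALSE])
    out[[cl]] <- tibble::tibble(
      gene = rownames(expr),
      cluster = cl,
      avg_logfc = unname(log((mean_in + 1) / (mean_out + 1))),
      p_value = unname(p),
      p_adj = pmin(1, unname(p) * nrow(expr)),
      pct_in = unname(rowMeans(detected[, in_cl, drop = FALSE])),
      pct_out = unname(rowMeans(detected[, !in_cl, drop = FALSE]))
    )
  }
  dplyr::bind_rows(out)
}

#' Select marker transcription factors by between-cluster CV
#'
#' From the significant markers (`avg_logfc > sig_logfc` and
#' `p_adj < sig_padj`), keeps the transcription factors whose
#' between-cluster coefficient of variation of mean normalised expression
#' strictly exceeds `cv_threshold`. The between-CV is the sample standard
#' deviation of the per-cluster means divided by their mean; the within-CV
#' is the mean, over clusters with at least 3 cells, of the within-cluster
#' sd/mean.
#'
#' @param x An [atlas()] with `is_tf` flags in `gene_meta`.
#' @param markers A [find_markers()] table.
#' @param clusters Cluster ids per cell; default `cell_meta$cluster`.
#' @param cv_threshold Strict lower bound on the between-CV (default 2).
#' @param sig_logfc,sig_padj Significance filter applied to `markers`.
#' @return A tibble of selected TFs with `gene`, `between_cv`,
#'   `within_cv`, `n_sig_clusters`. TFs with undefined CV (zero mean) are
#'   excluded and listed in the `"excluded"` attribute.
#' @export
select_variable_tfs <- function(x, markers, clusters = NULL, cv_threshold = 2,
                                sig_logfc = 0.5, sig_padj = 0.05) {
  if (is.null(clusters)) clusters <- x$cell_meta$cluster
  tf_genes <- x$gene_meta$gene_id[x$gene_meta$is_tf]
  if (length(tf_genes) == 0) stop("no genes flagged is_tf in gene_meta")
  sig <- markers |>
    dplyr::filter(
      .data$gene %in% tf_genes,
      .data$avg_logfc > sig_logfc,
      .data$p_adj < sig_padj
    ) |>
    dplyr::count(.data$gene, name = "n_sig_clusters")
  expr <- lognorm(x)[tf_genes, , drop = FALSE]
  cl <- as.character(clusters)
  cl_sizes <- table(cl)
  cl_ids <- names(cl_sizes)
  cl_means <- vapply(
    cl_ids,
    function(id) Matrix::rowMeans(expr[, cl == id, drop = FALSE]),
    numeric(length(tf_genes))
  )
  cl_sds <- vapply(
    cl_ids,
    function(id) apply(expr[, cl == id, drop = FALSE], 1, stats::sd),
    numeric(length(tf_genes))
  )
  grand <- rowMeans(cl_means)
  between_cv <- ifelse(grand > 0, apply(cl_means, 1, stats::sd) / grand, NA_real_)
  big <- cl_sizes >= 3
  within_cv <- vapply(seq_along(tf_genes), function(g) {
    m <- cl_means[g, big]
    s <- cl_sds[g, big]
    ok <- m > 0
    if (!any(ok)) return(NA_real_)
    mean(s[ok] / m[ok])
  }, numeric(1))
  cv_tbl <- tibble::tibble(
    gene = tf_genes,
    between_cv = unname(between_cv),
    within_cv = unname(within_cv)
  )
  joined <- dplyr::inner_join(sig, cv_tbl, by = "gene")
  excluded <- joined$gene[is.na(joined$between_cv)]
  res <- joined |>
    dplyr::filter(!is.na(.data$between_cv), .data$between_cv > cv_threshold) |>
    dplyr::arrange(dplyr::desc(.data$between_cv)) |>
    dplyr::select("gene", "between_cv", "within_cv", "n_sig_clusters")
  attr(res, "excluded") <- excluded
  res
}

#' Expressed-gene universe filter
#'
#' A gene counts as expressed iff (1) its summed UMI across all cells is
#' at least `min_sum`, (2) its maximum UMI in a single cell is at least
#' `min_max`, (3) no single dataset contributes more than
#' `max_dataset_frac` of its UMI, and (4) the designated special dataset
#' contributes no more than `max_special_frac`. All bounds are inclusive.
#'
#' @param x An [atlas()] with a `dataset` column in `cell_meta`.
#' @param special_dataset Dataset label for criterion (4).
#' @param min_sum,min_max,max_dataset_frac,max_special_frac Thresholds
#'   (defaults 400, 4, 0.60, 0.30).
#' @return A list with `genes` (kept gene ids) and `report` (per-gene
#'   statistics, `kept`, and the comma-joined `failed` criteria).
#' @export
expressed_gene_universe <- function(x, special_dataset,
                                    min_sum = 400, min_max = 4,
                                    max_dataset_frac = 0.60,
                                    max_special_frac = 0.30) {
  datasets <- x$cell_meta$dataset
  if (!special_dataset %in% datasets) {
    stop("unknown special_dataset: ", special_dataset)
  }
  total <- Matrix::rowSums(x$counts)
  max_umi <- apply(x$counts, 1, max)
  ds_sums <- vapply(
    unique(datasets),
    function(d) Matrix::rowSums(x$counts[, datasets == d, drop = FALSE]),
    numeric(n_genes(x))
  )
  safe_total <- ifelse(total == 0, 1, total)
  shares <- ds_sums / safe_total
  max_share <- apply(shares, 1, max)
  special_share <- shares[, special_dataset]
  report <- tibble::tibble(
    gene = x$gene_meta$gene_id,
    total_umi = total,
    max_umi = as.numeric(max_umi),
    max_dataset_share = max_share,
    special_share = special_share
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(failed = paste(c(
      if (.data$total_umi < min_sum) "sum",
      if (.data$max_umi < min_max) "max",
      if (.data$max_dataset_share > max_dataset_frac) "dataset_share",
      if (.data$special_share > max_special_frac) "special_share"
    ), collapse = ",")) |>
    dplyr::ungroup() |>
    dplyr::mutate(kept = .data$failed == "")
  list(genes = report$gene[report$kept], report = report)
}
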