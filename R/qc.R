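#' Droplet QC thresholds
#'
#' The droplet filters applied before any annotation: a kept droplet has
#' UMI strictly above `min_umi`, detected genes strictly above `min_genes`,
#' mitochondrial UMI fraction strictly below `max_mito_frac` and heat-shock
#' UMI fraction strictly below `max_heatshock_frac`. Defaults are 500 UMI,
#' 300 genes, 15% mito and 15% heat-shock.
#'
#' @param min_umi,min_genes Exclusive lower bounds (counts).
#' @param max_mito_frac,max_heatshock_frac Exclusive upper bounds
#'   (fractions in (0, 1]).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = 500, min_genes = 300,
                          max_mito_frac = 0.15, max_heatshock_frac = 0.15) {
  if (min_umi <= 0 || min_genes <= 0) stop("count bounds must be positive")
  for (f in c(max_mito_frac, max_heatshock_frac)) {
    if (f <= 0 || f > 1) stop("fraction bounds must be in (0, 1]")
  }
  structure(
    list(
      min_umi = min_umi, min_genes = min_genes,
      max_mito_frac = max_mito_frac, max_heatshock_frac = max_heatshock_frac
    ),
    class = "qc_thresholds"
  )
}

#' Filter droplets on UMI, gene, mitochondrial and heat-shock criteria
#'
#' Applies the strict-inequality droplet filters of [qc_thresholds()].
#' The report lists every cell with its statistics and, for removed cells,
#' the first failed criterion in the fixed order umi, genes, mito,
#' heatshock.
#'
#' @param x An [atlas()]. Mitochondrial and heat-shock genes are taken from
#'   the `is_mito` / `is_heatshock` flags in `gene_meta`.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `atlas` (kept cells) and `report` (a tibble with
#'   `cell_id`, the four statistics, `keep` and `failed_criterion`).
#' @export
filter_droplets <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (n_cells(x) == 0) {
    warning("empty atlas: nothing to filter")
    return(list(atlas = x, report = tibble::tibble(
      cell_id = character(), n_umi = numeric(), n_genes_detected = numeric(),
      mito_frac = numeric(), heatshock_frac = numeric(),
      keep = logical(), failed_criterion = character()
    )))
  }
  stats <- cell_qc_stats(x)
  report <- stats |>
    dplyr::mutate(
      failed_criterion = dplyr::case_when(
        .data$n_umi <= thresholds$min_umi ~ "umi",
        .data$n_genes_detected <= thresholds$min_genes ~ "genes",
        .data$mito_frac >= thresholds$max_mito_frac ~ "mito",
        .data$heatshock_frac >= thresholds$max_heatshock_frac ~ "heatshock",
        .default = NA_character_
      ),
      keep = is.na(.data$failed_criterion)
    )
  list(atlas = subset_atlas(x, cells = report$keep), report = report)
}

#' Score doublets with a simulated-doublet kNN detector
#'
#' Simulated doublets are sums of random cell pairs; real cells and
#' simulated doublets are embedded together by log-normalisation and PCA,
#' and each real cell is scored by the fraction of its `k` nearest
#' neighbours that are simulated, rescaled by the simulation rate. Calls
#' are made above an expected-doublet-rate quantile of the scores.
#'
#' @param x An [atlas()].
#' @param n_sim_doublets Number of simulated doublets (> 0).
#' @param n_pcs Number of principal components.
#' @param k Neighbourhood size (must be < number of cells).
#' @param expected_rate Expected doublet rate used for the call threshold
#'   (default 0.08, a typical droplet loading rate).
#' @param seed Integer seed.
#' @param detector_name Name recorded in the call set.
#' @return A `doublet_call_set` tibble: `cell_id`, `score`, `call`, with
#'   the detector name as an attribute.
#' @export
score_doublets_knn <- function(x, n_sim_doublets = n_cells(x), n_pcs = 10,
                               k = 30, expected_rate = 0.08, seed = 0L,
                               detector_name = "knn_sim") {
  n <- n_cells(x)
  if (n_sim_doublets <= 0) stop("n_sim_doublets must be > 0")
  if (k >= n) stop("k must be smaller than the number of cells")
  if (n < max(k + 1, 50)) stop("need at least max(k + 1, 50) cells")
  with_seed(seed, {
    p1 <- sample.int(n, n_sim_doublets, replace = TRUE)
    p2 <- sample.int(n, n_sim_doublets, replace = TRUE)
    same <- p1 == p2
    p2[same] <- (p2[same] %% n) + 1L
    sim <- x$counts[, p1, drop = FALSE] + x$counts[, p2, drop = FALSE]
    combined <- cbind(x$counts, sim)
    totals <- Matrix::colSums(combined)
    totals[totals == 0] <- 1
    ln <- combined %*% Matrix::Diagonal(x = 1e4 / totals)
    ln@x <- log1p(ln@x)
    # PCA on the genes with the highest log-normalised variance.
    v <- apply(ln, 1, stats::var)
    top <- order(v, decreasing = TRUE)[seq_len(min(500, nrow(ln)))]
    pcs <- stats::prcomp(t(as.matrix(ln[top, , drop = FALSE])),
      rank. = n_pcs, center = TRUE, scale. = FALSE
    )$x
    nn <- FNN::get.knn(pcs, k = k)$nn.index[seq_len(n), , drop = FALSE]
    frac_sim <- rowMeans(nn > n)
    sim_rate <- n_sim_doublets / (n + n_sim_doublets)
    score <- frac_sim / sim_rate
    threshold <- stats::quantile(score, 1 - expected_rate, names = FALSE)
    structure(
      tibble::tibble(
        cell_id = x$cell_meta$cell_id,
        score = score,
        call = score > threshold
      ),
      detector_name = detector_name,
      class = c("doublet_call_set", "tbl_df", "tbl", "data.frame")
    )
  })
}

#' Consensus doublet calling across detectors
#'
#' A cell is flagged as a doublet iff at least `min_votes` of the supplied
#' call sets call it (the 2-of-3 rule with the defaults).
#'
#' @param call_sets List of >= 3 call sets (tibbles with `cell_id` and
#'   logical `call`), all covering the same cells.
#' @param min_votes Minimum positive calls (default 2).
#' @return A tibble with `cell_id`, `n_votes` and logical `is_doublet`.
#' @export
consensus_doublets <- function(call_sets, min_votes = 2) {
  if (length(call_sets) < 3) stop("need at least 3 call sets")
  ids <- call_sets[[1]]$cell_id
  for (cs in call_sets[-1]) {
    if (!identical(sort(cs$cell_id), sort(ids))) {
      stop("call sets cover different cell ids")
    }
  }
  votes <- vapply(
    call_sets,
    function(cs) cs$call[match(ids, cs$cell_id)],
    logical(length(ids))
  )
  tibble::tibble(
    cell_id = ids,
    n_votes = rowSums(votes),
    is_doublet = rowSums(votes) >= min_votes
  )
}

#' In-silico sexing from a male gene program
#'
#' Computes the [module_score()] of the male-specific program (two roX-like
#' genes in the synthetic atlas) and labels cells with a score below or
#' equal to zero as female and above zero as male. A score of exactly zero
#' is assigned to female, the conservative majority choice.
#'
#' @param x An [atlas()].
#' @param male_genes Gene ids of the male program.
#' @inheritParams module_score
#' @return A tibble with `cell_id`, `male_score` and `sex_pred`.
#' @export
annotate_sex <- function(x, male_genes, n_bins = 24, n_ctrl = 100, seed = 0L) {
  score <- module_score(x, male_genes, n_bins, n_ctrl, seed)
  tibble::tibble(
    cell_id = x$cell_meta$cell_id,
    male_score = score,
    sex_pred = ifelse(score > 0, "male", "female")
  )
}

#' Precision/recall evaluation of a labelling
#'
#' @param predicted,truth Character vectors of labels, aligned.
#' @param positive_label The label treated as positive (e.g. `"female"`).
#' @return A `label_eval` list with `precision`, `recall` (NA when the
#'   denominator is zero, flagged in `undefined`) and a `confusion` tibble.
#' @export
evaluate_sexing <- function(predicted, truth, positive_label = "female") {
  stopifnot(length(predicted) == length(truth))
  if (!any(truth == positive_label)) {
    warning("no cells carry the positive truth label; recall undefined")
  }
  tp <- sum(predicted == positive_label & truth == positive_label)
  fp <- sum(predicted == positive_label & truth != positive_label)
  fn <- sum(predicted != positive_label & truth == positive_label)
  tn <- sum(predicted != positive_label & truth != positive_label)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(
    list(
      precision = precision, recall = recall,
      undefined = c(precision = tp + fp == 0, recall = tp + fn == 0),
      positive_label = positive_label,
      confusion = tibble::tibble(
        predicted = c(positive_label, positive_label, "other", "other"),
        truth = c(positive_label, "other", positive_label, "other"),
        n = c(tp, fp, fn, tn)
      )
    ),
    class = "label_eval"
  )
}

#' @export
print.label_eval <- function(x, ...) {
  cat(sprintf(
    "<label_eval> positive = %s: precision %.4f, recall %.4f\n",
    x$positive_label, x$precision, x$recall
  ))
  invisible(x)
}
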