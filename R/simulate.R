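#' Configuration for the synthetic atlas generator
#'
#' Bundles and validates the parameters of the ground-truth simulator. The
#' defaults describe the structure the downstream heuristics assume: a set
#' of neuroblast-like lineages, each with an early-born and a late-born
#' contingent; mutually exclusive two-gene early ("Imp/mamo-like") and late
#' ("dati/pros-like") marker programs; a two-gene male program (roX-like);
#' a shared temporal transcription-factor cascade along a birth-time axis;
#' lineage-specific TF codes; TF regulons whose targets co-vary with their
#' TF; negative-binomial counts with per-batch shifts on the log-mean; and
#' early-born cells with both a higher expected total UMI and a larger
#' active gene set.
#'
#' @param n_lineages Number of lineages (each becomes one cluster).
#' @param cells_per_lineage Cells per lineage.
#' @param n_genes Total genes (must be large enough to host all programs).
#' @param n_tfs Number of genes flagged as transcription factors.
#' @param early_fraction Expected fraction of cells that are early-born;
#'   birth time is uniform on `[0, 1]` and cells with birth time below this
#'   value are early-born.
#' @param early_umi_multiplier Ratio of expected total UMI in early-born
#'   vs late-born cells (>= 1).
#' @param doublet_rate Fraction of doublet columns appended (pair sums).
#' @param n_batches Number of batches.
#' @param batch_shift_sd SD of the per-gene, per-batch additive shift on
#'   the log-mean.
#' @param male_fraction Fraction of male cells.
#' @param regulon_size Targets per ground-truth regulon.
#' @param n_regulons Number of ground-truth regulons.
#' @param n_cascade Number of temporal-cascade TFs.
#' @param noise_dispersion Negative-binomial dispersion phi
#'   (`var = mu + phi * mu^2`).
#' @param seed Integer RNG seed; a fixed seed makes the generated atlas
#'   byte-identical across calls.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_lineages = 8,
                              cells_per_lineage = 250,
                              n_genes = 800,
                              n_tfs = 60,
                              early_fraction = 0.3,
                              early_umi_multiplier = 1.5,
                              doublet_rate = 0,
                              n_batches = 2,
                              batch_shift_sd = 0.1,
                              male_fraction = 0.5,
                              regulon_size = 10,
                              n_regulons = 5,
                              n_cascade = 5,
                              noise_dispersion = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_lineages = n_lineages, cells_per_lineage = cells_per_lineage,
    n_genes = n_genes, n_tfs = n_tfs, early_fraction = early_fraction,
    early_umi_multiplier = early_umi_multiplier, doublet_rate = doublet_rate,
    n_batches = n_batches, batch_shift_sd = batch_shift_sd,
    male_fraction = male_fraction, regulon_size = regulon_size,
    n_regulons = n_regulons, n_cascade = n_cascade,
    noise_dispersion = noise_dispersion, seed = as.integer(seed)
  )
  counts <- c("n_lineages", "cells_per_lineage", "n_genes", "n_tfs",
              "n_batches", "regulon_size", "n_regulons", "n_cascade")
  for (f in counts) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop(f, " must be a count >= 1")
    }
  }
  for (f in c("early_fraction", "male_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 0.5) {
    stop("doublet_rate must be in [0, 0.5)")
  }
  if (cfg$early_umi_multiplier < 1) stop("early_umi_multiplier must be >= 1")
  if (cfg$batch_shift_sd < 0) stop("batch_shift_sd must be >= 0")
  if (cfg$noise_dispersion <= 0) stop("noise_dispersion must be > 0")
  structure(cfg, class = "simulation_config")
}

# Disjoint gene index blocks hosting each program; documented layout so
# every program is addressable in tests.
gene_layout <- function(config) {
  take <- local({
    nxt <- 1L
    function(n) {
      idx <- seq.int(nxt, length.out = n)
      nxt <<- nxt + n
      idx
    }
  })
  layout <- list(
    early = take(2L), late = take(2L), male = take(2L),
    mito = take(4L), heatshock = take(4L)
  )
  tf_idx <- take(config$n_tfs)
  n_code <- 2L
  need_tfs <- config$n_cascade + n_code * config$n_lineages + config$n_regulons
  if (config$n_tfs < need_tfs) {
    stop(sprintf(
      "n_tfs too small: need %d (cascade %d + %d per-lineage codes + %d regulon TFs)",
      need_tfs, config$n_cascade, n_code * config$n_lineages, config$n_regulons
    ))
  }
  layout$tf_all <- tf_idx
  layout$cascade <- tf_idx[seq_len(config$n_cascade)]
  layout$lineage_code <- split(
    tf_idx[config$n_cascade + seq_len(n_code * config$n_lineages)],
    rep(seq_len(config$n_lineages), each = n_code)
  )
  layout$regulon_tfs <- tf_idx[config$n_cascade + n_code * config$n_lineages +
    seq_len(config$n_regulons)]
  layout$regulon_targets <- split(
    take(config$n_regulons * config$regulon_size),
    rep(seq_len(config$n_regulons), each = config$regulon_size)
  )
  layout$early_diversity <- take(50L)
  n_used <- max(layout$early_diversity)
  if (config$n_genes < n_used + 20L) {
    stop(sprintf(
      "n_genes too small to host all programs: need >= %d, got %d",
      n_used + 20L, config$n_genes
    ))
  }
  layout$background <- seq.int(n_used + 1L, config$n_genes)
  layout
}

#' Generate a ground-truth-labelled synthetic atlas
#'
#' Draws UMI counts from a negative-binomial model whose per-gene log-means
#' encode the simulated programs (see [simulation_config()]), builds a 2-D
#' embedding with punctate early-born / serpentine late-born geometry via
#' [generate_embedding()], and optionally appends doublets via
#' [spike_doublets()].
#'
#' @param config A [simulation_config()].
#' @return A list with elements `atlas` (an [atlas()]) and `truth`
#'   (class `atlas_truth`: the lineage TF codes, the ordered temporal
#'   cascade with activation windows, the true regulons and the gene
#'   layout).
#' @export
#' @examples
#' sim <- generate_atlas(simulation_config(n_lineages = 2, cells_per_lineage = 50))
#' sim$atlas
generate_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    layout <- gene_layout(config)
    G <- config$n_genes
    L <- config$n_lineages
    N <- L * config$cells_per_lineage

    gene_meta <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(G)),
      is_tf = seq_len(G) %in% layout$tf_all,
      is_mito = seq_len(G) %in% layout$mito,
      is_heatshock = seq_len(G) %in% layout$heatshock,
      program = "background"
    )
    gene_meta$program[layout$early] <- "early"
    gene_meta$program[layout$late] <- "late"
    gene_meta$program[layout$male] <- "male"
    gene_meta$program[layout$mito] <- "mito"
    gene_meta$program[layout$heatshock] <- "heatshock"
    gene_meta$program[layout$cascade] <- sprintf("cascade_%d", seq_along(layout$cascade))
    for (l in seq_len(L)) gene_meta$program[layout$lineage_code[[l]]] <- sprintf("code_L%02d", l)
    for (r in seq_len(config$n_regulons)) {
      gene_meta$program[layout$regulon_tfs[r]] <- sprintf("regulon_tf_%d", r)
      gene_meta$program[layout$regulon_targets[[r]]] <- sprintf("regulon_target_%d", r)
    }
    gene_meta$program[layout$early_diversity] <- "early_diversity"

    lineage_id <- sprintf("L%02d", rep(seq_len(L), each = config$cells_per_lineage))
    birth_time <- stats::runif(N)
    birth_class <- ifelse(birth_time < config$early_fraction, "early", "late")
    cell_meta <- tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(N)),
      dataset = sprintf("ds%d", 1L + (seq_len(N) - 1L) %% 2L),
      batch = sprintf("batch%d", sample.int(config$n_batches, N, replace = TRUE)),
      cluster = lineage_id,
      lineage_id = lineage_id,
      lineage_type = ifelse(
        rep(seq_len(L), each = config$cells_per_lineage) %% 2L == 1L, "type I", "type II"
      ),
      sex = ifelse(stats::runif(N) < config$male_fraction, "male", "female"),
      birth_time = birth_time,
      birth_class = birth_class,
      is_doublet = FALSE,
      parent1 = NA_character_,
      parent2 = NA_character_
    )

    mu <- matrix(0, nrow = G, ncol = N)
    early <- birth_class == "early"
    male <- cell_meta$sex == "male"
    mu[layout$background, ] <- stats::runif(length(layout$background), 0.8, 2.0)
    # Early-extra genes have a low baseline everywhere and burst
    # stochastically in a random half of the early cells, so the block is
    # enriched in early cells without forming a single on/off module.
    mu[layout$early_diversity, ] <- 0.3
    mu[layout$early_diversity, early] <- 0.3 + 1.6 *
      (matrix(stats::runif(length(layout$early_diversity) * sum(early)),
        nrow = length(layout$early_diversity)) < 0.5)
    mu[layout$early, early] <- 8
    mu[layout$late, !early] <- 8
    mu[layout$male, male] <- 8
    mu[layout$mito, ] <- 1.0
    mu[layout$heatshock, ] <- 0.5

    cascade <- cascade_windows(layout$cascade, gene_meta$gene_id, config$n_cascade)
    for (j in seq_len(config$n_cascade)) {
      in_win <- birth_time >= cascade$t_on[j] & birth_time <= cascade$t_off[j]
      mu[layout$cascade[j], in_win] <- 6
    }
    for (l in seq_len(L)) {
      mu[layout$lineage_code[[l]], lineage_id == sprintf("L%02d", l)] <- 6
    }
    regulons_true <- list()
    for (r in seq_len(config$n_regulons)) {
      activity <- 0.2 + 3.8 * (stats::runif(N) < 0.4)
      mu[layout$regulon_tfs[r], ] <- 1.5 * activity
      mu[layout$regulon_targets[[r]], ] <-
        matrix(activity, nrow = config$regulon_size, ncol = N, byrow = TRUE)
      regulons_true[[gene_meta$gene_id[layout$regulon_tfs[r]]]] <-
        gene_meta$gene_id[layout$regulon_targets[[r]]]
    }

    # Calibrate the early/late expected-total-UMI ratio exactly to the
    # configured multiplier (the larger early active-gene set already
    # contributes; the residual is absorbed into a uniform early scaling).
    if (any(early) && any(!early)) {
      t_early <- mean(colSums(mu[, early, drop = FALSE]))
      t_late <- mean(colSums(mu[, !early, drop = FALSE]))
      mu[, early] <- mu[, early, drop = FALSE] *
        (config$early_umi_multiplier * t_late / t_early)
    }

    if (config$batch_shift_sd > 0) {
      shift <- matrix(
        stats::rnorm(G * config$n_batches, 0, config$batch_shift_sd),
        nrow = G
      )
      batch_idx <- as.integer(sub("batch", "", cell_meta$batch))
      mu <- mu * exp(shift[, batch_idx, drop = FALSE])
    }

    counts <- matrix(
      stats::rnbinom(G * N, mu = as.vector(mu), size = 1 / config$noise_dispersion),
      nrow = G
    )

    spec <- default_morphology_spec(unique(lineage_id))
    cell_meta <- generate_embedding(cell_meta, spec)

    atl <- atlas(counts, cell_meta, gene_meta)
    truth <- structure(list(
      lineage_tf_code = stats::setNames(
        lapply(layout$lineage_code, function(i) gene_meta$gene_id[i]),
        sprintf("L%02d", seq_len(L))
      ),
      temporal_cascade = cascade,
      regulons_true = regulons_true,
      male_genes = gene_meta$gene_id[layout$male],
      early_genes = gene_meta$gene_id[layout$early],
      late_genes = gene_meta$gene_id[layout$late],
      layout = layout,
      config = config
    ), class = "atlas_truth")

    if (config$doublet_rate > 0) {
      atl <- spike_doublets(atl, config$doublet_rate)
    }
    list(atlas = atl, truth = truth)
  })
}

# Ordered activation windows on birth_time: evenly spaced centres, widths
# chosen so only adjacent windows overlap.
cascade_windows <- function(idx, gene_ids, n) {
  centre <- (seq_len(n) - 0.5) / n
  half <- 0.7 / n
  tibble::tibble(
    gene = gene_ids[idx],
    t_on = pmax(0, centre - half),
    t_off = pmin(1, centre + half)
  )
}

#' Serialise / load the simulation ground truth
#'
#' Writes the generator's ground truth (lineage TF codes, temporal
#' cascade windows, true regulons, configuration) as JSON next to the
#' plain-text atlas files.
#'
#' @param truth An `atlas_truth` from [generate_atlas()].
#' @param path Output (input) JSON file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns a
#'   list mirroring the truth object (without the gene-layout indices).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "atlas_truth"))
  out <- list(
    lineage_tf_code = truth$lineage_tf_code,
    temporal_cascade = truth$temporal_cascade,
    regulons_true = truth$regulons_true,
    male_genes = truth$male_genes,
    early_genes = truth$early_genes,
    late_genes = truth$late_genes,
    config = unclass(truth$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$temporal_cascade <- tibble::as_tibble(raw$temporal_cascade)
  raw$lineage_tf_code <- lapply(raw$lineage_tf_code, unlist)
  raw$regulons_true <- lapply(raw$regulons_true, unlist)
  raw
}

#' Default per-lineage embedding morphology specification
#'
#' Early-born cells are laid out as `k` well-separated Gaussian blobs
#' (punctate); late-born cells along a smooth curve ordered by birth time
#' with tube noise (serpentine).
#'
#' @param lineage_ids Character vector of lineage ids.
#' @param early_type,late_type "punctate" or "serpentine" per birth class.
#' @param k Number of blobs for punctate groups.
#' @param blob_sd Gaussian blob SD (embedding units).
#' @param span Serpentine curve horizontal span.
#' @param amplitude Serpentine curve amplitude.
#' @param tube_sd Serpentine tube noise SD.
#' @return A tibble, one row per (lineage, birth class).
#' @export
default_morphology_spec <- function(lineage_ids, early_type = "punctate",
                                    late_type = "serpentine", k = 3,
                                    blob_sd = 0.1, span = 12, amplitude = 2,
                                    tube_sd = 0.1) {
  tidyr::expand_grid(
    lineage_id = lineage_ids,
    birth_class = c("early", "late")
  ) |>
    dplyr::mutate(
      type = ifelse(.data$birth_class == "early", early_type, late_type),
      k = k, blob_sd = blob_sd, span = span, amplitude = amplitude,
      tube_sd = tube_sd
    )
}

#' Single-curve morphology specification
#'
#' Lays each whole lineage (early and late cells together) along one
#' serpentine curve ordered by birth time — the geometry of a continuous
#' birth-order trajectory, used for pseudotime analyses.
#'
#' @inheritParams default_morphology_spec
#' @return A tibble with `birth_class = "all"` rows.
#' @export
serpentine_lineage_spec <- function(lineage_ids, span = 20, amplitude = 2,
                                    tube_sd = 0.1) {
  tibble::tibble(
    lineage_id = lineage_ids,
    birth_class = "all",
    type = "serpentine",
    k = NA_real_, blob_sd = NA_real_,
    span = span, amplitude = amplitude, tube_sd = tube_sd
  )
}

#' Generate a 2-D embedding with prescribed cluster morphology
#'
#' Each lineage is allocated a territory on a grid; within it, each
#' (lineage, birth class) group is drawn either as `k` separated Gaussian
#' blobs ("punctate") or as points along a smooth sine curve ordered by
#' birth time with Gaussian tube noise ("serpentine").
#'
#' @param cell_meta A data frame with `lineage_id`, `birth_class` and
#'   `birth_time` columns.
#' @param morphology_spec A tibble as from [default_morphology_spec()];
#'   every (lineage, birth class) present in `cell_meta` must be covered.
#' @param territory_spacing Grid spacing between lineage territories.
#' @return `cell_meta` with `embedding_x` / `embedding_y` columns
#'   (re)filled.
#' @export
generate_embedding <- function(cell_meta, morphology_spec,
                               territory_spacing = 30) {
  cm <- tibble::as_tibble(cell_meta)
  lineages <- unique(cm$lineage_id)
  ncol_grid <- ceiling(sqrt(length(lineages)))
  centres <- tibble::tibble(
    lineage_id = lineages,
    cx = ((seq_along(lineages) - 1L) %% ncol_grid) * territory_spacing,
    cy = ((seq_along(lineages) - 1L) %/% ncol_grid) * territory_spacing
  )
  cm$embedding_x <- NA_real_
  cm$embedding_y <- NA_real_
  # A spec row with birth_class "all" lays out the whole lineage as one
  # group (e.g. a single continuous curve spanning early and late cells).
  whole <- unique(morphology_spec$lineage_id[morphology_spec$birth_class == "all"])
  groups <- dplyr::distinct(cm, .data$lineage_id, .data$birth_class) |>
    dplyr::mutate(
      birth_class = ifelse(.data$lineage_id %in% whole, "all", .data$birth_class)
    ) |>
    dplyr::distinct()
  for (i in seq_len(nrow(groups))) {
    lid <- groups$lineage_id[i]
    bc <- groups$birth_class[i]
    spec <- morphology_spec[
      morphology_spec$lineage_id == lid & morphology_spec$birth_class == bc,
    ]
    if (nrow(spec) == 0) stop("no morphology spec for lineage ", lid, " / ", bc)
    spec <- spec[1, ]
    rows <- if (bc == "all") {
      which(cm$lineage_id == lid)
    } else {
      which(cm$lineage_id == lid & cm$birth_class == bc)
    }
    ctr <- centres[centres$lineage_id == lid, ]
    offset_y <- switch(bc,
      early = territory_spacing / 3.5,
      late = -territory_spacing / 3.5,
      0
    )
    pts <- switch(spec$type,
      punctate = punctate_points(cm$birth_time[rows], spec$k, spec$blob_sd),
      serpentine = serpentine_points(
        cm$birth_time[rows], spec$span, spec$amplitude, spec$tube_sd
      ),
      stop("unknown morphology type: ", spec$type)
    )
    cm$embedding_x[rows] <- pts[, 1] + ctr$cx
    cm$embedding_y[rows] <- pts[, 2] + ctr$cy + offset_y
  }
  cm
}

punctate_points <- function(birth_time, k, blob_sd) {
  if (k < 1) stop("punctate morphology needs k >= 1 blobs")
  # Blob centres on a circle whose radius guarantees the separation
  # contract: inter-centre distance >= 10 * blob_sd.
  radius <- if (k == 1) 0 else max(5, 10 * blob_sd / (2 * sin(pi / k)))
  angles <- 2 * pi * (seq_len(k) - 1) / k
  cx <- radius * cos(angles)
  cy <- radius * sin(angles)
  # Cells are assigned to blobs by birth-time slice: blobs are discrete
  # temporal windows within the early contingent.
  blob <- pmin(k, 1L + floor(rank(birth_time, ties.method = "first") /
    (length(birth_time) + 1) * k))
  n <- length(birth_time)
  cbind(
    cx[blob] + stats::rnorm(n, 0, blob_sd),
    cy[blob] + stats::rnorm(n, 0, blob_sd)
  )
}

serpentine_points <- function(birth_time, span, amplitude, tube_sd) {
  if (span <= 0) stop("serpentine morphology needs span > 0")
  n <- length(birth_time)
  s <- (rank(birth_time, ties.method = "first") - 0.5) / n
  cbind(
    (s - 0.5) * span + stats::rnorm(n, 0, tube_sd),
    amplitude * sin(2 * pi * s) + stats::rnorm(n, 0, tube_sd)
  )
}

#' Append simulated doublets to an atlas
#'
#' Each doublet column is the element-wise sum of two distinct sampled
#' singlet cells (UMI counts are additive), flagged in `cell_meta` with its
#' parent cell ids recorded; the doublet's embedding is the midpoint of its
#' parents'.
#'
#' @param x An [atlas()].
#' @param rate Fraction of current cells to append as doublets, in
#'   `[0, 0.5)`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A new `atlas` with `round(rate * n_cells)` extra columns.
#' @export
spike_doublets <- function(x, rate, seed = NULL) {
  if (rate < 0 || rate >= 0.5) stop("rate must be in [0, 0.5)")
  if (rate == 0) return(x)
  run <- function() {
    singlets <- which(!x$cell_meta$is_doublet)
    n_dbl <- round(rate * n_cells(x))
    if (n_dbl == 0) return(x)
    p1 <- sample(singlets, n_dbl, replace = TRUE)
    p2 <- vapply(p1, function(i) sample(setdiff(singlets, i), 1L), integer(1))
    dbl_counts <- x$counts[, p1, drop = FALSE] + x$counts[, p2, drop = FALSE]
    dbl_meta <- x$cell_meta[p1, ]
    dbl_meta$cell_id <- sprintf("dbl_%05d", seq_len(n_dbl))
    dbl_meta$is_doublet <- TRUE
    dbl_meta$parent1 <- x$cell_meta$cell_id[p1]
    dbl_meta$parent2 <- x$cell_meta$cell_id[p2]
    if (all(c("embedding_x", "embedding_y") %in% names(x$cell_meta))) {
      dbl_meta$embedding_x <- (x$cell_meta$embedding_x[p1] + x$cell_meta$embedding_x[p2]) / 2
      dbl_meta$embedding_y <- (x$cell_meta$embedding_y[p1] + x$cell_meta$embedding_y[p2]) / 2
    }
    atlas(
      cbind(x$counts, dbl_counts),
      dplyr::bind_rows(x$cell_meta, dbl_meta),
      x$gene_meta
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
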