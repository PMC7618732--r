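#' Construct an atlas object
#'
#' An `atlas` bundles a sparse gene-by-cell UMI count matrix with per-cell
#' and per-gene metadata. It is the substrate every analysis stage in this
#' package operates on. Cells are columns, genes are rows.
#'
#' @param counts A sparse (or dense) non-negative integer matrix, genes in
#'   rows, cells in columns. Dimnames are taken from `gene_meta$gene_id` and
#'   `cell_meta$cell_id` if absent.
#' @param cell_meta A data frame with one row per cell. Must contain a
#'   `cell_id` column matching the columns of `counts`.
#' @param gene_meta A data frame with one row per gene. Must contain a
#'   `gene_id` column matching the rows of `counts`. Logical flag columns
#'   `is_tf`, `is_mito` and `is_heatshock` are used by downstream stages and
#'   are filled with `FALSE` when missing.
#'
#' @return An object of class `atlas`: a list with elements `counts`
#'   (a `dgCMatrix`), `cell_meta` and `gene_meta` (tibbles).
#' @export
#' @examples
#' counts <- matrix(rpois(20, 2), nrow = 4)
#' atl <- atlas(counts,
#'   cell_meta = tibble::tibble(cell_id = paste0("c", 1:5)),
#'   gene_meta = tibble::tibble(gene_id = paste0("g", 1:4))
#' )
#' atl
atlas <- function(counts, cell_meta, gene_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  cell_meta <- tibble::as_tibble(cell_meta)
  gene_meta <- tibble::as_tibble(gene_meta)
  if (!"cell_id" %in% names(cell_meta)) stop("cell_meta must have a cell_id column")
  if (!"gene_id" %in% names(gene_meta)) stop("gene_meta must have a gene_id column")
  if (ncol(counts) != nrow(cell_meta)) stop("ncol(counts) != nrow(cell_meta)")
  if (nrow(counts) != nrow(gene_meta)) stop("nrow(counts) != nrow(gene_meta)")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers (UMI)")
  for (flag in c("is_tf", "is_mito", "is_heatshock")) {
    if (!flag %in% names(gene_meta)) gene_meta[[flag]] <- FALSE
  }
  dimnames(counts) <- list(gene_meta$gene_id, cell_meta$cell_id)
  structure(
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
    class = "atlas"
  )
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf(
    "<atlas> %d genes x %d cells (%d TFs, %d flagged doublets)\n",
    nrow(x$counts), ncol(x$counts), sum(x$gene_meta$is_tf),
    if ("is_doublet" %in% names(x$cell_meta)) sum(x$cell_meta$is_doublet) else 0L
  ))
  cat("cell_meta: ", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells / genes in an atlas
#' @param x An `atlas`.
#' @return An integer.
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

#' Subset an atlas by cells or genes
#'
#' @param x An `atlas`.
#' @param cells,genes Logical, integer or character (id) index into cells or
#'   genes; `NULL` keeps everything.
#' @return A new `atlas`.
#' @export
subset_atlas <- function(x, cells = NULL, genes = NULL) {
  ci <- resolve_index(cells, x$cell_meta$cell_id, n_cells(x))
  gi <- resolve_index(genes, x$gene_meta$gene_id, n_genes(x))
  atlas(x$counts[gi, ci, drop = FALSE], x$cell_meta[ci, ], x$gene_meta[gi, ])
}

resolve_index <- function(idx, ids, n) {
  if (is.null(idx)) return(seq_len(n))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ids: ", paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) return(which(idx))
  idx
}

#' Log-normalised expression
#'
#' Per-cell depth normalisation followed by a log transform:
#' `ln(1 + count / cell_total * scale_factor)`. This is the expression
#' representation used by module scoring, marker testing and the
#' correlation-based network backend.
#'
#' @param x An `atlas`.
#' @param scale_factor Library-size target (default 1e4).
#' @return A sparse `dgCMatrix`, genes x cells.
#' @export
lognorm <- function(x, scale_factor = 1e4) {
  totals <- Matrix::colSums(x$counts)
  totals[totals == 0] <- 1
  out <- x$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(x$counts)
  methods::as(out, "CsparseMatrix")
}

#' Per-cell QC summaries
#'
#' @param x An `atlas`.
#' @return A tibble with `cell_id`, `n_umi`, `n_genes_detected`,
#'   `mito_frac`, `heatshock_frac`.
#' @export
cell_qc_stats <- function(x) {
  totals <- Matrix::colSums(x$counts)
  safe_tot <- ifelse(totals == 0, 1, totals)
  tibble::tibble(
    cell_id = x$cell_meta$cell_id,
    n_umi = as.numeric(totals),
    n_genes_detected = Matrix::colSums(x$counts > 0),
    mito_frac = as.numeric(Matrix::colSums(x$counts[x$gene_meta$is_mito, , drop = FALSE]) / safe_tot),
    heatshock_frac = as.numeric(Matrix::colSums(x$counts[x$gene_meta$is_heatshock, , drop = FALSE]) / safe_tot)
  )
}

#' Write / read an atlas as plain-text files
#'
#' Serialises the counts as Matrix Market (`matrix.mtx`) with `genes.tsv`
#' and `barcodes.tsv`, plus `cell_meta.tsv` and `gene_meta.tsv`. A
#' round-trip through disk is byte-stable for a fixed atlas.
#'
#' @param x An `atlas`.
#' @param dir Output (input) directory.
#' @return `write_atlas` returns `dir` invisibly; `read_atlas` returns an
#'   `atlas`.
#' @export
write_atlas <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_meta$gene_id, file.path(dir, "genes.tsv"))
  writeLines(x$cell_meta$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(x$gene_meta, file.path(dir, "gene_meta.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cell_meta <- tibble::as_tibble(utils::read.delim(file.path(dir, "cell_meta.tsv")))
  gene_meta <- tibble::as_tibble(utils::read.delim(file.path(dir, "gene_meta.tsv")))
  atlas(counts, cell_meta, gene_meta)
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
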