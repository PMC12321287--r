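# Streaming quality control and normalization.
#
# Per-cell statistics are complete within a chunk; the per-gene
# expressing-cell count is the one cross-chunk array, updated incrementally so
# a single pass over all chunks finalizes both filters.

#' Accumulate QC statistics in one pass over chunks
#'
#' @param store a `ChunkedMatrix` of raw counts.
#' @return an object of class `QCStats`: `genes_per_cell`, `counts_per_cell`
#'   (per cell) and `cells_per_gene` (per gene, accumulated across chunks).
#' @export
accumulate_qc <- function(store) {
  genes_per_cell <- integer(store$n_cells)
  counts_per_cell <- numeric(store$n_cells)
  cells_per_gene <- integer(store$n_genes)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    if (any(b@x < 0)) stop("invalid input: negative counts")
    rows <- row_range(store$chunk_bounds, k)
    if (length(rows) == 0) next
    nz <- b
    nz@x <- rep(1, length(nz@x))
    genes_per_cell[rows] <- as.integer(Matrix::rowSums(nz))
    counts_per_cell[rows] <- Matrix::rowSums(b)
    cells_per_gene <- cells_per_gene + as.integer(Matrix::colSums(nz))
  }
  structure(list(genes_per_cell = genes_per_cell,
                 counts_per_cell = counts_per_cell,
                 cells_per_gene = cells_per_gene),
            class = "QCStats")
}

#' Turn QC statistics into keep/drop masks
#'
#' Cells are kept when they express at least `min_genes_per_cell` genes and
#' their total counts fall inside `[min_counts_per_cell, max_counts_per_cell]`;
#' genes are kept when expressed in at least `min_cells_per_gene` cells. The
#' gene rule is evaluated on expressing-cell counts over *all* cells (before
#' cell filtering), matching the single-pass streaming design.
#'
#' @param stats a `QCStats`.
#' @param min_genes_per_cell,min_counts_per_cell,max_counts_per_cell,min_cells_per_gene
#'   thresholds; `max_counts_per_cell = Inf` disables the upper bound.
#' @return an object of class `QCMask` with logical `cell_keep`, `gene_keep`
#'   and the thresholds used.
#' @export
build_qc_mask <- function(stats, min_genes_per_cell = 200,
                          min_counts_per_cell = 0,
                          max_counts_per_cell = Inf,
                          min_cells_per_gene = 3) {
  thr <- c(min_genes_per_cell, min_counts_per_cell, min_cells_per_gene)
  if (any(thr < 0) || max_counts_per_cell < 0) stop("config error: negative threshold")
  cell_keep <- stats$genes_per_cell >= min_genes_per_cell &
    stats$counts_per_cell >= min_counts_per_cell &
    stats$counts_per_cell <= max_counts_per_cell
  gene_keep <- stats$cells_per_gene >= min_cells_per_gene
  structure(list(cell_keep = cell_keep, gene_keep = gene_keep,
                 thresholds = list(min_genes_per_cell = min_genes_per_cell,
                                   min_counts_per_cell = min_counts_per_cell,
                                   max_counts_per_cell = max_counts_per_cell,
                                   min_cells_per_gene = min_cells_per_gene)),
            class = "QCMask")
}

#' Filter a store by a QC mask
#'
#' Survivor order is preserved on both axes; the chunk plan is re-validated
#' against the nnz cap (filtering can only shrink chunks).
#'
#' @param store a `ChunkedMatrix`.
#' @param mask a `QCMask` whose dimensions match the store.
#' @return a filtered `ChunkedMatrix`.
#' @export
apply_qc <- function(store, mask) {
  if (length(mask$cell_keep) != store$n_cells ||
      length(mask$gene_keep) != store$n_genes) {
    stop("mask dimensions do not match store")
  }
  if (!any(mask$cell_keep) || !any(mask$gene_keep)) {
    stop("empty result: QC mask removes all cells or all genes")
  }
  gk <- mask$gene_keep
  map_chunks(store, function(b) b[, gk, drop = FALSE],
             new_gene_ids = store$gene_ids[gk],
             keep_rows = mask$cell_keep)
}

#' Library-size scaling and log1p transform
#'
#' Optionally rescales each cell's counts to sum to `target_sum` (cells with
#' zero total are left at zero), then applies `log(1 + x)` elementwise. Zeros
#' map to zeros, so the sparsity pattern is preserved and the transform is
#' chunk-local (bit-identical across chunk plans).
#'
#' @param store a `ChunkedMatrix` of counts.
#' @param target_sum per-cell total after scaling, or `NULL` to skip scaling
#'   and log-transform raw counts directly. Default `1e4`.
#' @return a `ChunkedMatrix` of normalized values.
#' @export
normalize_log1p <- function(store, target_sum = 1e4) {
  if (!is.null(target_sum) && target_sum <= 0) stop("config error: target_sum must be > 0")
  map_chunks(store, function(b) {
    if (!is.null(target_sum)) {
      tot <- Matrix::rowSums(b)
      sf <- ifelse(tot > 0, target_sum / tot, 0)
      b <- Matrix::Diagonal(x = sf) %*% b
      b <- as_dgc(b)
    }
    b@x <- log1p(b@x)
    b
  })
}
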