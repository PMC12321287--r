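# Row-chunked sparse cell x gene container.
#
# Cells are rows, genes are columns. Chunk bounds are 0-based half-open row
# intervals that partition [0, n_cells). Each chunk's non-zero count stays at
# or below a configurable cap (default 2^31 - 1, the 32-bit indexing limit of
# GPU sparse backends), so any statistic written against this container can be
# streamed chunk by chunk without ever indexing past the cap.

INT32_CAP <- 2^31 - 1

#' Plan row chunks under a non-zero cap
#'
#' Greedy first-fit packing of rows (cells) into contiguous chunks such that
#' no chunk holds more than `max_nnz` non-zero values. A row starts a new
#' chunk exactly when adding it would push the running total past the cap,
#' which keeps row order stable and makes the plan deterministic.
#'
#' @param row_nnz integer vector of per-row non-zero counts.
#' @param max_nnz cap on non-zeros per chunk; default `2^31 - 1`.
#' @param target_rows optional additional cap on rows per chunk.
#' @return an object of class `ChunkPlan` with elements `bounds` (n_chunks x 2
#'   matrix of 0-based half-open row intervals) and `max_nnz`.
#' @examples
#' plan_chunks(c(3, 2, 5), max_nnz = 5)$bounds  # rows {0,1} then row {2}
#' @export
plan_chunks <- function(row_nnz, max_nnz = INT32_CAP, target_rows = NULL) {
  row_nnz <- as.numeric(row_nnz)
  if (any(row_nnz < 0)) stop("row_nnz must be non-negative")
  if (max_nnz <= 0) stop("max_nnz must be positive")
  n <- length(row_nnz)
  if (n > 0 && max(row_nnz) > max_nnz) {
    stop("unsatisfiable plan: a single row exceeds max_nnz = ", max_nnz)
  }
  starts <- integer(0)
  if (n > 0) {
    cur_nnz <- 0
    cur_rows <- 0L
    starts <- 0L
    for (i in seq_len(n)) {
      over_nnz <- cur_nnz + row_nnz[i] > max_nnz
      over_rows <- !is.null(target_rows) && cur_rows + 1L > target_rows
      if (cur_rows > 0L && (over_nnz || over_rows)) {
        starts <- c(starts, i - 1L)
        cur_nnz <- 0
        cur_rows <- 0L
      }
      cur_nnz <- cur_nnz + row_nnz[i]
      cur_rows <- cur_rows + 1L
    }
  }
  bounds <- cbind(start = starts, end = c(starts[-1], n))
  structure(list(bounds = bounds, max_nnz = max_nnz), class = "ChunkPlan")
}

# Even row split into a requested number of chunks (used to exercise chunk
# invariance); still validated against the nnz cap.
plan_even_chunks <- function(row_nnz, n_chunks, max_nnz = INT32_CAP) {
  n <- length(row_nnz)
  n_chunks <- min(n_chunks, max(n, 1L))
  cuts <- unique(round(seq(0, n, length.out = n_chunks + 1)))
  bounds <- cbind(start = cuts[-length(cuts)], end = cuts[-1])
  nnz <- vapply(seq_len(nrow(bounds)), function(k) {
    if (bounds[k, 2] > bounds[k, 1]) sum(row_nnz[(bounds[k, 1] + 1):bounds[k, 2]]) else 0
  }, numeric(1))
  if (any(nnz > max_nnz)) stop("unsatisfiable plan: even split exceeds max_nnz")
  structure(list(bounds = bounds, max_nnz = max_nnz), class = "ChunkPlan")
}

new_chunked_matrix <- function(n_cells, n_genes, bounds, chunk_nnz, storage_mode,
                               gene_ids, cell_ids, batch = NULL,
                               chunks = NULL, chunk_dir = NULL) {
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    chunk_bounds = bounds, chunk_nnz = as.numeric(chunk_nnz),
    storage_mode = storage_mode,
    gene_ids = gene_ids, cell_ids = cell_ids, batch = batch,
    chunks = chunks, chunk_dir = chunk_dir
  ), class = "ChunkedMatrix")
}

#' Build a chunked store from an in-memory sparse matrix
#'
#' @param x a cells x genes matrix (coerced to `dgCMatrix`).
#' @param plan a [plan_chunks()] result, or `NULL` to plan automatically.
#' @param max_nnz chunk cap used when planning automatically.
#' @param mode storage backend: `"resident"` and `"host"` keep chunk blocks in
#'   memory (`resident` is an alias of `host` with an injectable array backend
#'   left as an extension point); `"stream"` writes each chunk to disk and
#'   re-reads it lazily on every iteration.
#' @param gene_ids,cell_ids identifiers; defaults from dimnames or generated.
#' @param batch optional per-cell batch/sample labels.
#' @param dir directory for stream-mode chunk files (default: a tempdir).
#' @return a `ChunkedMatrix`.
#' @export
as_chunked <- function(x, plan = NULL, max_nnz = INT32_CAP,
                       mode = c("host", "resident", "stream"),
                       gene_ids = NULL, cell_ids = NULL, batch = NULL,
                       dir = NULL) {
  mode <- match.arg(mode)
  x <- as_dgc(x)
  n_cells <- nrow(x); n_genes <- ncol(x)
  if (is.null(gene_ids)) gene_ids <- colnames(x) %||% sprintf("gene_%d", seq_len(n_genes))
  if (is.null(cell_ids)) cell_ids <- rownames(x) %||% sprintf("cell_%d", seq_len(n_cells))
  if (!is.null(batch) && length(batch) != n_cells) stop("batch length != n_cells")
  row_nnz <- row_nnz_dgc(x)
  if (is.null(plan)) plan <- plan_chunks(row_nnz, max_nnz)
  bounds <- plan$bounds
  if (nrow(bounds) == 0 || bounds[nrow(bounds), 2] != n_cells) {
    if (!(n_cells == 0 && nrow(bounds) == 0)) stop("plan does not cover all rows")
  }
  blocks <- lapply(seq_len(nrow(bounds)), function(k) {
    rows <- row_range(bounds, k)
    b <- if (length(rows) == 0) x[0, , drop = FALSE] else x[rows, , drop = FALSE]
    dimnames(b) <- NULL  # ids live at the store level, blocks are anonymous
    b
  })
  chunk_nnz <- vapply(blocks, function(b) as.numeric(length(b@x)), numeric(1))
  if (any(chunk_nnz > plan$max_nnz)) stop("unsatisfiable plan: chunk exceeds max_nnz")
  if (mode == "stream") {
    if (is.null(dir)) dir <- tempfile("chunkstore_")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(blocks)) {
      Matrix::writeMM(blocks[[k]], file.path(dir, sprintf("chunk_%05d.mtx", k)))
    }
    new_chunked_matrix(n_cells, n_genes, bounds, chunk_nnz, "stream",
                       gene_ids, cell_ids, batch, chunks = NULL, chunk_dir = dir)
  } else {
    new_chunked_matrix(n_cells, n_genes, bounds, chunk_nnz, mode,
                       gene_ids, cell_ids, batch, chunks = blocks)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

row_nnz_dgc <- function(x) {
  if (length(x@x) == 0) return(integer(nrow(x)))
  tabulate(x@i + 1L, nbins = nrow(x))
}

row_range <- function(bounds, k) {
  if (bounds[k, 2] <= bounds[k, 1]) return(integer(0))
  (bounds[k, 1] + 1L):bounds[k, 2]
}

#' @method print ChunkedMatrix
#' @export
print.ChunkedMatrix <- function(x, ...) {
  cat(sprintf("ChunkedMatrix: %d cells x %d genes, %d chunk(s), %s nnz, mode=%s\n",
              x$n_cells, x$n_genes, n_chunks(x),
              format(sum(x$chunk_nnz), big.mark = ","), x$storage_mode))
  invisible(x)
}

#' Number of chunks in a store
#' @param store a `ChunkedMatrix`.
#' @export
n_chunks <- function(store) nrow(store$chunk_bounds)

#' Fetch one chunk as a sparse block
#'
#' Stream-mode stores re-read the block from disk on every call, so repeated
#' iteration yields identical content without keeping blocks in memory.
#'
#' @param store a `ChunkedMatrix`.
#' @param k chunk index (1-based).
#' @return a `dgCMatrix` holding the rows of `chunk_interval(store, k)`.
#' @export
get_chunk <- function(store, k) {
  stopifnot(k >= 1, k <= n_chunks(store))
  if (store$storage_mode == "stream") {
    f <- file.path(store$chunk_dir, sprintf("chunk_%05d.mtx", k))
    if (!file.exists(f)) stop("I/O error: chunk file missing: ", f)
    as_dgc(Matrix::readMM(f))
  } else {
    store$chunks[[k]]
  }
}

#' Row interval (0-based, half-open) of one chunk
#' @param store a `ChunkedMatrix`.
#' @param k chunk index (1-based).
#' @export
chunk_interval <- function(store, k) store$chunk_bounds[k, ]

#' Apply a function over chunks in row order
#'
#' The canonical iteration primitive: `f(block, interval, k)` is called once
#' per chunk, in row order, and the results are returned as a list. Iteration
#' order and content are identical across storage modes.
#'
#' @param store a `ChunkedMatrix`.
#' @param f function of `(block, interval, k)`.
#' @export
chunk_apply <- function(store, f) {
  lapply(seq_len(n_chunks(store)), function(k) {
    f(get_chunk(store, k), chunk_interval(store, k), k)
  })
}

#' Materialize the whole logical matrix
#'
#' Row-wise concatenation of all chunks; intended for small matrices and
#' oracle comparisons in tests, not for production-scale data.
#' @param store a `ChunkedMatrix`.
#' @return a `dgCMatrix`.
#' @export
as_matrix.ChunkedMatrix <- function(store) {
  blocks <- chunk_apply(store, function(b, iv, k) b)
  out <- if (length(blocks) == 0) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(store$n_cells, store$n_genes))
  } else {
    do.call(rbind, blocks)
  }
  dimnames(out) <- list(store$cell_ids, store$gene_ids)
  as_dgc(out)
}

#' @export
as_matrix <- function(store) UseMethod("as_matrix")

# Map every chunk through `f` (block -> block), producing a new store in the
# same mode. Column set may change (pass new_gene_ids); rows may be dropped
# (pass keep_rows, a logical over all cells).
map_chunks <- function(store, f, new_gene_ids = NULL, keep_rows = NULL,
                       new_batch = store$batch) {
  gene_ids <- new_gene_ids %||% store$gene_ids
  blocks <- list()
  cell_keep_all <- keep_rows %||% rep(TRUE, store$n_cells)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    iv <- chunk_interval(store, k)
    rows <- row_range(store$chunk_bounds, k)
    kp <- cell_keep_all[rows]
    b <- b[kp, , drop = FALSE]
    blocks[[k]] <- as_dgc(f(b))
  }
  starts <- cumsum(c(0, vapply(blocks, nrow, integer(1))))
  n_cells <- starts[length(starts)]
  bounds <- cbind(start = starts[-length(starts)], end = starts[-1])
  # drop empty chunks produced by filtering
  keep_chunks <- bounds[, 2] > bounds[, 1]
  if (n_cells > 0) {
    bounds <- bounds[keep_chunks, , drop = FALSE]
    blocks <- blocks[keep_chunks]
  } else {
    bounds <- bounds[0, , drop = FALSE]; blocks <- list()
  }
  chunk_nnz <- vapply(blocks, function(b) as.numeric(length(b@x)), numeric(1))
  cell_ids <- store$cell_ids[cell_keep_all]
  batch <- if (!is.null(new_batch)) new_batch[cell_keep_all] else NULL
  if (store$storage_mode == "stream") {
    dir <- tempfile("chunkstore_")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(blocks)) {
      Matrix::writeMM(blocks[[k]], file.path(dir, sprintf("chunk_%05d.mtx", k)))
    }
    new_chunked_matrix(n_cells, length(gene_ids), bounds, chunk_nnz, "stream",
                       gene_ids, cell_ids, batch, chunk_dir = dir)
  } else {
    new_chunked_matrix(n_cells, length(gene_ids), bounds, chunk_nnz,
                       store$storage_mode, gene_ids, cell_ids, batch,
                       chunks = blocks)
  }
}

#' Open a 10x-style MTX directory as a chunked store
#'
#' Reads a MatrixMarket triplet directory (`matrix.mtx[.gz]` with genes as
#' rows and cell barcodes as columns, per the 10x convention, plus
#' `features.tsv[.gz]` and `barcodes.tsv[.gz]`), transposes to cells x genes,
#' and chunks it under the nnz cap. MatrixMarket indices are 1-based on disk
#' and converted to the package's 0-based intervals on read.
#'
#' @param path directory containing the triplet files.
#' @param fmt input format; only `"mtx_dir"` is supported.
#' @param mode storage backend, see [as_chunked()].
#' @param plan optional [plan_chunks()] result; `NULL` plans automatically.
#' @param max_nnz chunk cap for automatic planning.
#' @param batch_key if the barcodes table has >1 column, name or index of the
#'   column holding per-cell batch labels (default: none).
#' @return a `ChunkedMatrix`.
#' @export
open_store <- function(path, fmt = c("mtx_dir"), mode = c("host", "resident", "stream"),
                       plan = NULL, max_nnz = INT32_CAP, batch_key = NULL) {
  fmt <- match.arg(fmt)
  mode <- match.arg(mode)
  if (!dir.exists(path)) stop("parse error: not a directory: ", path)
  find1 <- function(base) {
    for (f in c(file.path(path, base), file.path(path, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("parse error: missing ", base, " in ", path)
  }
  m <- tryCatch(Matrix::readMM(find1("matrix.mtx")),
                error = function(e) stop("parse error: ", conditionMessage(e)))
  feat <- utils::read.table(find1("features.tsv"), sep = "\t",
                            stringsAsFactors = FALSE, quote = "", comment.char = "")
  bc <- utils::read.table(find1("barcodes.tsv"), sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (nrow(feat) != nrow(m)) stop("parse error: features.tsv rows != matrix rows")
  if (nrow(bc) != ncol(m)) stop("parse error: barcodes.tsv rows != matrix columns")
  x <- as_dgc(Matrix::t(m))  # cells x genes
  batch <- NULL
  if (!is.null(batch_key)) {
    if (!batch_key %in% seq_len(ncol(bc)) && !batch_key %in% names(bc)) {
      stop("invalid batch_key")
    }
    batch <- bc[[batch_key]]
  }
  as_chunked(x, plan = plan, max_nnz = max_nnz, mode = mode,
             gene_ids = feat[[1]], cell_ids = bc[[1]], batch = batch)
}

#' Write a chunked store as a 10x-style MTX directory
#'
#' Genes are written as matrix rows per the 10x convention; a round-trip
#' through [open_store()] reproduces values, identifiers and dimensions
#' exactly.
#'
#' @param store a `ChunkedMatrix`.
#' @param path output directory (created if needed).
#' @param fmt only `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path, fmt = c("mtx_dir")) {
  fmt <- match.arg(fmt)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  x <- as_matrix(store)
  Matrix::writeMM(Matrix::t(x), file.path(path, "matrix.mtx"))
  feat <- data.frame(id = store$gene_ids, symbol = store$gene_ids)
  utils::write.table(feat, file.path(path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bc <- if (!is.null(store$batch)) {
    data.frame(barcode = store$cell_ids, batch = store$batch)
  } else {
    data.frame(barcode = store$cell_ids)
  }
  utils::write.table(bc, file.path(path, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Re-chunk a store under a different plan (content unchanged).
rechunk <- function(store, plan) {
  as_chunked(as_matrix(store), plan = plan, mode = store$storage_mode,
             gene_ids = store$gene_ids, cell_ids = store$cell_ids,
             batch = store$batch)
}
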