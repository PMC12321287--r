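# Shared fixtures: all test data is generated in code.

library(Matrix)

# Random sparse count matrix (cells x genes) with Poisson-valued non-zeros.
random_counts <- function(n_cells, n_genes, density = 0.1, seed = 1,
                          lambda = 2) {
  set.seed(seed)
  m <- Matrix::rsparsematrix(n_cells, n_genes, density = density,
                             rand.x = function(n) stats::rpois(n, lambda) + 1)
  dimnames(m) <- list(sprintf("c%04d", seq_len(n_cells)),
                      sprintf("g%04d", seq_len(n_genes)))
  m
}

# Store with a requested number of (even) chunks.
store_with_chunks <- function(x, n_chunks, mode = "host", batch = NULL) {
  row_nnz <- tabulate(as(x, "TsparseMatrix")@i + 1L, nbins = nrow(x))
  plan <- chunkcell:::plan_even_chunks(row_nnz, n_chunks)
  as_chunked(x, plan = plan, mode = mode, batch = batch)
}

# Well-separated Gaussian blobs: list(X = n x d matrix, labels).
make_blobs <- function(n_per = 50, centers, sd = 0.2, seed = 1) {
  set.seed(seed)
  K <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(K), each = n_per))
}
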