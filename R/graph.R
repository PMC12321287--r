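# Neighborhood graph: exact blockwise kNN, UMAP-style fuzzy connectivities,
# and delegated Leiden clustering / UMAP layout.
#
# Exactness is the point: approximate neighbor search (NN-descent and
# friends) yields platform-dependent graphs, so the search here is exhaustive
# Euclidean distance, computed in row blocks of the query set to keep memory
# at O(block x N) instead of O(N^2).

#' Exact k-nearest neighbors
#'
#' Exhaustive Euclidean search, blockwise over query rows. Self-matches are
#' excluded; ties are broken by the lower cell index so results are fully
#' deterministic and reproducible against an all-pairs oracle.
#'
#' @param embedding cells x d matrix.
#' @param k neighbor count (`k < n_cells`).
#' @param block query rows per block (default 4096).
#' @return an object of class `NeighborGraph` with `indices` (cells x k),
#'   `distances` (cells x k, ascending per row) and `k`.
#' @export
exact_knn <- function(embedding, k = 15, block = 4096) {
  N <- nrow(embedding)
  if (k >= N) stop("config error: k must be < n_cells")
  sq <- rowSums(embedding^2)
  indices <- matrix(0L, N, k)
  distances <- matrix(0, N, k)
  for (start in seq(1, N, by = block)) {
    rows <- start:min(start + block - 1, N)
    # squared distances of this block against all points
    D2 <- sq[rows] + matrix(sq, length(rows), N, byrow = TRUE) -
      2 * tcrossprod(embedding[rows, , drop = FALSE], embedding)
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      d2 <- D2[ii, ]
      d2[i] <- Inf                      # exclude self
      ord <- order(d2, seq_len(N))[seq_len(k)]  # ties -> lower index
      indices[i, ] <- ord
      distances[i, ] <- sqrt(pmax(d2[ord], 0))
    }
  }
  structure(list(indices = indices, distances = distances, k = k),
            class = "NeighborGraph")
}

#' Fuzzy simplicial connectivities from a kNN graph
#'
#' UMAP-style per-cell adaptive kernel: with `rho_i` the distance to the
#' nearest neighbor, the bandwidth `sigma_i` is solved by bisection so that
#' `sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k)`, and the directed weights
#' `exp(-max(0, d - rho)/sigma)` are symmetrized by the fuzzy union
#' `A + A' - A * A'`. Values lie in (0, 1]; each cell's nearest neighbor gets
#' the row-maximal affinity (weight 1 before union).
#'
#' @param graph a `NeighborGraph` (or list with `indices` and `distances`).
#' @return symmetric sparse affinity matrix (`dgCMatrix`).
#' @export
connectivities_from_knn <- function(graph) {
  idx <- graph$indices
  dst <- graph$distances
  N <- nrow(idx)
  k <- ncol(idx)
  target <- log2(k)
  rho <- dst[, 1]
  sigma <- vapply(seq_len(N), function(i) {
    d <- pmax(dst[i, ] - rho[i], 0)
    if (all(d == 0)) return(1)
    lo <- 1e-12; hi <- max(d) * 64
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-d / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  w <- exp(-pmax(dst - rho, 0) / sigma)
  A <- Matrix::sparseMatrix(i = rep(seq_len(N), k), j = as.vector(idx),
                            x = as.vector(w), dims = c(N, N))
  At <- Matrix::t(A)
  conn <- A + At - A * At
  as_dgc(conn)
}

#' Leiden clustering on the connectivity graph
#'
#' Delegates to igraph's Leiden community detection (modularity objective) on
#' the weighted undirected affinity graph; labels are relabeled to dense
#' 0..k-1 in decreasing cluster size. The seed is applied to the delegate's
#' RNG, so a fixed seed gives identical labels across runs.
#'
#' @param connectivities symmetric sparse affinity matrix.
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed RNG seed.
#' @param n_iterations Leiden refinement iterations (default 2).
#' @return integer vector of 0-based cluster labels.
#' @export
cluster_leiden_graph <- function(connectivities, resolution = 1, seed = 0,
                                 n_iterations = 2) {
  if (nrow(connectivities) == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(connectivities, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = n_iterations)
  ))
  relabel_by_size(as.integer(memb))
}

# Dense 0-based labels in decreasing cluster size (ties: first-seen order).
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab) - 1L, names(tab))
  unname(map[as.character(labels)])
}

#' 2-D UMAP layout
#'
#' Delegated to the uwot implementation on the corrected embedding. UMAP is
#' stochastic: a fixed seed reproduces the layout under pinned library
#' versions, but layouts are not comparable across versions.
#'
#' @param embedding cells x d matrix.
#' @param seed RNG seed.
#' @param n_neighbors,min_dist standard UMAP parameters.
#' @return cells x 2 coordinate matrix.
#' @export
embed_umap <- function(embedding, seed = 0, n_neighbors = 15, min_dist = 0.5) {
  with_seed(seed, uwot::umap(embedding, n_neighbors = n_neighbors,
                             min_dist = min_dist, n_threads = 1,
                             n_sgd_threads = 1))
}
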