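# Chunked PCA on the (normalized, HVG-restricted) matrix.
#
# The gene x gene Gram matrix X'X is a sum over chunks, and the zero-centered
# scatter follows from the identity
#   (X - m)'(X - m) = X'X - m's - s'm + N m'm,
# so a single pass accumulates everything needed for the eigendecomposition.
# With M ~ 2000 HVGs, decomposing the M x M scatter is far cheaper than an
# SVD of X. A second pass projects chunks onto the components. Eigenvector
# signs are fixed so each component's largest-magnitude loading is positive,
# which makes repeated fits (and everything downstream, e.g. Harmony) exactly
# reproducible.

#' Accumulate the Gram matrix and column sums in one pass
#'
#' @param store a `ChunkedMatrix` of normalized values (HVG columns).
#' @return list with `XtX` (gene x gene dense matrix), `s_vec` (column sums)
#'   and `N` (cell count).
#' @export
accumulate_gram <- function(store) {
  M <- store$n_genes
  XtX <- matrix(0, M, M)
  s_vec <- numeric(M)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    if (length(b@x) && any(!is.finite(b@x))) stop("invalid input: non-finite values")
    XtX <- XtX + as.matrix(Matrix::crossprod(b))
    s_vec <- s_vec + Matrix::colSums(b)
  }
  list(XtX = XtX, s_vec = s_vec, N = store$n_cells)
}

#' Zero-centered scatter from Gram accumulators
#'
#' Applies the centering identity with two rank-one outer products; the result
#' equals the directly centered cross-product `(X - m)'(X - m)` and is
#' symmetrized to remove rounding asymmetry.
#'
#' @param XtX,s_vec,N outputs of [accumulate_gram()].
#' @return gene x gene centered scatter matrix.
#' @export
centered_covariance <- function(XtX, s_vec, N) {
  if (N == 0) stop("empty input: N = 0")
  if (N < 2) stop("need at least 2 cells")
  m <- s_vec / N
  S <- XtX - outer(m, s_vec) - outer(s_vec, m) + N * outer(m, m)
  (S + t(S)) / 2
}

#' Top-d eigendecomposition of the centered scatter
#'
#' @param scatter symmetric gene x gene matrix.
#' @param d number of components (1 <= d <= n_genes).
#' @return list with `components` (gene x d orthonormal, sign-corrected) and
#'   `eigvals` (length d, non-increasing).
#' @export
eigendecompose <- function(scatter, d) {
  M <- nrow(scatter)
  if (d < 1 || d > M) stop("config error: d must be in [1, n_genes]")
  eg <- eigen(scatter, symmetric = TRUE)
  comps <- enforce_sign_convention(eg$vectors[, seq_len(d), drop = FALSE])
  list(components = comps, eigvals = eg$values[seq_len(d)])
}

#' Deterministic eigenvector orientation
#'
#' Flips each column so its largest-magnitude entry is positive (ties broken
#' by the lowest index). Idempotent; removes the sign ambiguity of
#' eigendecomposition so repeated fits are bit-identical.
#'
#' @param components matrix whose columns are eigenvectors.
#' @return the sign-corrected matrix.
#' @export
enforce_sign_convention <- function(components) {
  for (i in seq_len(ncol(components))) {
    v <- components[, i]
    if (all(v == 0)) stop("degenerate component: all-zero eigenvector")
    k <- which.max(abs(v))  # which.max returns the first maximum: lowest index
    if (v[k] < 0) components[, i] <- -v
  }
  components
}

#' Fit a PCA model over a chunked store
#'
#' One pass accumulates the Gram matrix (and, when `scale = TRUE`, reuses the
#' per-gene moments to standardize); the centered scatter is then
#' eigendecomposed. With scaling, each gene is treated as
#' `Z = (X - mu) / (sigma + eps)`; since standardization is a per-gene affine
#' map, the scaled scatter is `D^-1 S D^-1` with `D = diag(sigma + eps)` and
#' no extra pass is needed.
#'
#' @param store a `ChunkedMatrix` of normalized values restricted to HVGs.
#' @param d number of components (default 50).
#' @param scale standardize genes to unit variance before projection
#'   (default `FALSE`: centering only).
#' @param eps ridge constant added to sigma to avoid division by zero.
#' @return an object of class `PCAModel`: `m` (gene means), `components`,
#'   `eigvals`, `d`, `scaled`, `eps`, `sigma` (per-gene sd when scaled),
#'   `gene_ids`.
#' @export
fit_pca <- function(store, d = 50, scale = FALSE, eps = 1e-8) {
  acc <- accumulate_gram(store)
  m <- acc$s_vec / acc$N
  S <- centered_covariance(acc$XtX, acc$s_vec, acc$N)
  sigma <- NULL
  if (scale) {
    # per-gene sd from the same accumulators (sample variance, N-1 divisor)
    v <- pmax(diag(S) / (acc$N - 1), 0)
    sigma <- sqrt(v)
    inv <- 1 / (sigma + eps)
    S <- S * outer(inv, inv)
  }
  eg <- eigendecompose(S, d)
  structure(list(m = m, s_vec = acc$s_vec, components = eg$components,
                 eigvals = eg$eigvals, d = d, scaled = scale, eps = eps,
                 sigma = sigma, gene_ids = store$gene_ids),
            class = "PCAModel")
}

#' Project a chunked store onto PCA components
#'
#' Per chunk, rows are centered (and standardized when the model was fitted
#' with scaling) and multiplied by the loading matrix; the centering is
#' applied as a rank-one correction so the sparse block is never densified.
#'
#' @param store a `ChunkedMatrix` on the same gene set used for fitting.
#' @param model a `PCAModel`.
#' @return dense cells x d embedding matrix.
#' @export
pca_transform <- function(store, model) {
  if (store$n_genes != length(model$m) ||
      !identical(store$gene_ids, model$gene_ids)) {
    stop("dimension error: gene set does not match the fitted model")
  }
  V <- model$components
  if (model$scaled) {
    inv <- 1 / (model$sigma + model$eps)
    Vs <- V * inv            # fold the per-gene scaling into the loadings
    offset <- as.numeric((model$m * inv) %*% V)
  } else {
    Vs <- V
    offset <- as.numeric(model$m %*% V)
  }
  out <- matrix(0, store$n_cells, model$d)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    rows <- row_range(store$chunk_bounds, k)
    if (length(rows) == 0) next
    proj <- as.matrix(b %*% Vs)
    out[rows, ] <- sweep(proj, 2, offset, "-")
  }
  out
}
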