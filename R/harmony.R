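# Memory-lean Harmony batch correction.
#
# Harmony alternates diversity-penalized soft k-means on a cosine-normalized
# embedding with per-cluster mixture-of-experts ridge regressions whose batch
# coefficients are subtracted from the embedding. The memory pressure points
# at scale are the B x N design matrices: here the one-hot design Phi, the
# intercept-augmented Phi_moe and the soft-assignment-scaled Phi_Rk are all
# kept sparse (nnz ~ N or 2N), and the MoE solve evaluates
#   W_k = (Phi_Rk Phi_moe' + diag(lambda))^-1 (Phi_Rk Z_orig')
# with the right-hand factor first, so no dense B x N intermediate is ever
# formed. K-means initialization uses a sequential, order-deterministic RNG
# stream so a fixed seed gives bit-identical starting centroids.

#' Sparse one-hot batch design
#'
#' @param batch_labels per-cell batch/sample labels (any atomic type); rows of
#'   the design are ordered by first appearance of each label.
#' @return an object of class `BatchDesign`: `phi` (sparse B x N one-hot),
#'   `phi_moe` (sparse (B+1) x N with an all-ones intercept row prepended) and
#'   `batch_names`.
#' @export
build_batch_design <- function(batch_labels) {
  if (length(batch_labels) == 0) stop("invalid input: no batch labels")
  if (any(is.na(batch_labels))) stop("invalid input: missing batch labels")
  N <- length(batch_labels)
  batch_names <- unique(batch_labels)
  B <- length(batch_names)
  row <- match(batch_labels, batch_names)
  phi <- Matrix::sparseMatrix(i = row, j = seq_len(N), x = 1, dims = c(B, N))
  phi_moe <- rbind(Matrix::sparseMatrix(i = rep(1L, N), j = seq_len(N), x = 1,
                                        dims = c(1L, N)),
                   phi)
  structure(list(phi = as_dgc(phi), phi_moe = as_dgc(phi_moe),
                 batch_names = batch_names),
            class = "BatchDesign")
}

#' Deterministic k-means centroid initialization
#'
#' k-means++ seeding drawn from a sequential RNG stream (bit-reproducible for
#' a fixed seed), optionally followed by Lloyd refinement. `one_step` runs the
#' package's own Lloyd loop; `two_step` seeds identically and hands the Lloyd
#' refinement to a pluggable backend (the extension point for accelerated
#' implementations; the default backend is the same Lloyd loop, so the two
#' modes coincide in this build).
#'
#' @param Z d x N matrix of points (columns are observations).
#' @param K number of centroids (K <= N).
#' @param seed integer seed for the sequential stream.
#' @param mode `"two_step"` (default) or `"one_step"`.
#' @param lloyd_backend for `two_step`: `function(Z, Y0)` returning refined
#'   d x K centroids.
#' @param iter_max Lloyd iteration cap.
#' @return d x K centroid matrix.
#' @export
init_centroids_deterministic <- function(Z, K, seed = 0,
                                         mode = c("two_step", "one_step"),
                                         lloyd_backend = NULL, iter_max = 25) {
  mode <- match.arg(mode)
  N <- ncol(Z)
  if (K > N) stop("config error: K > N")
  Y0 <- with_seed(seed, kmeanspp_seed(Z, K))
  if (K == N) return(Y0)
  if (mode == "one_step" || is.null(lloyd_backend)) {
    lloyd(Z, Y0, iter_max)
  } else {
    lloyd_backend(Z, Y0)
  }
}

# Sequential k-means++ seeding; assumes the caller fixed the RNG state.
kmeanspp_seed <- function(Z, K) {
  N <- ncol(Z)
  chosen <- integer(K)
  chosen[1] <- sample.int(N, 1)
  d2 <- colSums((Z - Z[, chosen[1]])^2)
  if (K > 1) {
    for (k in 2:K) {
      if (sum(d2) <= 0) {
        remaining <- setdiff(seq_len(N), chosen[seq_len(k - 1)])
        chosen[k] <- remaining[sample.int(length(remaining), 1)]
      } else {
        chosen[k] <- sample.int(N, 1, prob = d2)
      }
      d2 <- pmin(d2, colSums((Z - Z[, chosen[k]])^2))
    }
  }
  Z[, chosen, drop = FALSE]
}

# Deterministic Lloyd refinement; assignment ties break at the lowest
# centroid index, empty clusters keep their previous centroid.
lloyd <- function(Z, Y, iter_max = 25) {
  assign_prev <- NULL
  for (it in seq_len(iter_max)) {
    d2 <- outer(colSums(Y^2), rep(1, ncol(Z))) - 2 * crossprod(Y, Z)
    assign <- apply(d2, 2, which.min)
    if (identical(assign, assign_prev)) break
    for (k in seq_len(ncol(Y))) {
      members <- assign == k
      if (any(members)) Y[, k] <- rowMeans(Z[, members, drop = FALSE])
    }
    assign_prev <- assign
  }
  Y
}

l2_normalize_cols <- function(X) {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  sweep(X, 2, nrm, "/")
}

new_harmony_state <- function(Z_orig, design, theta, sigma, lambda, K, seed, init,
                              block_size = 0.05) {
  N <- ncol(Z_orig)
  B <- nrow(design$phi)
  Z_cos <- l2_normalize_cols(Z_orig)
  Y <- l2_normalize_cols(init_centroids_deterministic(Z_cos, K, seed, mode = init))
  Pr_b <- Matrix::rowSums(design$phi) / N
  dist <- 2 * (1 - crossprod(Y, Z_cos))
  R <- exp(sweep(-dist / sigma, 2, apply(-dist / sigma, 2, max), "-"))
  R <- sweep(R, 2, colSums(R), "/")
  O <- as.matrix(R %*% Matrix::t(design$phi))
  E <- outer(rowSums(R), Pr_b)
  structure(list(Z_orig = Z_orig, Z_corr = Z_orig, Z_cos = Z_cos,
                 R = R, Y = Y, O = O, E = E, Pr_b = Pr_b,
                 sigma = sigma, theta = rep_len(theta, B),
                 lam = c(0, rep_len(lambda, B)),
                 dist = dist, K = K, seed = seed, block_size = block_size),
            class = "HarmonyState")
}

harmony_objective <- function(state, design) {
  kmeans_error <- sum(state$R * state$dist)
  safe_ent <- state$R * log(pmax(state$R, .Machine$double.xmin))
  entropy <- sum(safe_ent) * state$sigma
  z <- log((state$O + 1) / (state$E + 1))         # K x B
  w <- (sweep(z, 2, state$theta, "*")) %*% design$phi  # K x N, within budget
  cross_entropy <- sum(state$R * state$sigma * as.matrix(w))
  kmeans_error + entropy + cross_entropy
}

#' One soft-clustering update (centroids and assignments)
#'
#' Refits and re-normalizes the centroids from the current soft assignments,
#' then updates R under the entropy temperature `sigma` and the batch-
#' diversity penalty `((E+1)/(O+1))^theta` (reference Harmony semantics). R is
#' updated in randomly ordered blocks of `state$block_size * N` cells with the
#' batch-composition bookkeeping matrices E and O maintained incrementally --
#' the block-coordinate scheme the objective's convergence relies on
#' (`block_size = 1` gives the plain full-batch update). Columns of R always
#' renormalize to 1.
#'
#' @param state a `HarmonyState`.
#' @param design a `BatchDesign`.
#' @return the updated state.
#' @export
cluster_step <- function(state, design) {
  if (state$sigma <= 0) stop("config error: sigma must be > 0")
  state$Y <- l2_normalize_cols(as.matrix(state$Z_cos %*% t(state$R)))
  state$dist <- 2 * (1 - crossprod(state$Y, state$Z_cos))
  N <- ncol(state$R)
  logS <- -state$dist / state$sigma
  S <- exp(sweep(logS, 2, apply(logS, 2, max), "-"))
  order_all <- sample.int(N)
  n_blocks <- max(1L, min(ceiling(1 / state$block_size), N))
  blocks <- split(order_all, rep(seq_len(n_blocks),
                                 each = ceiling(N / n_blocks),
                                 length.out = N))
  theta_mat <- matrix(state$theta, state$K, length(state$theta), byrow = TRUE)
  for (b in blocks) {
    phi_b <- design$phi[, b, drop = FALSE]
    # take block cells out of the bookkeeping
    state$E <- state$E - outer(rowSums(state$R[, b, drop = FALSE]), state$Pr_b)
    state$O <- state$O - as.matrix(state$R[, b, drop = FALSE] %*% Matrix::t(phi_b))
    # re-assign the block under the current diversity penalty
    pen <- ((state$E + 1) / (state$O + 1))^theta_mat
    Rb <- S[, b, drop = FALSE] * as.matrix(pen %*% phi_b)
    Rb <- sweep(Rb, 2, colSums(Rb), "/")
    state$R[, b] <- Rb
    # put them back
    state$E <- state$E + outer(rowSums(Rb), state$Pr_b)
    state$O <- state$O + as.matrix(Rb %*% Matrix::t(phi_b))
  }
  state
}

#' One mixture-of-experts ridge correction
#'
#' For every cluster k, scales the sparse intercept-augmented design by the
#' soft assignments (`Phi_Rk`, still sparse), solves the ridge system with the
#' `Phi_Rk Z_orig'` product evaluated first (associativity ordering: no
#' B x N dense intermediate), zeroes the intercept row of `W_k`, and subtracts
#' the batch terms from the embedding.
#'
#' @param state a `HarmonyState`.
#' @param design a `BatchDesign`.
#' @return the updated state with new `Z_corr` and `Z_cos`; the per-cluster
#'   `W` coefficients of the final step are stored in `state$W` (a list).
#' @export
moe_correct_step <- function(state, design) {
  if (any(state$lam[-1] <= 0)) stop("ridge too small: lambda must be > 0 on batch rows")
  Z_corr <- state$Z_orig
  phi_moe <- design$phi_moe
  W_list <- vector("list", state$K)
  for (k in seq_len(state$K)) {
    r <- state$R[k, ]
    if (sum(r) < 1e-10) {                                  # empty cluster
      W_list[[k]] <- matrix(0, nrow(phi_moe), nrow(state$Z_orig))
      next
    }
    Phi_Rk <- phi_moe %*% Matrix::Diagonal(x = r)          # sparse, nnz ~ 2N
    A <- as.matrix(Phi_Rk %*% Matrix::t(phi_moe)) + diag(state$lam)
    rhs <- as.matrix(Phi_Rk %*% t(state$Z_orig))           # (B+1) x d, first
    W <- solve(A, rhs)
    W[1, ] <- 0                                            # keep the intercept
    W_list[[k]] <- W
    Z_corr <- Z_corr - as.matrix(t(W) %*% Phi_Rk)
  }
  state$W <- W_list
  state$Z_corr <- Z_corr
  state$Z_cos <- l2_normalize_cols(Z_corr)
  state
}

#' Run Harmony batch correction on an embedding
#'
#' @param Z cells x d embedding (e.g. from [pca_transform()]).
#' @param batch_labels per-cell batch labels.
#' @param theta diversity penalty (scalar, broadcast over batches; default 2).
#' @param sigma soft k-means entropy temperature (default 0.1).
#' @param lambda ridge penalty on batch rows (default 1; the intercept row is
#'   never penalized).
#' @param K number of soft clusters; default `min(100, round(N / 30))`.
#' @param max_iter outer iterations (default 10).
#' @param max_iter_cluster inner clustering iterations per outer round
#'   (default 20).
#' @param tol relative objective-change tolerance for convergence (default
#'   1e-4).
#' @param seed seed for the deterministic centroid initialization.
#' @param init `"two_step"` (default) or `"one_step"`, see
#'   [init_centroids_deterministic()].
#' @return an object of class `HarmonyResult`: `embedding` (corrected cells x
#'   d matrix), `R`, `Y`, `objective` (trace), `iterations`, `design`.
#' @export
run_harmony <- function(Z, batch_labels, theta = 2, sigma = 0.1, lambda = 1,
                        K = NULL, max_iter = 10, max_iter_cluster = 20,
                        tol = 1e-4, seed = 0, init = c("two_step", "one_step"),
                        block_size = 0.05) {
  init <- match.arg(init)
  if (any(!is.finite(Z))) stop("invalid input: non-finite embedding")
  if (length(batch_labels) != nrow(Z)) stop("batch_labels length != nrow(Z)")
  N <- nrow(Z)
  if (is.null(K)) K <- max(2L, min(100L, as.integer(round(N / 30))))
  design <- build_batch_design(batch_labels)
  state <- new_harmony_state(t(Z), design, theta, sigma, lambda, K, seed, init,
                             block_size = block_size)
  obj_trace <- harmony_objective(state, design)
  outer <- 0L
  with_seed(derive_seed(seed, "harmony_blocks"), {
    for (outer in seq_len(max_iter)) {
      obj_in <- obj_trace[length(obj_trace)]
      prev <- obj_in
      for (inner in seq_len(max_iter_cluster)) {
        state <- cluster_step(state, design)
        obj <- harmony_objective(state, design)
        if (abs(prev - obj) < 1e-5 * abs(prev)) { prev <- obj; break }
        prev <- obj
      }
      state <- moe_correct_step(state, design)
      state <- cluster_distances_refresh(state)
      obj_out <- harmony_objective(state, design)
      obj_trace <- c(obj_trace, obj_out)
      if (abs(obj_in - obj_out) < tol * abs(obj_in)) break
    }
  })
  structure(list(embedding = t(state$Z_corr), R = state$R, Y = state$Y,
                 W = state$W, objective = obj_trace, iterations = outer,
                 design = design, K = K),
            class = "HarmonyResult")
}

cluster_distances_refresh <- function(state) {
  state$dist <- 2 * (1 - crossprod(state$Y, state$Z_cos))
  state
}

#' @method print HarmonyResult
#' @export
print.HarmonyResult <- function(x, ...) {
  cat(sprintf("HarmonyResult: %d cells x %d dims, %d batches, K=%d, %d outer iteration(s)\n",
              nrow(x$embedding), ncol(x$embedding),
              length(x$design$batch_names), x$K, x$iterations))
  invisible(x)
}
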