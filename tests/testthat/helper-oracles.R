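# Independent reference implementations used as oracles. Each is a dense,
# direct transcription of the corresponding definition, sharing no code with
# the chunked implementations it checks.

# Dense Seurat-v3 HVG oracle: moments, local quadratic trend, clipped
# standardized variance, all on a dense matrix in one shot.
dense_hvg_oracle <- function(X, n_top, span = 0.3, clip = c("sqrt_n", "n")) {
  clip <- match.arg(clip)
  X <- as.matrix(X)
  N <- nrow(X)
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)  # sample variance, N-1
  use <- mu > 0 & v > 0
  fitted_sd <- numeric(ncol(X))
  fitted_sd[use] <- sqrt(10^local_quadratic_oracle(log10(mu[use]), log10(v[use]),
                                                   log10(mu[use]), span))
  clip_value <- if (clip == "sqrt_n") sqrt(N) else N
  norm_var <- vapply(seq_len(ncol(X)), function(j) {
    if (fitted_sd[j] == 0) return(0)
    xp <- pmin((X[, j] - mu[j]) / fitted_sd[j], clip_value)
    stats::var(xp)
  }, numeric(1))
  ord <- order(-norm_var, seq_along(norm_var))
  is_hvg <- seq_along(norm_var) %in% ord[seq_len(min(n_top, length(norm_var)))]
  list(mu = mu, var = v, fitted_sd = fitted_sd, norm_var = norm_var,
       is_hvg = is_hvg)
}

# Hand-rolled local weighted quadratic regression with tricube weights over
# the span-nearest points -- the definition LOESS (direct surface) computes.
local_quadratic_oracle <- function(x, y, x0, span) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x0, function(p) {
    d <- abs(x - p)
    idx <- order(d)[seq_len(q)]
    dmax <- max(d[idx])
    w <- (1 - (d[idx] / dmax)^3)^3
    xi <- x[idx] - p
    Xd <- cbind(1, xi, xi^2)
    fit <- stats::lm.wfit(Xd, y[idx], w)
    fit$coefficients[1]
  }, numeric(1))
}

# Exhaustive all-pairs kNN oracle, ties by lower index.
brute_knn_oracle <- function(X, k) {
  N <- nrow(X)
  D <- as.matrix(stats::dist(X))
  indices <- matrix(0L, N, k)
  distances <- matrix(0, N, k)
  for (i in seq_len(N)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(N))[seq_len(k)]
    indices[i, ] <- ord
    distances[i, ] <- d[ord]
  }
  list(indices = indices, distances = distances)
}

# Dense, left-to-right (unoptimized order) MoE ridge oracle for one cluster:
# builds the dense designs and multiplies (A^-1 PhiRk) first -- exactly the
# B x N intermediate the sparse path avoids.
dense_moe_oracle <- function(Z_orig, phi_dense, r, lam) {
  phi_moe <- rbind(1, phi_dense)
  Phi_Rk <- sweep(phi_moe, 2, r, "*")
  A <- Phi_Rk %*% t(phi_moe) + diag(lam)
  left <- solve(A) %*% Phi_Rk           # dense (B+1) x N intermediate
  W <- left %*% t(Z_orig)
  W[1, ] <- 0
  list(W = W, correction = t(W) %*% Phi_Rk)
}

# Mean silhouette width against given labels (Euclidean), small-n direct form.
mean_silhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
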