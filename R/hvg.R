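# Seurat-v3 highly variable gene selection, streamed in exactly two passes.
#
# Pass 1 accumulates per-gene running sums s and s2 over chunks and converts
# them to means and sample variances (N-1 divisor; swapping in the population
# variance changes downstream selection, so the divisor is pinned by tests).
# A LOESS trend of log10 variance on log10 mean yields a fitted standard
# deviation per gene. Pass 2 standardizes every entry by (x - mu) / sd_fit,
# clips at an upper bound, and recomputes the variance of the clipped values
# with the same streaming recurrences. The N - nnz implicit zeros of each gene
# all standardize to the same value -mu/sd_fit, so their contribution is added
# analytically and the pass never densifies.

#' Pass 1: streaming per-gene moments of raw counts
#'
#' @param store a `ChunkedMatrix` of raw counts (post-QC).
#' @return an object of class `GeneMoments`: `s`, `s2` (running sums over all
#'   chunks), `mu`, `var` (sample variance, N-1 divisor) and `n_cells`.
#' @export
pass1_moments <- function(store) {
  N <- store$n_cells
  if (N < 2) stop("variance undefined: need at least 2 cells")
  s <- numeric(store$n_genes)
  s2 <- numeric(store$n_genes)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    s <- s + Matrix::colSums(b)
    b2 <- b
    b2@x <- b2@x^2
    s2 <- s2 + Matrix::colSums(b2)
  }
  mu <- s / N
  v <- N / (N - 1) * (s2 / N - mu^2)
  v <- pmax(v, 0)  # guard tiny negative rounding for constant genes
  structure(list(s = s, s2 = s2, mu = mu, var = v, n_cells = N),
            class = "GeneMoments")
}

#' Fit the mean-variance trend
#'
#' LOESS of log10 variance on log10 mean (degree 2, exact "direct" surface so
#' the fit is a pure local weighted quadratic regression, reproducible against
#' an independent implementation). Only genes with positive mean and positive
#' variance enter the fit; genes with zero mean or zero variance get
#' `fitted_sd = 0` and are excluded from selection downstream.
#'
#' @param mu,var per-gene means and sample variances from [pass1_moments()].
#' @param span LOESS span fraction (default 0.3, the Seurat-v3 convention).
#' @return per-gene fitted standard deviation `sqrt(10^fit)`.
#' @export
fit_trend <- function(mu, var, span = 0.3) {
  stopifnot(length(mu) == length(var))
  use <- mu > 0 & var > 0
  fitted_sd <- numeric(length(mu))
  if (sum(use) < 3) stop("fit error: fewer than 3 genes with positive mean and variance")
  x <- log10(mu[use])
  y <- log10(var[use])
  if (diff(range(x)) < 1e-12) {
    # degenerate: all genes share one mean; the local fit is the plain mean
    fitted_sd[use] <- sqrt(10^mean(y))
    return(fitted_sd)
  }
  fit <- stats::loess(y ~ x, span = span, degree = 2, family = "gaussian",
                      surface = "direct")
  fitted_sd[use] <- sqrt(10^stats::predict(fit, x))
  fitted_sd
}

#' Pass 2: variance of clipped standardized counts
#'
#' Standardizes each raw count as `x' = min((x - mu)/sd_fit, clip_value)` over
#' all N cells of every gene -- implicit zeros standardize to
#' `min(-mu/sd_fit, clip_value)` and are accumulated in closed form -- then
#' returns the per-gene sample variance of x'. One pass over chunks; genes
#' with `fitted_sd = 0` get `norm_var = 0` (with a warning when such a gene is
#' not constant).
#'
#' @param store a `ChunkedMatrix` of raw counts (same one as pass 1).
#' @param mu per-gene raw means.
#' @param fitted_sd per-gene trend-fitted standard deviations.
#' @param clip_value upper clip bound for standardized values.
#' @return per-gene `norm_var`.
#' @export
pass2_normalized_variance <- function(store, mu, fitted_sd, clip_value) {
  if (clip_value <= 0) stop("config error: clip_value must be > 0")
  N <- store$n_cells
  M <- store$n_genes
  ok <- fitted_sd > 0
  sd_safe <- ifelse(ok, fitted_sd, 1)
  sum1 <- numeric(M)
  sum2 <- numeric(M)
  nnz <- numeric(M)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    j <- rep.int(seq_len(M), diff(b@p))  # column of each stored value
    xp <- pmin((b@x - mu[j]) / sd_safe[j], clip_value)
    bs <- b; bs@x <- xp
    sum1 <- sum1 + Matrix::colSums(bs)
    bs@x <- xp^2
    sum2 <- sum2 + Matrix::colSums(bs)
    nnz <- nnz + diff(b@p)
  }
  z0 <- pmin(-mu / sd_safe, clip_value)     # standardized value of an implicit zero
  n0 <- N - nnz
  sum1 <- sum1 + n0 * z0
  sum2 <- sum2 + n0 * z0^2
  mean_x <- sum1 / N
  norm_var <- N / (N - 1) * (sum2 / N - mean_x^2)
  norm_var <- pmax(norm_var, 0)
  norm_var[!ok] <- 0
  bad <- !ok & (store_gene_nonconstant(store, mu))
  if (any(bad)) {
    warning(sum(bad), " non-constant gene(s) with zero fitted sd excluded from HVG")
  }
  norm_var
}

# Cheap non-constancy check used only for the zero-fitted-sd warning.
store_gene_nonconstant <- function(store, mu) {
  # a gene is constant iff all N values equal mu; for count data that means
  # either mu == 0 with no stored values, or every cell stores the value mu.
  nz_count <- numeric(store$n_genes)
  all_eq_mu <- rep(TRUE, store$n_genes)
  for (k in seq_len(n_chunks(store))) {
    b <- get_chunk(store, k)
    j <- rep.int(seq_len(store$n_genes), diff(b@p))
    nz_count <- nz_count + tabulate(j, nbins = store$n_genes)
    neq <- j[abs(b@x - mu[j]) > 1e-12]
    if (length(neq)) all_eq_mu[unique(neq)] <- FALSE
  }
  constant <- (nz_count == 0 & mu == 0) | (nz_count == store$n_cells & all_eq_mu)
  !constant
}

#' Rank genes and flag the top K as highly variable
#'
#' @param norm_var per-gene normalized variances from pass 2.
#' @param K number of genes to flag; ties at the boundary are broken by lower
#'   gene index; if `K > n_genes` all genes are flagged.
#' @return an object of class `HVGResult`: `norm_var`, `rank` (dense rank by
#'   decreasing `norm_var`, ties by index) and logical `is_hvg`.
#' @export
select_hvgs <- function(norm_var, K) {
  if (K < 1) stop("K must be >= 1")
  ord <- order(-norm_var, seq_along(norm_var))
  rank <- integer(length(norm_var))
  rank[ord] <- seq_along(norm_var)
  is_hvg <- rank <= min(K, length(norm_var))
  structure(list(norm_var = norm_var, rank = rank, is_hvg = is_hvg,
                 K = min(K, length(norm_var))),
            class = "HVGResult")
}

#' Full highly variable gene selection over a chunked store
#'
#' Runs the two streaming passes plus the trend fit: moments, LOESS trend,
#' clipped standardized variance, top-K flagging.
#'
#' @param store a `ChunkedMatrix` of raw counts (post-QC).
#' @param n_top number of genes to flag (default 2000).
#' @param span LOESS span.
#' @param clip `"sqrt_n"` (default; clip standardized values at sqrt(N)) or
#'   `"n"` (clip at N).
#' @return an `HVGResult` additionally carrying `mu`, `var`, `fitted_sd` and
#'   `clip_value`.
#' @export
find_hvgs <- function(store, n_top = 2000, span = 0.3, clip = c("sqrt_n", "n")) {
  clip <- match.arg(clip)
  mom <- pass1_moments(store)
  fitted_sd <- fit_trend(mom$mu, mom$var, span = span)
  clip_value <- if (clip == "sqrt_n") sqrt(store$n_cells) else store$n_cells
  norm_var <- pass2_normalized_variance(store, mom$mu, fitted_sd, clip_value)
  res <- select_hvgs(norm_var, n_top)
  res$mu <- mom$mu
  res$var <- mom$var
  res$fitted_sd <- fitted_sd
  res$clip_value <- clip_value
  res
}
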