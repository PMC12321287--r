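# Synthetic chunked count data with planted structure.
#
# Counts are negative binomial: per-gene baseline means are log-normal across
# genes, each cluster's planted markers have their mean multiplied by a fold
# change inside that cluster, and batches act as per-gene multiplicative
# log-normal factors on the means before sampling. Everything is keyed by a
# single seed, so identical specs give bit-identical matrices.

#' Specify a synthetic dataset
#'
#' Defaults emulate a desk-scale study: 10k cells in 7 equally sized planted
#' clusters across 4 batches, 5 exclusive markers per cluster at 8x fold
#' change, negative binomial counts at ~90% sparsity.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param K_clusters,B_batches planted cluster and batch counts.
#' @param cluster_props cluster proportions (default equal; must sum to 1).
#' @param markers_per_cluster exclusive marker genes per cluster.
#' @param marker_fold_change in-cluster mean multiplier for markers.
#' @param nb_mean median per-gene baseline NB mean (log-normal across genes,
#'   `sdlog = gene_sdlog`).
#' @param marker_nb_mean median baseline mean of marker genes (markers emulate
#'   strongly expressed canonical cell-type genes, in the spirit of real
#'   markers whose elevated expression distinguishes clusters;
#'   `sdlog = 0.25`).
#' @param gene_sdlog spread of baseline means across genes.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param batch_effect_scale sdlog of the per-gene per-batch multiplicative
#'   log-normal factor (0 disables batch effects).
#' @param seed RNG seed.
#' @return an object of class `SimSpec`.
#' @export
sim_spec <- function(n_cells = 10000, n_genes = 2000, K_clusters = 7,
                     B_batches = 4, cluster_props = NULL,
                     markers_per_cluster = 5, marker_fold_change = 8,
                     nb_mean = 0.1, marker_nb_mean = 1, gene_sdlog = 1.2,
                     nb_dispersion = 0.5, batch_effect_scale = 0.1, seed = 0) {
  if (is.null(cluster_props)) cluster_props <- rep(1 / K_clusters, K_clusters)
  if (abs(sum(cluster_props) - 1) > 1e-8) stop("cluster_props must sum to 1")
  if (K_clusters * markers_per_cluster > n_genes) stop("more markers than genes")
  structure(list(n_cells = n_cells, n_genes = n_genes, K_clusters = K_clusters,
                 B_batches = B_batches, cluster_props = cluster_props,
                 markers_per_cluster = markers_per_cluster,
                 marker_fold_change = marker_fold_change,
                 nb_mean = nb_mean, marker_nb_mean = marker_nb_mean,
                 gene_sdlog = gene_sdlog, nb_dispersion = nb_dispersion,
                 batch_effect_scale = batch_effect_scale, seed = seed),
            class = "SimSpec")
}

#' Simulate a chunked count matrix with planted structure
#'
#' @param spec a [sim_spec()].
#' @param plan optional `ChunkPlan`; `NULL` plans automatically.
#' @param max_nnz chunk nnz cap for automatic planning.
#' @param mode storage backend for the returned store.
#' @return list with `store` (`ChunkedMatrix`, batch labels attached),
#'   `clusters` (per-cell planted cluster, 1..K), `batches` (per-cell batch),
#'   `markers` (named list: planted marker genes per cluster) and `spec`.
#' @export
simulate_counts <- function(spec, plan = NULL, max_nnz = INT32_CAP,
                            mode = "host") {
  with_seed(spec$seed, {
    G <- spec$n_genes; N <- spec$n_cells
    K <- spec$K_clusters; B <- spec$B_batches
    gene_ids <- sprintf("gene_%04d", seq_len(G))
    base_mu <- stats::rlnorm(G, meanlog = log(spec$nb_mean), sdlog = spec$gene_sdlog)
    marker_idx <- matrix(sample.int(G, K * spec$markers_per_cluster),
                         nrow = K, byrow = TRUE)
    base_mu[as.vector(marker_idx)] <-
      stats::rlnorm(K * spec$markers_per_cluster,
                    meanlog = log(spec$marker_nb_mean), sdlog = 0.25)
    # per-cluster mean profiles
    mu_cluster <- matrix(base_mu, G, K)
    for (c in seq_len(K)) {
      mu_cluster[marker_idx[c, ], c] <- base_mu[marker_idx[c, ]] * spec$marker_fold_change
    }
    batch_factor <- if (spec$batch_effect_scale > 0) {
      matrix(stats::rlnorm(G * B, 0, spec$batch_effect_scale), G, B)
    } else {
      matrix(1, G, B)
    }
    clusters <- sample(rep(seq_len(K), times = round(spec$cluster_props * N))[seq_len(N)])
    clusters[is.na(clusters)] <- K
    batches <- sample(rep_len(seq_len(B), N))
    size <- 1 / spec$nb_dispersion
    trip_i <- list(); trip_j <- list(); trip_x <- list(); t_idx <- 0
    for (c in seq_len(K)) {
      for (b in seq_len(B)) {
        cells <- which(clusters == c & batches == b)
        if (length(cells) == 0) next
        mu <- mu_cluster[, c] * batch_factor[, b]
        draws <- stats::rnbinom(length(cells) * G, mu = rep(mu, times = length(cells)),
                                size = size)
        nz <- which(draws > 0)
        t_idx <- t_idx + 1
        trip_i[[t_idx]] <- cells[((nz - 1) %/% G) + 1]
        trip_j[[t_idx]] <- ((nz - 1) %% G) + 1
        trip_x[[t_idx]] <- draws[nz]
      }
    }
    x <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = as.numeric(unlist(trip_x)), dims = c(N, G))
    colnames(x) <- gene_ids
    rownames(x) <- sprintf("cell_%06d", seq_len(N))
    batch_labels <- sprintf("batch_%d", batches)
    store <- as_chunked(x, plan = plan, max_nnz = max_nnz, mode = mode,
                        batch = batch_labels)
    markers <- stats::setNames(
      lapply(seq_len(K), function(c) gene_ids[marker_idx[c, ]]),
      sprintf("cluster_%d", seq_len(K)))
    list(store = store, clusters = clusters, batches = batch_labels,
         markers = markers, spec = spec)
  })
}

#' Expand a dataset by resampling cluster expression profiles
#'
#' Per cluster, per-gene negative binomial parameters are fit from the
#' empirical mean and variance (method of moments; genes with variance <=
#' mean fall back to Poisson), then `replication` new cells are drawn per
#' original cell. Output is the original data plus the simulated copies, with
#' batch ids suffixed per replicate; the chunk plan is re-validated against
#' the cap.
#'
#' @param store a `ChunkedMatrix` of raw counts.
#' @param clusters per-cell cluster labels.
#' @param replication number of simulated copies (>= 1).
#' @param seed RNG seed.
#' @param max_nnz chunk cap for the expanded store.
#' @return list with `store`, `clusters`, `batches`.
#' @export
expand_dataset <- function(store, clusters, replication = 9, seed = 0,
                           max_nnz = INT32_CAP) {
  stopifnot(length(clusters) == store$n_cells, replication >= 1)
  X <- as_matrix(store)
  G <- ncol(X)
  cl <- sort(unique(clusters))
  with_seed(seed, {
    blocks <- list(X)
    labs <- list(clusters)
    batches <- list(store$batch %||% rep("orig", nrow(X)))
    for (c in cl) {
      members <- which(clusters == c)
      if (length(members) < 2) {
        warning("cluster ", c, " has < 2 cells; skipped in expansion")
        next
      }
      sub <- X[members, , drop = FALSE]
      mu <- Matrix::colMeans(sub)
      ex2 <- Matrix::colMeans(sub^2)
      v <- pmax(ex2 - mu^2, 0) * length(members) / (length(members) - 1)
      size <- ifelse(v > mu & mu > 0, mu^2 / (v - mu), Inf)
      n_new <- length(members) * replication
      draws <- matrix(0, n_new, G)
      pois <- !is.finite(size)
      if (any(pois)) {
        draws[, pois] <- stats::rpois(n_new * sum(pois),
                                      lambda = rep(mu[pois], each = n_new))
      }
      if (any(!pois)) {
        draws[, !pois] <- stats::rnbinom(n_new * sum(!pois),
                                         mu = rep(mu[!pois], each = n_new),
                                         size = rep(size[!pois], each = n_new))
      }
      blocks[[length(blocks) + 1]] <- as_dgc(Matrix::Matrix(draws, sparse = TRUE))
      labs[[length(labs) + 1]] <- rep(c, n_new)
      batches[[length(batches) + 1]] <-
        paste0(rep(store$batch[members] %||% rep("orig", length(members)),
                   times = replication),
               "_rep", rep(seq_len(replication), each = length(members)))
    }
    all_x <- do.call(rbind, blocks)
    colnames(all_x) <- store$gene_ids
    batch_all <- unlist(batches)
    new_store <- as_chunked(all_x, max_nnz = max_nnz, mode = store$storage_mode,
                            gene_ids = store$gene_ids, batch = batch_all)
    list(store = new_store, clusters = unlist(labs), batches = batch_all)
  })
}
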