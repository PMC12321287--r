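# Marker gene identification, NSForest-style on gradient-boosted trees.
#
# Per cluster, a one-vs-rest gradient-boosted tree ensemble (sparse-native
# input) ranks genes by total gain; candidates are filtered by a binary
# expression specificity score, and each cluster's final marker set is graded
# by the F_beta of a simple all-genes-above-threshold decision rule (the
# "decision tree F score" used downstream by cluster merging).

marker_defaults <- list(nrounds = 100, max_depth = 6, eta = 0.3,
                        n_candidates = 30, min_binary = 0.1, beta = 0.5,
                        min_cells = 10)

# Sparse cells x genes matrix from a store or a matrix-like input.
marker_matrix <- function(X) {
  if (inherits(X, "ChunkedMatrix")) X <- as_matrix(X)
  X <- as_dgc(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("gene_%d", seq_len(ncol(X)))
  X
}

#' Rank candidate marker genes for one cluster
#'
#' Fits a one-vs-rest binary gradient-boosted tree classifier on the sparse
#' expression matrix and ranks genes by total gain importance. Deterministic
#' for a fixed seed (single-threaded training).
#'
#' @param X normalized expression (`ChunkedMatrix` or sparse cells x genes).
#' @param labels per-cell cluster labels.
#' @param cluster_id the positive cluster.
#' @param n_candidates genes to return (default 30).
#' @param nrounds,max_depth,eta boosting parameters (defaults 100, 6, 0.3).
#' @param seed RNG seed handed to the booster.
#' @param min_cells minimum positive-cluster size (default 10).
#' @return data.frame `gene`, `importance` (gain, descending).
#' @export
rank_candidates <- function(X, labels, cluster_id,
                            n_candidates = marker_defaults$n_candidates,
                            nrounds = marker_defaults$nrounds,
                            max_depth = marker_defaults$max_depth,
                            eta = marker_defaults$eta,
                            seed = 0, min_cells = marker_defaults$min_cells) {
  X <- marker_matrix(X)
  if (length(unique(labels)) < 2) stop("single-class labels")
  y <- as.numeric(labels == cluster_id)
  if (sum(y) < min_cells) stop("cluster has fewer than ", min_cells, " cells")
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  out <- data.frame(gene = imp$Feature, importance = imp$Gain,
                    stringsAsFactors = FALSE)
  utils::head(out[order(-out$importance), , drop = FALSE], n_candidates)
}

#' Per-gene per-cluster expressing fractions
#'
#' Fraction of cells with value > 0, accumulated in a single streaming pass
#' over chunks (exactly chunk invariant).
#'
#' @param X `ChunkedMatrix` or sparse cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @return clusters x genes matrix of fractions, rownames = cluster ids.
#' @export
expressing_fractions <- function(X, labels) {
  cl <- sort(unique(labels))
  if (inherits(X, "ChunkedMatrix")) {
    counts <- matrix(0, length(cl), X$n_genes,
                     dimnames = list(as.character(cl), X$gene_ids))
    for (k in seq_len(n_chunks(X))) {
      b <- get_chunk(X, k)
      rows <- row_range(X$chunk_bounds, k)
      nz <- b
      nz@x <- rep(1, length(nz@x))
      lab_chunk <- labels[rows]
      for (c in cl) {
        sel <- lab_chunk == c
        if (any(sel)) {
          counts[as.character(c), ] <- counts[as.character(c), ] +
            Matrix::colSums(nz[sel, , drop = FALSE])
        }
      }
    }
    sizes <- as.numeric(table(factor(labels, levels = cl)))
    counts / sizes
  } else {
    X <- marker_matrix(X)
    nz <- X
    nz@x <- rep(1, length(nz@x))
    frac <- matrix(0, length(cl), ncol(X),
                   dimnames = list(as.character(cl), colnames(X)))
    for (idx in seq_along(cl)) {
      sel <- labels == cl[idx]
      frac[idx, ] <- Matrix::colSums(nz[sel, , drop = FALSE]) / sum(sel)
    }
    frac
  }
}

#' Binary expression specificity score
#'
#' `score = (fraction of positive-cluster cells expressing the gene) *
#' (1 - median over other clusters of their expressing fractions)`, clipped to
#' \[0, 1\]. A fully penetrant, perfectly exclusive marker scores 1.
#'
#' @param X expression matrix or `ChunkedMatrix` (used when `fractions` is
#'   not supplied).
#' @param labels per-cell cluster labels.
#' @param cluster_id positive cluster.
#' @param gene gene identifier.
#' @param fractions optional precomputed [expressing_fractions()] matrix.
#' @return scalar score in \[0, 1\].
#' @export
binary_score <- function(X, labels, cluster_id, gene, fractions = NULL) {
  if (is.null(fractions)) fractions <- expressing_fractions(X, labels)
  if (!gene %in% colnames(fractions)) stop("gene not in universe: ", gene)
  cid <- as.character(cluster_id)
  pos <- fractions[cid, gene]
  others <- fractions[setdiff(rownames(fractions), cid), gene]
  med <- if (length(others)) stats::median(others) else 0
  min(max(pos * (1 - med), 0), 1)
}

# Decision-tree split threshold for one gene (single stump on cluster
# membership); falls back to "expressing" (> 0) when no split improves purity.
stump_threshold <- function(values, positive) {
  df <- data.frame(y = factor(positive), x = values)
  fit <- rpart::rpart(y ~ x, data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                     minsplit = 2, minbucket = 1,
                                                     xval = 0))
  if (is.null(fit$splits) || nrow(fit$splits) == 0) return(0)
  unname(fit$splits[1, "index"])
}

#' Marker-set quality (decision-tree F score)
#'
#' Predicts cluster membership by the conjunction rule "every marker gene
#' exceeds its fitted single-tree split threshold" and returns the F_beta of
#' that rule against true membership. Beta defaults to 0.5 (precision-
#' weighted), the NSForest convention.
#'
#' @param X expression matrix or `ChunkedMatrix`.
#' @param labels per-cell cluster labels.
#' @param cluster_id positive cluster.
#' @param genes marker genes G_i (non-empty).
#' @param beta F-score weight.
#' @return scalar S_i in \[0, 1\].
#' @export
cluster_f_score <- function(X, labels, cluster_id, genes, beta = marker_defaults$beta) {
  if (length(genes) == 0) stop("empty marker set")
  X <- marker_matrix(X)
  positive <- labels == cluster_id
  pred <- rep(TRUE, nrow(X))
  for (g in genes) {
    thr <- stump_threshold(X[, g], positive)
    pred <- pred & (X[, g] > thr)
  }
  tp <- sum(pred & positive)
  precision <- if (sum(pred) == 0) 0 else tp / sum(pred)
  recall <- if (sum(positive) == 0) 0 else tp / sum(positive)
  f_beta(precision, recall, beta)
}

#' Identify marker genes for all clusters
#'
#' Per cluster: gradient-boosted ranking, binary-score filtering
#' (`>= min_binary`), top-m selection by importance, and the decision-tree
#' F score S_i of the selected set. Expressing fractions are accumulated
#' chunk-wise in one pass.
#'
#' @param X normalized expression (`ChunkedMatrix` or sparse cells x genes).
#' @param labels per-cell cluster labels (>= 2 clusters).
#' @param m markers per cluster (default 5).
#' @param n_candidates,min_binary,beta,nrounds,max_depth,eta,min_cells see
#'   [rank_candidates()] / [binary_score()] / [cluster_f_score()].
#' @param seed RNG seed.
#' @return an object of class `MarkerSet`: `markers` (named list of per-
#'   cluster data.frames with gene, importance, binary_score), `S` (named
#'   quality scores), `m`, and `fractions`.
#' @export
find_markers <- function(X, labels, m = 5,
                         n_candidates = marker_defaults$n_candidates,
                         min_binary = marker_defaults$min_binary,
                         beta = marker_defaults$beta,
                         nrounds = marker_defaults$nrounds,
                         max_depth = marker_defaults$max_depth,
                         eta = marker_defaults$eta,
                         min_cells = marker_defaults$min_cells,
                         seed = 0) {
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters")
  Xm <- marker_matrix(X)
  fractions <- expressing_fractions(X, labels)
  markers <- list()
  S <- stats::setNames(numeric(length(cl)), as.character(cl))
  for (c in cl) {
    cand <- rank_candidates(Xm, labels, c, n_candidates = n_candidates,
                            nrounds = nrounds, max_depth = max_depth,
                            eta = eta, seed = seed, min_cells = min_cells)
    cand$binary_score <- vapply(cand$gene, function(g) {
      binary_score(NULL, labels, c, g, fractions = fractions)
    }, numeric(1))
    keep <- cand[cand$binary_score >= min_binary, , drop = FALSE]
    # composite final ranking: gain importance x binary specificity. Gain alone
    # admits noise genes the booster used to split off a sister cluster of the
    # same type; specificity alone drops a strong marker whose baseline
    # expression dilutes its binary score. The product requires both.
    sel <- utils::head(keep[order(-(keep$importance * keep$binary_score)), ,
                            drop = FALSE], m)
    markers[[as.character(c)]] <- sel
    S[as.character(c)] <- if (nrow(sel) > 0) {
      cluster_f_score(Xm, labels, c, sel$gene, beta = beta)
    } else 0
  }
  structure(list(markers = markers, S = S, m = m, fractions = fractions),
            class = "MarkerSet")
}

#' Marker gene sets as a named list of character vectors
#' @param marker_set a `MarkerSet`.
#' @export
marker_genes <- function(marker_set) {
  lapply(marker_set$markers, function(df) df$gene)
}

#' Dot-plot summary table for markers
#'
#' Per (cluster, gene): mean expression scaled to 0-1 across clusters and the
#' fraction of expressing cells -- the standard dot-plot display quantities.
#'
#' @param X expression matrix or `ChunkedMatrix`.
#' @param labels per-cell cluster labels.
#' @param marker_set a `MarkerSet`.
#' @return data.frame with cluster, gene, mean_scaled, frac_expressing.
#' @export
marker_dotplot_table <- function(X, labels, marker_set) {
  Xm <- marker_matrix(X)
  genes <- unique(unlist(marker_genes(marker_set)))
  cl <- sort(unique(labels))
  means <- t(vapply(cl, function(c) {
    Matrix::colMeans(Xm[labels == c, genes, drop = FALSE])
  }, numeric(length(genes))))
  rng <- apply(means, 2, function(v) {
    if (diff(range(v)) == 0) rep(0, length(v)) else (v - min(v)) / diff(range(v))
  })
  frac <- marker_set$fractions[, genes, drop = FALSE]
  expand <- expand.grid(cluster = as.character(cl), gene = genes,
                        stringsAsFactors = FALSE)
  expand$mean_scaled <- mapply(function(c, g) rng[match(c, as.character(cl)), g],
                               expand$cluster, expand$gene)
  expand$frac_expressing <- mapply(function(c, g) frac[c, g],
                                   expand$cluster, expand$gene)
  expand
}
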