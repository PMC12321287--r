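# Small planted-marker fixture shared by the marker tests: K clusters, each
# with `mpc` exclusive markers at high fold change over a noisy background.
planted_marker_data <- function(n = 600, g = 60, K = 3, mpc = 2, seed = 41,
                                fold = 16, background = 0.15) {
  set.seed(seed)
  labels <- sample(rep(seq_len(K), length.out = n))
  mu <- matrix(background, g, K)
  markers <- lapply(seq_len(K), function(c) {
    idx <- ((c - 1) * mpc + 1):(c * mpc)
    mu[idx, c] <<- 0.5 * fold
    idx
  })
  X <- t(vapply(seq_len(n), function(i) {
    rnbinom(g, mu = mu[, labels[i]], size = 2)
  }, numeric(g)))
  Xs <- Matrix::Matrix(log1p(X), sparse = TRUE)
  colnames(Xs) <- sprintf("g%03d", seq_len(g))
  list(X = chunkcell:::as_dgc(Xs), labels = labels,
       markers = lapply(markers, function(i) sprintf("g%03d", i)))
}

test_that("rank_candidates puts a planted exclusive marker first", {
  set.seed(42)
  n <- 500; g <- 40
  labels <- rep(1:2, length.out = n)
  X <- matrix(rnbinom(n * g, mu = 0.5, size = 2), n, g)
  X[labels == 1, 7] <- rnbinom(sum(labels == 1), mu = 5, size = 2)
  X[labels == 2, 7] <- 0
  Xs <- Matrix::Matrix(log1p(X), sparse = TRUE)
  colnames(Xs) <- sprintf("g%03d", 1:g)
  ranked <- rank_candidates(Xs, labels, 1, seed = 1)
  expect_equal(ranked$gene[1], "g007")

  # permuting cell order leaves the ranking unchanged
  perm <- sample(n)
  ranked_p <- rank_candidates(Xs[perm, ], labels[perm], 1, seed = 1)
  expect_equal(ranked$gene, ranked_p$gene)

  expect_error(rank_candidates(Xs, rep(1, n), 1), "single-class")
  expect_error(rank_candidates(Xs[1:30, ], c(1, rep(2, 29)), 1),
               "fewer than")
})

test_that("null data shows no spurious importance concentration", {
  set.seed(43)
  n <- 800; g <- 100
  labels <- rep(1:2, length.out = n)
  X <- Matrix::Matrix(log1p(matrix(rnbinom(n * g, mu = 1, size = 2), n, g)),
                      sparse = TRUE)
  colnames(X) <- sprintf("g%03d", 1:g)
  ranked <- rank_candidates(X, labels, 1, n_candidates = g, seed = 1)
  top1_share <- ranked$importance[1] / sum(ranked$importance)
  expect_lt(top1_share, 3 / nrow(ranked))
})

test_that("binary_score follows the penetrance x specificity formula", {
  # 3 clusters x 1 gene with known expressing fractions
  labels <- rep(1:3, each = 10)
  vals <- c(rep(1, 8), rep(0, 2),   # cluster 1: 0.8 expressing
            rep(1, 5), rep(0, 5),   # cluster 2: 0.5
            rep(0, 10))             # cluster 3: 0.0
  X <- Matrix::Matrix(matrix(vals, 30, 1), sparse = TRUE)
  colnames(X) <- "g1"
  # median other fraction for cluster 1 is median(0.5, 0) = 0.25
  expect_equal(binary_score(X, labels, 1, "g1"), 0.8 * (1 - 0.25))

  # perfect marker scores 1, absent gene scores 0
  Xp <- Matrix::Matrix(matrix(c(rep(1, 10), rep(0, 20), rep(0, 30)), 30, 2),
                       sparse = TRUE)
  colnames(Xp) <- c("gA", "gB")
  expect_equal(binary_score(Xp, labels, 1, "gA"), 1)
  expect_equal(binary_score(Xp, labels, 1, "gB"), 0)
})

test_that("expressing fractions accumulate chunk-invariantly", {
  d <- planted_marker_data()
  st1 <- store_with_chunks(d$X, 1)
  st4 <- store_with_chunks(d$X, 4)
  f1 <- expressing_fractions(st1, d$labels)
  f4 <- expressing_fractions(st4, d$labels)
  fd <- expressing_fractions(d$X, d$labels)
  expect_identical(f1, f4)
  expect_equal(f1, fd, tolerance = 1e-15)
})

test_that("cluster F score grades threshold rules as F_beta", {
  # crafted precision 0.8, recall 0.5 at beta 0.5 -> 0.714286
  labels <- c(rep("pos", 8), rep("neg", 92))
  vals <- c(rep(5, 4), rep(0, 4),   # 4 of 8 positives express
            5, rep(0, 91))          # 1 negative expresses
  X <- Matrix::Matrix(matrix(vals, 100, 1), sparse = TRUE)
  colnames(X) <- "g1"
  expect_equal(cluster_f_score(X, labels, "pos", "g1", beta = 0.5),
               (1.25 * 0.8 * 0.5) / (0.25 * 0.8 + 0.5), tolerance = 1e-12)

  # perfect marker, perfectly separable cluster
  Xp <- Matrix::Matrix(matrix(c(rep(3, 8), rep(0, 92)), 100, 1), sparse = TRUE)
  colnames(Xp) <- "g1"
  expect_equal(cluster_f_score(Xp, labels, "pos", "g1"), 1.0)

  # a rule that predicts nobody scores 0
  Xn <- Matrix::Matrix(matrix(0, 100, 1), sparse = TRUE)
  colnames(Xn) <- "g1"
  expect_equal(cluster_f_score(Xn, labels, "pos", "g1"), 0)

  expect_error(cluster_f_score(Xp, labels, "pos", character(0)), "empty")
})

test_that("find_markers recovers planted markers with high quality scores", {
  d <- planted_marker_data()
  ms <- find_markers(d$X, d$labels, m = 2, nrounds = 50, seed = 1)
  for (c in 1:3) {
    expect_setequal(ms$markers[[as.character(c)]]$gene, d$markers[[c]])
    expect_gte(ms$S[[as.character(c)]], 0.9)
  }

  # m larger than surviving candidates: shorter sets, no error
  ms_big <- find_markers(d$X, d$labels, m = 50, nrounds = 20,
                         min_binary = 0.5, seed = 1)
  expect_true(all(vapply(ms_big$markers, nrow, integer(1)) <= 50))

  # renaming clusters permutes the MarkerSet identically
  renamed <- c("z", "a", "m")[d$labels]
  ms_r <- find_markers(d$X, renamed, m = 2, nrounds = 50, seed = 1)
  expect_setequal(ms_r$markers[["z"]]$gene, ms$markers[["1"]]$gene)
  expect_equal(unname(ms_r$S["m"]), unname(ms$S["3"]))

  expect_error(find_markers(d$X, rep(1, nrow(d$X))), "at least 2")
})

test_that("dot-plot table reports scaled means and expressing fractions", {
  d <- planted_marker_data()
  ms <- find_markers(d$X, d$labels, m = 2, nrounds = 30, seed = 1)
  tab <- marker_dotplot_table(d$X, d$labels, ms)
  expect_true(all(tab$mean_scaled >= 0 & tab$mean_scaled <= 1))
  expect_true(all(tab$frac_expressing >= 0 & tab$frac_expressing <= 1))
  # a cluster's own marker has the maximal scaled mean in its column
  g <- ms$markers[["1"]]$gene[1]
  sub <- tab[tab$gene == g, ]
  expect_equal(sub$cluster[which.max(sub$mean_scaled)], "1")
})
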