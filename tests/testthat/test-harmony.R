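test_that("batch design is one-hot, sparse and ordered by first appearance", {
  d <- build_batch_design(c("a", "a", "b"))
  expect_equal(as.matrix(d$phi), matrix(c(1, 0, 1, 0, 0, 1), 2),
               ignore_attr = TRUE)
  expect_equal(length(d$phi@x), 3)
  expect_equal(d$batch_names, c("a", "b"))
  expect_true(all(d$phi_moe[1, ] == 1))

  # single batch: all-ones 1 x N row
  d1 <- build_batch_design(rep("s1", 7))
  expect_equal(dim(d1$phi), c(1L, 7L))
  expect_true(all(as.matrix(d1$phi) == 1))

  # one-hot property on many random labels
  set.seed(23)
  labs <- sample(letters[1:12], 1000, replace = TRUE)
  dd <- build_batch_design(labs)
  expect_true(all(Matrix::colSums(dd$phi) == 1))
  expect_equal(length(dd$phi@x), 1000)

  expect_error(build_batch_design(c("a", NA)), "invalid input")
})

test_that("centroid initialization is deterministic and complete at K = N", {
  set.seed(24)
  Z <- matrix(rnorm(5 * 60), 5)
  y1 <- init_centroids_deterministic(Z, 8, seed = 4)
  y2 <- init_centroids_deterministic(Z, 8, seed = 4)
  expect_identical(y1, y2)
  expect_false(identical(y1, init_centroids_deterministic(Z, 8, seed = 5)))

  # K = N: every point becomes a centroid (in some order)
  yk <- init_centroids_deterministic(Z[, 1:10], 10, seed = 1)
  expect_equal(dim(yk), c(5L, 10L))
  expect_setequal(apply(round(yk, 10), 2, paste, collapse = ","),
                  apply(round(Z[, 1:10], 10), 2, paste, collapse = ","))

  expect_error(init_centroids_deterministic(Z, 100, seed = 1), "config error")
})

test_that("one_step and a pluggable two_step backend agree on separated blobs", {
  blobs <- make_blobs(40, centers = rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3,
                      seed = 25)
  Z <- t(blobs$X)
  y1 <- init_centroids_deterministic(Z, 3, seed = 2, mode = "one_step")
  kmeans_backend <- function(Zb, Y0) {
    unname(t(stats::kmeans(t(Zb), centers = t(Y0), iter.max = 50,
                           algorithm = "Lloyd")$centers))
  }
  y2 <- init_centroids_deterministic(Z, 3, seed = 2, mode = "two_step",
                                     lloyd_backend = kmeans_backend)
  # both reach the unique local optimum of a well-separated mixture
  expect_equal(y1[, order(y1[1, ])], y2[, order(y2[1, ])], tolerance = 1e-8)
})

test_that("cluster_step has the hard-assignment limit and normalizes R", {
  # two directions on the sphere, theta 0, tiny sigma: R approaches hard
  # nearest-centroid assignment (distances are cosine-based)
  Z <- matrix(c(1, 0, 0.99, 0.14, 0, 1, 0.14, 0.99), 2)
  st <- chunkcell:::new_harmony_state(Z, build_batch_design(rep("b", 4)),
                                      theta = 0, sigma = 1e-3, lambda = 1,
                                      K = 2, seed = 1, init = "two_step",
                                      block_size = 1)
  st <- cluster_step(st, build_batch_design(rep("b", 4)))
  hard <- apply(st$R, 2, which.max)
  expect_equal(hard[1], hard[2])
  expect_equal(hard[3], hard[4])
  expect_false(hard[1] == hard[3])
  expect_true(all(pmax(st$R[cbind(hard, 1:4)], 0) > 1 - 1e-6))

  # identical cells get identical assignment columns
  set.seed(26)
  Zi <- matrix(rnorm(3 * 30), 3)
  Zi[, 2] <- Zi[, 1]
  design <- build_batch_design(rep("b", 30))
  sti <- chunkcell:::new_harmony_state(Zi, design, 2, 0.1, 1, 4, 1, "two_step",
                                       block_size = 1)
  sti <- cluster_step(sti, design)
  expect_equal(sti$R[, 1], sti$R[, 2], tolerance = 1e-12)
  expect_equal(colSums(sti$R), rep(1, 30), tolerance = 1e-9)

  sti$sigma <- 0
  expect_error(cluster_step(sti, design), "config error")
})

test_that("sparse MoE solve equals the dense left-to-right oracle", {
  set.seed(27)
  B <- 5; N <- 400; d <- 10; K <- 3
  Z <- matrix(rnorm(d * N), d)
  labs <- sample(paste0("b", 1:B), N, replace = TRUE)
  design <- build_batch_design(labs)
  st <- chunkcell:::new_harmony_state(Z, design, 2, 0.1, 1, K, 1, "two_step")
  st <- cluster_step(st, design)
  st2 <- moe_correct_step(st, design)

  phi_dense <- as.matrix(design$phi)
  Z_oracle <- Z
  for (k in seq_len(K)) {
    oc <- dense_moe_oracle(Z, phi_dense, st$R[k, ], st$lam)
    expect_equal(unname(st2$W[[k]]), unname(oc$W), tolerance = 1e-8)
    Z_oracle <- Z_oracle - oc$correction
  }
  expect_equal(st2$Z_corr, Z_oracle, tolerance = 1e-8)

  # structural sparsity: the B x N objects stay sparse with nnz ~ N
  expect_s4_class(design$phi, "dgCMatrix")
  expect_s4_class(design$phi_moe, "dgCMatrix")
  expect_lte(length(design$phi_moe@x), 2 * N)

  # a cluster with zero responsibility contributes no correction
  st$R[2, ] <- 0
  st3 <- moe_correct_step(st, design)
  expect_equal(unname(st3$W[[2]]), matrix(0, B + 1, d))
})

test_that("run_harmony removes a planted batch shift without collapsing clusters", {
  set.seed(28)
  centers <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  blobs <- make_blobs(80, centers, sd = 0.5, seed = 28)
  N <- nrow(blobs$X)
  batch <- rep(c("b1", "b2"), length.out = N)
  shift <- matrix(c(2, 2, 0), N, 3, byrow = TRUE) * (batch == "b2")
  Z <- blobs$X + shift

  res <- run_harmony(Z, batch, seed = 3)
  before <- sqrt(sum((colMeans(Z[batch == "b1", ]) -
                      colMeans(Z[batch == "b2", ]))^2))
  after <- sqrt(sum((colMeans(res$embedding[batch == "b1", ]) -
                     colMeans(res$embedding[batch == "b2", ]))^2))
  expect_lte(after, 0.1 * before)

  sil_before <- mean_silhouette(blobs$X, blobs$labels)  # without batch shift
  sil_after <- mean_silhouette(res$embedding, blobs$labels)
  expect_gte(sil_after, 0.9 * sil_before)

  # determinism: same seed, same output
  res2 <- run_harmony(Z, batch, seed = 3)
  expect_equal(res$embedding, res2$embedding, tolerance = 1e-10)
})

test_that("a single batch passes through essentially unchanged", {
  set.seed(29)
  Z <- matrix(rnorm(100 * 5), 100)
  res <- run_harmony(Z, rep("only", 100), seed = 1)
  expect_equal(res$embedding, Z, tolerance = 1e-6)

  expect_error(run_harmony(matrix(c(1, NA), 1), c("a"), seed = 1),
               "invalid input")
})
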