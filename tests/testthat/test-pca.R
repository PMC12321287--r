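test_that("gram accumulation is exact and chunk associative", {
  z <- as_chunked(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0), dims = c(4, 3)))
  expect_true(all(accumulate_gram(z)$XtX == 0))

  x <- Matrix::Matrix(matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE),
                      sparse = TRUE)
  acc <- accumulate_gram(as_chunked(x))
  expect_equal(acc$XtX, matrix(c(2, 1, 1, 2), 2))
  expect_equal(acc$s_vec, c(2, 2))

  y <- random_counts(60, 20, density = 0.2, seed = 14)
  a1 <- accumulate_gram(store_with_chunks(y, 1))
  a3 <- accumulate_gram(store_with_chunks(y, 3))
  expect_equal(a1$XtX, a3$XtX, tolerance = 1e-12)
})

test_that("centering identity equals the dense centered cross-product", {
  # rows all equal to the mean: centering kills everything
  x <- Matrix::Matrix(matrix(rep(c(1, 2), each = 4), 4), sparse = TRUE)
  acc <- accumulate_gram(as_chunked(x))
  expect_equal(centered_covariance(acc$XtX, acc$s_vec, acc$N),
               matrix(0, 2, 2), tolerance = 1e-12)

  # hand-applied identity on the 3x2 example
  x2 <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  acc2 <- accumulate_gram(as_chunked(Matrix::Matrix(x2, sparse = TRUE)))
  S <- centered_covariance(acc2$XtX, acc2$s_vec, acc2$N)
  expect_equal(S, matrix(c(2 / 3, -1 / 3, -1 / 3, 2 / 3), 2), tolerance = 1e-12)

  # dense oracle on a 200x50 random matrix
  y <- as.matrix(random_counts(200, 50, density = 0.2, seed = 15))
  acc3 <- accumulate_gram(as_chunked(Matrix::Matrix(y, sparse = TRUE)))
  S3 <- centered_covariance(acc3$XtX, acc3$s_vec, acc3$N)
  yc <- scale(y, center = TRUE, scale = FALSE)
  expect_equal(S3, unname(crossprod(yc)), tolerance = 1e-8)
  expect_equal(S3, t(S3))

  expect_error(centered_covariance(matrix(0, 2, 2), c(0, 0), 0), "empty input")
})

test_that("eigendecomposition is ordered, orthonormal and reconstructive", {
  eg <- eigendecompose(diag(c(4, 1)), 2)
  expect_equal(eg$eigvals, c(4, 1))
  expect_equal(abs(eg$components), diag(2), tolerance = 1e-12)

  # isotropic scatter: all eigenvalues equal
  expect_equal(eigendecompose(3 * diag(4), 4)$eigvals, rep(3, 4))

  # reconstruction on a full-rank toy
  set.seed(16)
  A <- crossprod(matrix(rnorm(36), 6))
  eg2 <- eigendecompose(A, 6)
  expect_equal(eg2$components %*% diag(eg2$eigvals) %*% t(eg2$components),
               A, tolerance = 1e-6)
  expect_equal(crossprod(eg2$components), diag(6), tolerance = 1e-8)

  expect_error(eigendecompose(diag(2), 3), "config error")
})

test_that("sign convention fixes orientation and is idempotent", {
  expect_equal(enforce_sign_convention(matrix(c(0.1, -0.9), 2)),
               matrix(c(-0.1, 0.9), 2))
  expect_equal(enforce_sign_convention(matrix(c(0.9, 0.1), 2)),
               matrix(c(0.9, 0.1), 2))

  set.seed(17)
  V <- matrix(rnorm(200), 2)  # 100 random vectors as columns
  once <- enforce_sign_convention(V)
  expect_identical(enforce_sign_convention(once), once)
  expect_true(all(apply(once, 2, function(v) v[which.max(abs(v))] > 0)))

  expect_error(enforce_sign_convention(matrix(0, 2, 1)), "degenerate")
})

test_that("chunked PCA matches dense PCA and is deterministic", {
  y <- as.matrix(random_counts(200, 50, density = 0.2, seed = 18))
  store5 <- store_with_chunks(Matrix::Matrix(y, sparse = TRUE), 5)
  model <- fit_pca(store5, d = 10)
  emb <- pca_transform(store5, model)

  # repeated fits are bit-identical (sign determinism)
  model2 <- fit_pca(store5, d = 10)
  expect_identical(model$components, model2$components)

  # chunk invariance of the embedding
  store1 <- store_with_chunks(Matrix::Matrix(y, sparse = TRUE), 1)
  emb1 <- pca_transform(store1, fit_pca(store1, d = 10))
  expect_equal(emb, emb1, tolerance = 1e-10)

  # dense oracle: prcomp scores after the same sign convention
  pr <- stats::prcomp(y, center = TRUE, scale. = FALSE)
  rot <- enforce_sign_convention(pr$rotation[, 1:10])
  scores <- scale(y, center = TRUE, scale = FALSE) %*% rot
  expect_equal(emb, unname(scores), tolerance = 1e-6)

  # projecting the mean row gives the zero vector
  mean_row <- Matrix::Matrix(matrix(colMeans(y), 1), sparse = TRUE)
  mstore <- as_chunked(rbind(mean_row, mean_row), gene_ids = model$gene_ids)
  expect_equal(pca_transform(mstore, model), matrix(0, 2, 10),
               tolerance = 1e-10)

  # variance conservation: full-spectrum eigvals sum to the scatter trace
  acc <- accumulate_gram(store5)
  S <- centered_covariance(acc$XtX, acc$s_vec, acc$N)
  expect_equal(sum(eigendecompose(S, 50)$eigvals), sum(diag(S)),
               tolerance = 1e-8)
})

test_that("scaled PCA standardizes genes before projection", {
  y <- as.matrix(random_counts(150, 30, density = 0.3, seed = 19))
  store <- as_chunked(Matrix::Matrix(y, sparse = TRUE))
  model <- fit_pca(store, d = 5, scale = TRUE)
  emb <- pca_transform(store, model)
  # dense oracle on standardized data (same sigma + eps convention)
  sd_vec <- apply(y, 2, sd)
  Z <- sweep(sweep(y, 2, colMeans(y)), 2, sd_vec + 1e-8, "/")
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- enforce_sign_convention(pr$rotation[, 1:5])
  expect_equal(abs(emb), abs(unname(Z %*% rot)), tolerance = 1e-6)

  # gene-set mismatch is a dimension error
  other <- as_chunked(Matrix::Matrix(y[, 1:10], sparse = TRUE))
  expect_error(pca_transform(other, model), "dimension error")
})
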