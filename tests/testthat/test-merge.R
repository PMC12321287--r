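test_that("quality labeling thresholds S at t_C with >= boundary", {
  expect_equal(unname(label_quality(c(a = 0.9, b = 0.2), 0.5)),
               c("high", "low"))
  expect_true(all(label_quality(c(a = 0, b = 1), 0) == "high"))
  # boundary: S == t_C counts as high
  expect_equal(unname(label_quality(c(a = 0.5), 0.5)), "high")
  expect_error(label_quality(c(a = 1.2), 0.5))
})

test_that("candidate pairs use overlap fractions in either direction", {
  sets <- list(A = paste0("g", 1:5), B = paste0("g", 1:5),
               C = paste0("g", 6:10))
  # identical sets pass at t_G = 1; disjoint sets never pass for t_G > 0
  p <- candidate_pairs(sets, t_G = 1)
  expect_equal(nrow(p), 1)
  expect_setequal(c(p$i, p$j), c("A", "B"))

  # 4/5 overlap: included at 0.8, excluded at 1.0
  sets2 <- list(A = paste0("g", 1:5), B = c(paste0("g", 1:4), "g99"))
  expect_equal(nrow(candidate_pairs(sets2, t_G = 0.8)), 1)
  expect_equal(nrow(candidate_pairs(sets2, t_G = 1.0)), 0)

  # asymmetric sizes: |G_i|=2 fully inside |G_j|=5 passes "both" via i-side
  sets3 <- list(A = paste0("g", 1:2), B = paste0("g", 1:5))
  expect_equal(nrow(candidate_pairs(sets3, t_G = 1, direction = "both")), 1)
  expect_equal(nrow(candidate_pairs(sets3, t_G = 1, direction = "forward")), 1)

  expect_warning(candidate_pairs(list(A = character(0), B = "g1"), t_G = 1),
                 "empty")
  expect_error(candidate_pairs(sets, t_G = 1.5), "t_G")
})

test_that("merge plans respect quality exclusivity and transitivity", {
  sizes <- c(A = 100, B = 50, C = 80)
  pairs_ab <- data.frame(i = "A", j = "B", overlap_i = 1, overlap_j = 1)

  # both high: nothing merges
  plan <- build_merge_plan(pairs_ab, c(A = "high", B = "high", C = "high"), sizes)
  expect_equal(unname(plan$relabeling), c("A", "B", "C"))

  # chain (A,B), (B,C) with B low, A and C high: all three merge into A
  chain <- rbind(pairs_ab, data.frame(i = "B", j = "C", overlap_i = 1,
                                      overlap_j = 1))
  plan2 <- build_merge_plan(chain, c(A = "high", B = "low", C = "high"), sizes)
  expect_equal(unname(plan2$relabeling[c("A", "B", "C")]), rep("A", 3))

  # empty candidate set: identity relabeling
  plan3 <- build_merge_plan(candidate_pairs(list(A = "g1", B = "g2"), t_G = 1),
                            c(A = "low", B = "low"), sizes[1:2])
  expect_equal(unname(plan3$relabeling), c("A", "B"))
})

test_that("apply_merge is a pure, idempotent relabeling", {
  # 18 clusters, plan merges {c0, c1, c2, c3} -> 15 distinct labels
  ids <- paste0("c", 0:17)
  S <- setNames(c(rep(0.2, 4), rep(0.9, 14)), ids)
  sizes <- setNames(rep(10, 18), ids); sizes["c0"] <- 40
  sets <- setNames(c(rep(list(paste0("g", 1:5)), 4),
                     lapply(5:18, function(i) paste0("h", i, 1:5))), ids)
  plan <- build_merge_plan(candidate_pairs(sets, t_G = 1),
                           label_quality(S, 0.5), sizes)
  labels <- rep(ids, each = 3)
  merged <- apply_merge(labels, plan)
  expect_equal(length(unique(merged)), 15)
  expect_true(all(merged[labels %in% paste0("c", 0:3)] == "c0"))
  # idempotence and order preservation
  expect_identical(apply_merge(merged, plan), merged)
  expect_identical(merged[labels == "c5"], rep("c5", 3))

  expect_error(apply_merge(c("c0", "zzz"), plan), "unknown label")
})

test_that("lowering t_G merges monotonically more", {
  set.seed(51)
  universe <- paste0("g", 1:40)
  for (rep in 1:10) {
    sets <- setNames(lapply(1:6, function(i) sample(universe, 5)),
                     paste0("c", 1:6))
    p_hi <- candidate_pairs(sets, t_G = 1)
    p_lo <- candidate_pairs(sets, t_G = 0.6)
    key <- function(p) paste(p$i, p$j)
    expect_true(all(key(p_hi) %in% key(p_lo)))

    quality <- setNames(rep("low", 6), names(sets))
    sizes <- setNames(rep(10, 6), names(sets))
    n_hi <- length(unique(build_merge_plan(p_hi, quality, sizes)$relabeling))
    n_lo <- length(unique(build_merge_plan(p_lo, quality, sizes)$relabeling))
    expect_lte(n_lo, n_hi)
  }
})

test_that("merge_clusters recovers a planted over-clustered partition", {
  # 3 true clusters, each split in two; markers identical within true cluster
  truth <- rep(1:3, each = 40)
  sub <- paste0(truth, letters[rep(1:2, 60)])
  sets <- setNames(lapply(sort(unique(sub)), function(s) {
    paste0("marker", substr(s, 1, 1), "_", 1:5)
  }), sort(unique(sub)))
  ms <- structure(list(markers = lapply(sets, function(g) {
    data.frame(gene = g, importance = 1, binary_score = 1)
  }), S = setNames(rep(0.3, 6), names(sets)), m = 5), class = "MarkerSet")
  out <- merge_clusters(sub, ms, t_C = 0.5, t_G = 1)
  expect_equal(adjusted_rand_index(out$labels, truth), 1.0)
})

test_that("adjusted_rand_index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(52)
  for (rep in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})
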