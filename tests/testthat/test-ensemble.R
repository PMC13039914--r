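mk_map <- function(v, h = 2, w = 2) normalize_unit(matrix(v, h, w))

test_that("drop_invalid filters and reports", {
  good <- cam_result("gradcam", mk_map(c(1, 0, 0, 0)))
  bad <- cam_result("fullgrad", NULL, valid = FALSE, reason = "no biases")
  zero <- cam_result("layercam", saliency_map(matrix(0, 2, 2)))
  kept <- drop_invalid(list(good, bad, zero))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$method, "gradcam")
  expect_identical(drop_invalid(list(good, good)), list(good, good))
  expect_error(drop_invalid(list(bad, zero)), "no biases")
})

test_that("mean ensemble averages pixelwise then normalizes", {
  m1 <- saliency_map(matrix(c(1, 0, 0, 0), 2, 2), normalized = TRUE)
  m2 <- saliency_map(matrix(c(0, 0, 0, 1), 2, 2), normalized = TRUE)
  got <- mean_ensemble(list(m1, m2))
  expect_equal(as.matrix(got), matrix(c(1, 0, 0, 1), 2, 2))  # 0.5s rescale to 1
  same <- mean_ensemble(list(m1, m1, m1))
  expect_equal(as.matrix(same), as.matrix(m1))
  expect_error(mean_ensemble(list(m1, saliency_map(matrix(0.5, 3, 3)))),
               "shape")
})

test_that("weight transforms follow their rules", {
  expect_equal(weight_transform(c(0.1, 0.2), "minmax"), c(0, 1))
  expect_equal(weight_transform(c(0.3, 0.3, 0.3), "minmax"), rep(1 / 3, 3))
  for (mode in c("minmax", "softmax_amplified", "exponential"))
    expect_true(all(abs(diff(weight_transform(rep(0.2, 4), mode))) < 1e-12))
  # amplification: smallest power of ten s with max|s*v| >= 10
  v <- c(0.01, 0.02)
  amp <- exp(c(10, 20) - 20); amp <- amp / sum(amp)   # softmax([10, 20])
  expect_equal(weight_transform(v, "softmax_amplified"), amp, tolerance = 1e-12)
  # already-large values are not amplified
  big <- weight_transform(c(10, 20), "softmax_amplified")
  expect_equal(big, amp, tolerance = 1e-12)
  # raw mode shifts negatives up to zero
  expect_equal(weight_transform(c(-0.1, 0.3), "none"), c(0, 0.4))
})

test_that("weighted ensemble matches hand arithmetic and reduces to the mean", {
  m1 <- saliency_map(matrix(c(1, 0, 0.5, 0), 2, 2), normalized = TRUE)
  m2 <- saliency_map(matrix(c(0, 1, 0.5, 0), 2, 2), normalized = TRUE)
  # uniform weights: bit-for-bit equal to the plain mean
  expect_identical(as.matrix(weighted_ensemble(list(m1, m2), c(1, 1))),
                   as.matrix(mean_ensemble(list(m1, m2))))
  # degenerate selection
  expect_equal(as.matrix(weighted_ensemble(list(m1, m2), c(1, 0))),
               as.matrix(normalize_unit(m1)))
  # (1, 3): hand-computed convex combination
  hand <- (1 * as.matrix(m1) + 3 * as.matrix(m2)) / 4
  expect_equal(as.matrix(weighted_ensemble(list(m1, m2), c(1, 3))),
               as.matrix(normalize_unit(hand)))
  expect_error(weighted_ensemble(list(m1, m2), c(0, 0)), "zero")
})

test_that("consensus identities hold", {
  m <- normalize_unit(matrix(c(0.2, 0.8, 0.4, 1, 0, 0.6, 0.1, 0.9, 0.5), 3, 3))
  expect_equal(as.matrix(consensus_metacam(list(m), 100)), as.matrix(m))
  # maps agreeing on one pixel only: small k keeps just the agreement pixel
  a <- saliency_map(matrix(c(1, 0.4, 0, 0), 2, 2), normalized = TRUE)
  b <- saliency_map(matrix(c(1, 0, 0.4, 0), 2, 2), normalized = TRUE)
  cons <- consensus_metacam(list(a, b), 25)
  expect_equal(which(as.matrix(cons) > 0), 1L)
  # adding a constant map shifts the sum uniformly: same surviving set
  cst <- saliency_map(matrix(0.7, 2, 2))
  cons2 <- consensus_metacam(list(a, b, cst), 25)
  expect_equal(which(as.matrix(cons2) > 0), which(as.matrix(cons) > 0))
})

test_that("consensus support shrinks weakly as k decreases", {
  set.seed(23)
  for (trial in 1:20) {
    stack <- lapply(1:4, function(i) normalize_unit(matrix(runif(64), 8, 8)))
    sizes <- vapply(c(90, 60, 30, 10), function(k)
      sum(as.matrix(consensus_metacam(stack, k)) > 0), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("adaptive search is internally consistent and breaks ties low", {
  m <- constant_model(c(0, 1), 8, 8)
  img <- matrix(runif(64), 8, 8)
  stack <- list(normalize_unit(matrix(runif(64), 8, 8)),
                normalize_unit(matrix(runif(64), 8, 8)))
  cfg <- road_config(percentiles = c(30, 60), noise_std = 0)
  res <- adaptive_threshold_search(stack, m, img, 1, k_grid = c(20, 50, 80),
                                   config = cfg)
  # constant model: every score 0, the tie resolves to the smallest k
  expect_true(all(res$scores_by_k$road == 0))
  expect_equal(res$best_k, 20)
  expect_equal(res$best_score, max(res$scores_by_k$road))
  # singleton grid returns its only candidate
  one <- adaptive_threshold_search(stack, m, img, 1, k_grid = 35, config = cfg)
  expect_equal(one$best_k, 35)
  # single-map form thresholds that map directly
  sm <- adaptive_threshold_search(stack[[1]], m, img, 1, k_grid = c(40, 70),
                                  config = cfg)
  expect_equal(as.matrix(sm$best_map),
               as.matrix(normalize_unit(topk_threshold(stack[[1]], 40))))
})

test_that("adaptive best_k attains the maximum of its own table on a real model", {
  model <- fixture_model()
  sc <- gen_scene(501, with_decoy = TRUE)
  img <- array(sc$image, c(64, 64, 1))
  stack <- gen_cam_stack(sc, good_decoy_random_specs(), seed = 7)
  cfg <- road_config(percentiles = c(20, 60), noise_std = 0)
  res <- adaptive_threshold_search(stack, model, img, sc$class_label,
                                   k_grid = c(10, 25, 40, 70), config = cfg)
  expect_equal(res$best_score, max(res$scores_by_k$road))
  expect_equal(res$scores_by_k$road[res$scores_by_k$k == res$best_k],
               res$best_score)
  # the returned map is the consensus at best_k
  expect_equal(as.matrix(res$best_map),
               as.matrix(consensus_metacam(stack, res$best_k)))
})
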