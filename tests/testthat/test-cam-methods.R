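test_that("the registry exposes exactly the 11 methods plus the random baseline", {
  ids <- cam_methods()
  expect_length(ids, 12)
  expect_true(all(c("gradcam", "gradcampp", "xgradcam", "eigengradcam",
                    "hirescam", "gradcam_elementwise", "layercam", "scorecam",
                    "ablationcam", "eigencam", "fullgrad", "randomcam") %in% ids))
})

test_that("channel weights follow their definitions", {
  A <- array(1, c(2, 2, 2))
  G <- array(c(rep(1, 4), rep(1, 4)), c(2, 2, 2))
  expect_equal(channel_weights("gradcam",
                               activation_bundle(A, G)), c(1, 1))
  G2 <- array(c(rep(0.5, 4), rep(-1, 4)), c(2, 2, 2))
  expect_equal(channel_weights("gradcam", activation_bundle(A, G2)),
               c(0.5, -1))
  # epsilon guard: all-zero activation channel gets zero xgradcam weight
  A0 <- A; A0[, , 1] <- 0
  w <- channel_weights("xgradcam", activation_bundle(A0, G2))
  expect_equal(w[1], 0)
})

test_that("elementwise maps follow their ReLU placements", {
  g <- matrix(c(1, 0, -1, 2), 2, 2)
  b <- activation_bundle(array(g, c(2, 2, 1)), array(g, c(2, 2, 1)))
  hand <- matrix(c(1, 0, 1, 4), 2, 2)        # g*g elementwise
  expect_equal(elementwise_map("hirescam", b), hand)
  expect_equal(elementwise_map("gradcam_elementwise", b), hand)
  # two channels whose products cancel: the ReLU placement now matters
  A2 <- array(c(1, 1, 1, 1, 1, 1, 1, 1), c(2, 2, 2))
  G2 <- array(c(2, 2, 2, 2, -1, -1, -1, -1), c(2, 2, 2))
  b2 <- activation_bundle(A2, G2)
  expect_equal(elementwise_map("hirescam", b2), matrix(1, 2, 2))      # 2-1
  expect_equal(elementwise_map("gradcam_elementwise", b2), matrix(2, 2, 2))
  # layercam zeroes negative gradients before weighting
  ballneg <- activation_bundle(array(1, c(2, 2, 1)), array(-1, c(2, 2, 1)))
  expect_equal(elementwise_map("layercam", ballneg), matrix(0, 2, 2))
})

test_that("assemble_cam runs weights -> sum -> ReLU -> normalize by hand", {
  A <- array(c(1, 0, 0, 0, 0, 0, 0, 1), c(2, 2, 2))
  G <- array(c(rep(0.5, 4), rep(-1, 4)), c(2, 2, 2))
  m <- bundle_model(A, G)
  r <- assemble_cam("gradcam", m, matrix(0, 2, 2), "lyr", 1)
  # weighted sum = 0.5*A1 - A2 -> ReLU zeroes the -1 pixel -> normalize
  expect_true(r$valid)
  expect_equal(as.matrix(r$map), matrix(c(1, 0, 0, 0), 2, 2))
})

test_that("all-zero gradients produce an invalid result, not an error", {
  A <- array(1, c(2, 2, 1)); G <- array(0, c(2, 2, 1))
  r <- assemble_cam("gradcam", bundle_model(A, G), matrix(0, 2, 2), "lyr", 1)
  expect_false(r$valid)
  expect_match(r$reason, "zero")
})

test_that("gradcam equals hirescam under spatially constant gradients", {
  set.seed(21)
  A <- array(runif(4 * 4 * 3), c(4, 4, 3))
  G <- array(rep(c(0.7, 0.2, 1.3), each = 16), c(4, 4, 3))
  m <- bundle_model(A, G)
  img <- matrix(0, 4, 4)
  r1 <- assemble_cam("gradcam", m, img, "lyr", 1)
  r2 <- assemble_cam("hirescam", m, img, "lyr", 1)
  expect_equal(as.matrix(r1$map), as.matrix(r2$map), tolerance = 1e-12)
})

test_that("eigen methods agree with a dense SVD oracle", {
  set.seed(31)
  A <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  G <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  b <- activation_bundle(A, G)
  for (method in c("eigencam", "eigengradcam")) {
    X <- if (method == "eigencam") A else G * A
    M <- t(matrix(X, 30, 3))                 # K x (h*w)
    sv <- svd(M)
    proj <- sv$d[1] * sv$v[, 1]
    if (proj[which.max(abs(proj))] < 0) proj <- -proj
    oracle <- as.matrix(normalize_unit(matrix(proj, 6, 5)))
    got <- eigen_cam(method, b, 6, 5)
    expect_true(got$valid)
    expect_equal(as.matrix(got$map), oracle, tolerance = 1e-6)
  }
  # K = 1: output proportional to the single channel
  b1 <- activation_bundle(array(A[, , 1], c(6, 5, 1)),
                          array(1, c(6, 5, 1)))
  r1 <- eigen_cam("eigencam", b1, 6, 5)
  expect_equal(as.matrix(r1$map), as.matrix(normalize_unit(A[, , 1])),
               tolerance = 1e-8)
  # duplicated channels change nothing (rank-1 invariance)
  bdup <- activation_bundle(array(c(A[, , 1], A[, , 1]), c(6, 5, 2)),
                            array(1, c(6, 5, 2)))
  rdup <- eigen_cam("eigencam", bdup, 6, 5)
  expect_equal(as.matrix(rdup$map), as.matrix(r1$map), tolerance = 1e-8)
  # rank-0 input is invalid
  r0 <- eigen_cam("eigencam",
                  activation_bundle(array(0, c(2, 2, 1)),
                                    array(0, c(2, 2, 1))), 2, 2)
  expect_false(r0$valid)
})

test_that("scorecam and ablationcam match naive per-channel loops", {
  model <- fixture_model()
  sc <- gen_scene(301)
  img <- array(sc$image, c(64, 64, 1))
  ci <- sc$class_label
  b <- capture(model, img, "conv2", ci)
  A <- b$feature_maps
  K <- dim(A)[3]
  # naive scorecam: loop over channels, mask input, read raw target score
  raw <- vapply(seq_len(K), function(k) {
    up <- bilinear_oracle(A[, , k], 64, 64)
    rng <- range(up)
    upn <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1]) else up * 0
    model$predict_logits(img * array(upn, c(64, 64, 1)))[ci]
  }, numeric(1))
  w_sc <- exp(raw - max(raw)); w_sc <- w_sc / sum(w_sc)
  naive_sc <- matrix(0, 16, 16)
  for (k in seq_len(K)) naive_sc <- naive_sc + w_sc[k] * A[, , k]
  naive_sc <- as.matrix(normalize_unit(upsample_bilinear(pmax(naive_sc, 0),
                                                       64, 64)))
  got_sc <- perturbation_cam("scorecam", model, img, "conv2", ci)
  expect_true(got_sc$valid)
  expect_equal(as.matrix(got_sc$map), naive_sc, tolerance = 1e-5)
  # naive ablationcam: zero each channel in turn
  y_c <- model$predict_logits(img)[ci]
  w_ab <- vapply(seq_len(K), function(k) {
    scale <- rep(1, K); scale[k] <- 0
    (y_c - model$forward_masked(img, "conv2", scale)[ci]) / y_c
  }, numeric(1))
  naive_ab <- matrix(0, 16, 16)
  for (k in seq_len(K)) naive_ab <- naive_ab + w_ab[k] * A[, , k]
  naive_ab <- as.matrix(normalize_unit(upsample_bilinear(pmax(naive_ab, 0),
                                                       64, 64)))
  got_ab <- perturbation_cam("ablationcam", model, img, "conv2", ci)
  expect_true(got_ab$valid)
  expect_equal(as.matrix(got_ab$map), naive_ab, tolerance = 1e-5)
})

test_that("ablating a channel the score ignores gives weight zero", {
  # a model whose logits depend only on channel 1 of the layer
  h <- 4L
  m <- model_handle(
    class_count = 2,
    input_shape = c(h, h, 1L),
    layers = "lyr",
    predict_logits = function(image) c(sum(image), 0),
    capture_fn = function(image, layer, class_index)
      list(feature_maps = array(c(image[, , 1] + 1, matrix(1, h, h)),
                                c(h, h, 2L)),
           gradients = array(1, c(h, h, 2L))),
    forward_masked = function(image, layer, channel_scale)
      c(sum(image) * channel_scale[1], 0))
  img <- array(runif(h * h) + 0.5, c(h, h, 1))
  r <- perturbation_cam("ablationcam", m, img, "lyr", 1)
  # channel 2 is ignored: its ablation weight must be exactly 0, so the
  # map is channel 1 alone
  b <- m$capture_fn(img, "lyr", 1)
  expected <- as.matrix(normalize_unit(upsample_bilinear(
    pmax(b$feature_maps[, , 1], 0), h, h)))
  expect_equal(as.matrix(r$map), expected, tolerance = 1e-10)
})

test_that("fullgrad reduces to |input x input-gradient| for a bias-free linear model", {
  h <- 4; w <- 4
  W <- list(matrix(seq(-1, 1, length.out = 16), h, w),
            matrix(seq(1, -1, length.out = 16), h, w))
  m <- linear_model(W, h, w)
  img <- matrix(runif(16) + 0.1, h, w)
  r <- fullgrad_map(m, array(img, c(h, w, 1)), 1)
  expect_true(r$valid)
  expect_equal(as.matrix(r$map), as.matrix(normalize_unit(abs(img * W[[1]]))),
               tolerance = 1e-10)
  # a model without bias gradients exposed is gracefully invalid
  m2 <- constant_model(c(1, 2), 4, 4)
  expect_false(fullgrad_map(m2, matrix(0, 4, 4), 1)$valid)
})

test_that("randomcam is seeded, normalized and seed-sensitive", {
  r1 <- random_cam(32, 32, seed = 9)
  r2 <- random_cam(32, 32, seed = 9)
  r3 <- random_cam(32, 32, seed = 10)
  expect_identical(as.matrix(r1$map), as.matrix(r2$map))
  expect_false(identical(as.matrix(r1$map), as.matrix(r3$map)))
  expect_gte(min(r1$map), 0)
  expect_lte(max(r1$map), 1)
})

test_that("every CAM on the fixture model is normalized at image resolution or invalid", {
  model <- fixture_model()
  sc <- gen_scene(302)
  img <- array(sc$image, c(64, 64, 1))
  for (m in cam_methods()) {
    r <- compute_cam(m, model, img, class_index = sc$class_label, seed = 4)
    if (r$valid) {
      expect_identical(dim(r$map), c(64L, 64L))
      expect_gte(min(r$map), 0)
      expect_lte(max(r$map), 1)
    } else {
      expect_true(is.character(r$reason) && nzchar(r$reason))
    }
  }
})
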