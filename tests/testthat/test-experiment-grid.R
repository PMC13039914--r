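test_that("grid enumeration is a bijection with subsets", {
  g6 <- build_grid()
  expect_length(g6$experiments, 64)
  codes <- vapply(g6$experiments, `[[`, character(1), "code")
  expect_false(anyDuplicated(codes) > 0)
  # each group included in exactly half the codes
  for (pos in 1:6)
    expect_equal(sum(substr(codes, pos, pos) == "1"), 32)
  # the all-zero code exists but is unscorable
  zero <- g6$experiments[[which(codes == "000000")]]
  expect_false(zero$scorable)
  expect_length(zero$methods, 0)
  # base case n = 1
  g1 <- build_grid(list(cam_group("X", "gradcam")))
  expect_setequal(vapply(g1$experiments, `[[`, character(1), "code"),
                  c("0", "1"))
  # n <= 8: size and uniqueness by enumeration
  for (n in 2:8) {
    gn <- build_grid(lapply(seq_len(n), function(i)
      cam_group(LETTERS[i], cam_methods()[i])))
    cn <- vapply(gn$experiments, `[[`, character(1), "code")
    expect_length(unique(cn), 2^n)
  }
})

test_that("grid construction validates its groups", {
  expect_error(build_grid(list(cam_group("A", "gradcam"),
                               cam_group("B", "gradcam"))), "disjoint")
  expect_error(build_grid(list(cam_group("A", "gradcam"),
                               cam_group("A", "layercam"))), "unique")
  expect_error(cam_group("Z", "not_a_method"), "unknown")
})

test_that("codes resolve to the union of included groups' methods", {
  g <- build_grid()
  codes <- vapply(g$experiments, `[[`, character(1), "code")
  ex <- g$experiments[[which(codes == "110000")]]
  expect_setequal(ex$methods, c("hirescam", "gradcam_elementwise",
                                "gradcam", "gradcampp"))
  full <- g$experiments[[which(codes == "111111")]]
  expect_length(full$methods, 9)
})

test_that("CRE reproduces the two-group hand example", {
  res <- data.frame(code = c("01", "10", "11"),
                    road = c(0.1, 0.3, 0.2),
                    scorable = TRUE, stringsAsFactors = FALSE)
  rep <- cre(res, labels = c("A", "B"))
  expect_equal(rep$median_score, 0.2)
  expect_equal(unname(rep$cre["A"]), 0.1)    # (0.3-0.2) + (0.2-0.2)
  expect_equal(unname(rep$cre["B"]), -0.1)   # (0.1-0.2) + (0.2-0.2)
  expect_equal(rep$n_scored, 3)
})

test_that("CRE invariances: equal scores, constant shifts, label permutation", {
  codes <- sprintf("%03d", c(1, 10, 11, 100, 101, 110, 111))
  codes <- gsub("[2-9]", "1", codes)         # binary strings 001..111
  res <- data.frame(code = codes, road = rep(0.25, 7), scorable = TRUE,
                    stringsAsFactors = FALSE)
  expect_true(all(cre(res, labels = c("A", "B", "C"))$cre == 0))
  set.seed(29)
  res$road <- runif(7)
  r1 <- cre(res, labels = c("A", "B", "C"))
  res2 <- res; res2$road <- res$road + 5
  r2 <- cre(res2, labels = c("A", "B", "C"))
  expect_equal(r1$cre, r2$cre, tolerance = 1e-12)
  # permuting the code positions permutes the CREs identically
  res3 <- res
  res3$code <- paste0(substr(res$code, 2, 2), substr(res$code, 1, 1),
                      substr(res$code, 3, 3))
  r3 <- cre(res3, labels = c("B", "A", "C"))
  expect_equal(r3$cre[c("A", "B", "C")], r1$cre[c("A", "B", "C")],
               tolerance = 1e-12)
  expect_error(cre(res[1, , drop = FALSE]), "at least 2")
})

test_that("aggregating grids equals summing group-wise CREs", {
  set.seed(31)
  mk <- function() {
    codes <- c("01", "10", "11")
    data.frame(code = codes, road = runif(3), scorable = TRUE,
               stringsAsFactors = FALSE)
  }
  a <- mk(); b <- mk()
  # residuals are per-grid; inter-experiment aggregation is the sum of the
  # per-grid group-wise values
  agg <- cre(a, labels = c("A", "B"))$cre + cre(b, labels = c("A", "B"))$cre
  expect_length(agg, 2)
  expect_equal(names(agg), c("A", "B"))
})

test_that("a two-group grid on the fixture model scores 3 of 4 codes", {
  model <- fixture_model()
  sc <- gen_scene(601)
  img <- array(sc$image, c(64, 64, 1))
  g <- build_grid(list(cam_group("E", "layercam"),
                       cam_group("B", c("gradcam", "gradcampp"))))
  res <- run_grid(g, model, img, sc$class_label, k_grid = c(15, 40),
                  config = road_config(percentiles = c(30, 60),
                                       noise_std = 0))
  expect_equal(nrow(res), 4)
  expect_equal(sum(res$scorable), 3)
  expect_false(res$scorable[res$code == "00"])
  expect_true(all(res$best_k[res$scorable] %in% c(15, 40)))
  expect_true(all(is.finite(res$road[res$scorable])))
  expect_identical(attr(res, "group_labels"), c("E", "B"))
  # a one-code restriction reduces to a single adaptive run
  single <- res[res$code == "10", ]
  ad <- adaptive_threshold_search(
    list(compute_cam("layercam", model, img,
                     class_index = sc$class_label)$map),
    model, img, sc$class_label, k_grid = c(15, 40),
    config = road_config(percentiles = c(30, 60), noise_std = 0))
  expect_equal(single$road, ad$best_score)
  expect_equal(single$best_k, ad$best_k)
})
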