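# Shared fixture models. The trained tiny classifier is expensive enough to
# build once and reuse across test files; everything else is built fresh.

.fixture_cache <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fixture_cache$model))
    .fixture_cache$model <- train_tiny_model(seed = 1, n_scenes = 400,
                                             epochs = 20)
  .fixture_cache$model
}

# classifier that ignores its input entirely: logits are fixed
constant_model <- function(logits, h = 8L, w = 8L) {
  model_handle(
    class_count = length(logits),
    input_shape = c(h, w, 1L),
    layers = "lyr",
    predict_logits = function(image) logits,
    capture_fn = function(image, layer, class_index)
      list(feature_maps = array(1, c(h, w, 1L)),
           gradients = array(0, c(h, w, 1L))))
}

# linear scorer: score_c = sum(W[[c]] * image); the captured layer is the
# image itself, so the analytic gradient of score_c at the layer is W[[c]]
linear_model <- function(W, h, w) {
  model_handle(
    class_count = length(W),
    input_shape = c(h, w, 1L),
    layers = "input",
    predict_logits = function(image) {
      img <- if (length(dim(image)) == 3L) image[, , 1] else image
      vapply(W, function(wc) sum(wc * img), numeric(1))
    },
    capture_fn = function(image, layer, class_index) {
      img <- if (length(dim(image)) == 3L) image[, , 1] else image
      list(feature_maps = array(img, c(h, w, 1L)),
           gradients = array(W[[class_index]], c(h, w, 1L)))
    },
    fullgrad_fn = function(image, class_index) {
      list(input_grad = array(W[[class_index]], c(h, w, 1L)),
           bias_terms = list())
    })
}

# model handle exposing a fixed activation bundle, for hand-built CAM cases
bundle_model <- function(A, G, n_classes = 2L) {
  d <- dim(A)
  model_handle(
    class_count = n_classes,
    input_shape = c(d[1], d[2], 1L),
    layers = "lyr",
    predict_logits = function(image) seq_len(n_classes),
    capture_fn = function(image, layer, class_index)
      list(feature_maps = A, gradients = G))
}

good_decoy_random_specs <- function() {
  list(synthetic_cam_spec(0.90, 0.15),
       synthetic_cam_spec(0.85, 0.20),
       synthetic_cam_spec(0.95, 0.10),
       synthetic_cam_spec(0.90, 0.15, targets_decoy = TRUE),
       synthetic_cam_spec(0.00, 1.00))
}
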