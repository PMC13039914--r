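#' Classifier adapter contract
#'
#' CAM computation and ROAD evaluation are decoupled from any particular
#' network through a minimal adapter: a `model_handle` bundles the forward
#' pass, the list of capturable layers, and closures that return activations
#' and gradients at a named layer. Any classifier that can honour this
#' contract — the in-package tiny CNN ([train_tiny_model()]), or a hand-built
#' toy model in a test — plugs into every downstream method unchanged.
#'
#' @param class_count number of output classes (>= 2).
#' @param input_shape integer vector `c(H, W, C)` the model expects.
#' @param layers character vector of capturable layer names (>= 1).
#' @param predict_logits `function(image) -> numeric[class_count]` raw scores.
#' @param capture_fn `function(image, layer, class_index) -> list(feature_maps,
#'   gradients)` with both arrays of shape `h x w x K`; `gradients` holds
#'   d(score of `class_index`) / d(feature_maps).
#' @param forward_masked optional `function(image, layer, channel_scale) ->
#'   logits`: re-runs the forward pass with the named layer's activations
#'   multiplied channel-wise by `channel_scale` (length K). Required by
#'   AblationCAM.
#' @param fullgrad_fn optional `function(image, class_index) ->
#'   list(input_grad, bias_terms)` where `input_grad` matches the image shape
#'   and `bias_terms` is a list of `h x w` matrices, one per bias unit, each
#'   already multiplied by its bias value. Required by FullGrad.
#' @param meta optional list of extra fields kept on the handle.
#' @return An object of class `model_handle`.
#' @export
model_handle <- function(class_count, input_shape, layers, predict_logits,
                         capture_fn, forward_masked = NULL, fullgrad_fn = NULL,
                         meta = list()) {
  if (class_count < 2) stop("a classifier needs at least 2 classes", call. = FALSE)
  if (length(layers) < 1) stop("at least one capturable layer is required", call. = FALSE)
  structure(
    c(list(class_count = as.integer(class_count),
           input_shape = as.integer(input_shape),
           layers = as.character(layers),
           predict_logits = predict_logits,
           capture_fn = capture_fn,
           forward_masked = forward_masked,
           fullgrad_fn = fullgrad_fn),
      meta),
    class = "model_handle")
}

#' @export
print.model_handle <- function(x, ...) {
  cat(sprintf("<model_handle: %d classes, input %s, layers: %s>\n",
              x$class_count, paste(x$input_shape, collapse = "x"),
              paste(x$layers, collapse = ", ")))
  invisible(x)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

check_image_shape <- function(model, image) {
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or array", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L)
  want <- model$input_shape
  if (!all(d == want))
    stop(sprintf("image shape %s does not match model input %s",
                 paste(d, collapse = "x"), paste(want, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Softmax confidence of a class
#'
#' The probability the model assigns to `class_index` for `image`. This is
#' the "confidence" used throughout ROAD scoring: a softmax probability
#' rather than a raw logit, so that confidence differences are bounded and
#' the combined ROAD score is scale-stable across models.
#'
#' @param model a [model_handle()].
#' @param image image matching the model's input spec.
#' @param class_index 1-based target class; `NULL` means the model's argmax
#'   on this image.
#' @return A probability in `[0, 1]`.
#' @export
predict_confidence <- function(model, image, class_index = NULL) {
  check_image_shape(model, image)
  p <- softmax(model$predict_logits(image))
  if (is.null(class_index)) class_index <- which.max(p)
  if (class_index < 1 || class_index > model$class_count)
    stop("class_index out of range", call. = FALSE)
  unname(p[class_index])
}

#' Class predicted by the model
#'
#' @inheritParams predict_confidence
#' @return The 1-based index of the highest-scoring class.
#' @export
predict_class <- function(model, image) {
  check_image_shape(model, image)
  which.max(model$predict_logits(image))
}

#' Activation bundle
#'
#' Feature maps and matching gradients captured at one model layer for one
#' (image, class) pair: the raw material of every gradient-based CAM. Both
#' arrays have shape `h x w x K` (layer resolution, K channels) and must be
#' finite.
#'
#' @param feature_maps `h x w x K` array of layer activations.
#' @param gradients array of the same shape: d(class score)/d(feature_maps).
#' @param class_index the target class the gradients refer to.
#' @return An object of class `activation_bundle`.
#' @export
activation_bundle <- function(feature_maps, gradients, class_index = NA_integer_) {
  if (length(dim(feature_maps)) == 2L)
    feature_maps <- array(feature_maps, c(dim(feature_maps), 1L))
  if (length(dim(gradients)) == 2L)
    gradients <- array(gradients, c(dim(gradients), 1L))
  if (!identical(dim(feature_maps), dim(gradients)))
    stop("feature maps and gradients must share shape exactly", call. = FALSE)
  if (!all(is.finite(feature_maps)) || !all(is.finite(gradients)))
    stop("activation bundle must be finite", call. = FALSE)
  structure(list(feature_maps = feature_maps, gradients = gradients,
                 class_index = class_index),
            class = "activation_bundle")
}

#' Capture activations and gradients at a layer
#'
#' Runs the model forward on `image`, records the activations of
#' `layer_name`, and back-propagates the score of `class_index` to obtain
#' the matching gradients. Capture is deterministic for a fixed model and
#' image: adapters must run in evaluation mode (no dropout, no batch-norm
#' statistics updates).
#'
#' @inheritParams predict_confidence
#' @param layer_name one of `model$layers`.
#' @return An [activation_bundle()].
#' @export
capture <- function(model, image, layer_name, class_index = NULL) {
  check_image_shape(model, image)
  if (!layer_name %in% model$layers)
    stop(sprintf("unknown layer '%s'; capturable layers: %s", layer_name,
                 paste(model$layers, collapse = ", ")), call. = FALSE)
  if (is.null(class_index)) class_index <- predict_class(model, image)
  if (class_index < 1 || class_index > model$class_count)
    stop("class_index out of range", call. = FALSE)
  got <- model$capture_fn(image, layer_name, as.integer(class_index))
  activation_bundle(got$feature_maps, got$gradients, as.integer(class_index))
}

# run expr with a private RNG stream; restores the caller's .Random.seed
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
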