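#' Available CAM methods
#'
#' The registry holds eleven published visual-explanation methods plus a
#' seeded random baseline (`randomcam`, uniform on `[-1, 1]`). Each name maps
#' to exactly one computation path in [compute_cam()].
#'
#' @return Character vector of method identifiers.
#' @export
cam_methods <- function() {
  c("gradcam", "gradcampp", "xgradcam", "eigengradcam",
    "hirescam", "gradcam_elementwise", "layercam",
    "scorecam", "ablationcam", "eigencam", "fullgrad", "randomcam")
}

CAM_EPS <- 1e-7

#' CAM result container
#'
#' Every method returns a `cam_result`: the method id, a normalized
#' image-resolution [saliency_map()], and a validity flag. Methods never
#' throw on a degenerate output (all-zero or non-finite map, missing model
#' capability); they return `valid = FALSE` with a reason so the ensemble
#' can drop them.
#'
#' @param method method identifier.
#' @param map a `saliency_map` or `NULL` when invalid.
#' @param valid logical.
#' @param reason character reason when invalid.
#' @return An object of class `cam_result`.
#' @export
cam_result <- function(method, map, valid = TRUE, reason = NA_character_) {
  structure(list(method = method, map = map, valid = valid, reason = reason),
            class = "cam_result")
}

#' @export
print.cam_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<cam_result %s: %dx%d map>\n", x$method,
                nrow(x$map), ncol(x$map)))
  else
    cat(sprintf("<cam_result %s: invalid (%s)>\n", x$method, x$reason))
  invisible(x)
}

# ReLU -> lift to image resolution -> validity check -> [0,1] normalization
finish_cam <- function(method, layer_map, target_h, target_w, relu = TRUE) {
  if (relu) layer_map <- pmax(layer_map, 0)
  if (!all(is.finite(layer_map)))
    return(cam_result(method, NULL, FALSE, "non-finite map"))
  up <- upsample_bilinear(saliency_map(layer_map), target_h, target_w)
  if (!any(up != 0))
    return(cam_result(method, NULL, FALSE, "all-zero map"))
  cam_result(method, normalize_unit(up))
}

#' Channel weights for the weighted-sum CAM family
#'
#' The classic CAM formulation combines the K feature maps at a layer as a
#' weighted sum with per-channel weights derived from the gradients:
#' `gradcam` uses the spatial mean of the gradient per channel; `gradcampp`
#' uses the GradCAM++ higher-order weighting (alpha coefficients from squared
#' and cubed first-order gradients, applied to positive gradients);
#' `xgradcam` scales gradients by activations, `sum(grad * A) / (sum(A) +
#' eps)` per channel.
#'
#' @param method one of `"gradcam"`, `"gradcampp"`, `"xgradcam"`.
#' @param bundle an [activation_bundle()].
#' @return Numeric vector of K channel weights.
#' @export
channel_weights <- function(method, bundle) {
  A <- bundle$feature_maps; G <- bundle$gradients
  K <- dim(A)[3]
  switch(method,
    gradcam = apply(G, 3, mean),
    xgradcam = vapply(seq_len(K), function(k) {
      sum(G[, , k] * A[, , k]) / (sum(A[, , k]) + CAM_EPS)
    }, numeric(1)),
    gradcampp = {
      g2 <- G^2; g3 <- G^3
      sumA <- apply(A, 3, sum)
      vapply(seq_len(K), function(k) {
        denom <- 2 * g2[, , k] + sumA[k] * g3[, , k]
        alpha <- ifelse(abs(denom) > CAM_EPS, g2[, , k] / denom, 0)
        sum(alpha * pmax(G[, , k], 0))
      }, numeric(1))
    },
    stop("unknown weighting method: ", method, call. = FALSE))
}

#' Elementwise-gradient CAM maps at layer resolution
#'
#' These methods weight each spatial location by its own gradient instead of
#' a channel-wide average: `hirescam` is `ReLU(sum_k(grad_k * A_k))`,
#' `gradcam_elementwise` applies the ReLU before the channel sum,
#' `sum_k ReLU(grad_k * A_k)`, and `layercam` keeps positive gradients only,
#' `ReLU(sum_k(ReLU(grad_k) * A_k))`.
#'
#' @param method one of `"hirescam"`, `"gradcam_elementwise"`, `"layercam"`.
#' @param bundle an [activation_bundle()].
#' @return Numeric `h x w` matrix (layer resolution, ReLU already applied).
#' @export
elementwise_map <- function(method, bundle) {
  A <- bundle$feature_maps; G <- bundle$gradients
  m <- switch(method,
    hirescam = pmax(apply(G * A, c(1, 2), sum), 0),
    gradcam_elementwise = apply(pmax(G * A, 0), c(1, 2), sum),
    layercam = pmax(apply(pmax(G, 0) * A, c(1, 2), sum), 0),
    stop("unknown elementwise method: ", method, call. = FALSE))
  m
}

#' Assemble a gradient-based CAM for an image
#'
#' Captures activations and gradients at `layer`, combines them according to
#' `method` (channel weighting or elementwise weighting), applies the final
#' ReLU, lifts the result to image resolution and normalizes to `[0, 1]`.
#'
#' @param method a gradient-based method id (weighted or elementwise family).
#' @param model a [model_handle()].
#' @param image input image.
#' @param layer capturable layer name.
#' @param class_index 1-based target class (default: model argmax).
#' @return A [cam_result()].
#' @export
assemble_cam <- function(method, model, image, layer, class_index = NULL) {
  bundle <- tryCatch(capture(model, image, layer, class_index),
                     error = function(e) e)
  if (inherits(bundle, "error"))
    return(cam_result(method, NULL, FALSE, conditionMessage(bundle)))
  d <- dim(image); if (is.null(d)) d <- c(length(image), 1L)
  if (method %in% c("hirescam", "gradcam_elementwise", "layercam")) {
    m <- elementwise_map(method, bundle)
    return(finish_cam(method, m, d[1], d[2], relu = FALSE))
  }
  w <- channel_weights(method, bundle)
  m <- weighted_channel_sum(bundle$feature_maps, w)
  finish_cam(method, m, d[1], d[2], relu = TRUE)
}

weighted_channel_sum <- function(A, w) {
  d <- dim(A)
  matrix(matrix(A, d[1] * d[2], d[3]) %*% w, d[1], d[2])
}

#' Perturbation-based CAMs (ScoreCAM, AblationCAM)
#'
#' ScoreCAM weights each channel by the model's target score on the input
#' masked by that channel's normalized, upsampled activation map; by default
#' the channel scores are passed through a softmax before weighting
#' (`score_norm = "softmax"`, the reference convention), or used raw
#' (`"raw"`). AblationCAM weights channel k by the relative score drop
#' `(y_c - y_c^ablated) / y_c` when channel k is zeroed at the layer
#' (epsilon-guarded when `y_c` is 0); it requires the adapter's
#' `forward_masked` capability.
#'
#' @param method `"scorecam"` or `"ablationcam"`.
#' @inheritParams assemble_cam
#' @param score_norm ScoreCAM channel-score normalization, `"softmax"` or
#'   `"raw"`.
#' @return A [cam_result()].
#' @export
perturbation_cam <- function(method, model, image, layer, class_index = NULL,
                             score_norm = c("softmax", "raw")) {
  score_norm <- match.arg(score_norm)
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (is.null(class_index)) class_index <- predict_class(model, image)
  bundle <- tryCatch(capture(model, image, layer, class_index),
                     error = function(e) e)
  if (inherits(bundle, "error"))
    return(cam_result(method, NULL, FALSE, conditionMessage(bundle)))
  A <- bundle$feature_maps
  K <- dim(A)[3]
  if (method == "scorecam") {
    scores <- vapply(seq_len(K), function(k) {
      ch <- normalize_unit(upsample_bilinear(saliency_map(A[, , k]), d[1], d[2]))
      mask <- array(as_map_matrix(ch), d)   # same mask on every channel
      model$predict_logits(image * mask)[class_index]
    }, numeric(1))
    w <- if (score_norm == "softmax") softmax(scores) else scores
  } else if (method == "ablationcam") {
    if (is.null(model$forward_masked))
      return(cam_result(method, NULL, FALSE,
                        "model does not support channel ablation"))
    y_c <- model$predict_logits(image)[class_index]
    denom <- if (abs(y_c) < CAM_EPS) CAM_EPS else y_c
    w <- vapply(seq_len(K), function(k) {
      scale <- rep(1, K); scale[k] <- 0
      y_abl <- model$forward_masked(image, layer, scale)[class_index]
      (y_c - y_abl) / denom
    }, numeric(1))
  } else stop("unknown perturbation method: ", method, call. = FALSE)
  m <- weighted_channel_sum(A, w)
  finish_cam(method, m, d[1], d[2], relu = TRUE)
}

#' Principal-component CAMs (EigenCAM, EigenGradCAM)
#'
#' EigenCAM projects the `K x (h*w)` activation matrix onto its first right
#' singular vector: the resulting `h x w` map is the dominant spatial
#' component shared across channels, computed without any class gradient.
#' EigenGradCAM applies the same decomposition to the elementwise product
#' `grad * A`, restoring class discrimination. The sign of a singular vector
#' is arbitrary; it is fixed so the entry of largest magnitude is positive.
#'
#' @param method `"eigencam"` or `"eigengradcam"`.
#' @param bundle an [activation_bundle()].
#' @param target_h,target_w image resolution for the final map.
#' @return A [cam_result()].
#' @export
eigen_cam <- function(method, bundle, target_h, target_w) {
  A <- switch(method,
    eigencam = bundle$feature_maps,
    eigengradcam = bundle$gradients * bundle$feature_maps,
    stop("unknown eigen method: ", method, call. = FALSE))
  d <- dim(A)
  M <- t(matrix(A, d[1] * d[2], d[3]))     # K x (h*w)
  if (all(M == 0))
    return(cam_result(method, NULL, FALSE, "rank-0 activation matrix"))
  sv <- svd(M, nu = 0, nv = 1)
  proj <- sv$d[1] * sv$v[, 1]
  if (proj[which.max(abs(proj))] < 0) proj <- -proj
  finish_cam(method, matrix(proj, d[1], d[2]), target_h, target_w, relu = FALSE)
}

#' FullGrad saliency
#'
#' Aggregates the input-gradient term `|x * d(score)/dx|` with one term per
#' bias unit, `|b * d(score)/d(pre-activation)|`, each term lifted to image
#' resolution and min-max normalized before summation, then normalized once
#' more. Requires the adapter's `fullgrad_fn` capability (bias terms exposed
#' with their spatial gradients); models without it yield an invalid result.
#'
#' @inheritParams assemble_cam
#' @return A [cam_result()].
#' @export
fullgrad_map <- function(model, image, class_index = NULL) {
  if (is.null(model$fullgrad_fn))
    return(cam_result("fullgrad", NULL, FALSE,
                      "model does not expose bias gradients"))
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (is.null(class_index)) class_index <- predict_class(model, image)
  fg <- model$fullgrad_fn(image, as.integer(class_index))
  norm_term <- function(m) {
    m <- abs(m)
    up <- upsample_bilinear(saliency_map(m), d[1], d[2])
    as_map_matrix(normalize_unit(up))
  }
  input_term <- apply(abs(image * fg$input_grad), c(1, 2), sum)
  total <- norm_term(input_term)
  for (bt in fg$bias_terms) total <- total + norm_term(bt)
  finish_cam("fullgrad", total, d[1], d[2], relu = FALSE)
}

#' Random baseline CAM
#'
#' An activation map drawn i.i.d. uniform on `[-1, 1]` and then min-max
#' normalized — the "RandomCAM" control used to probe whether an ensemble
#' benefits from uninformative components. Deterministic under `seed`.
#'
#' @param h,w map dimensions (image resolution).
#' @param seed integer seed.
#' @return A [cam_result()].
#' @export
random_cam <- function(h, w, seed = 1L) {
  if (h < 1 || w < 1) stop("dimensions must be positive", call. = FALSE)
  vals <- with_rng_seed(seed, matrix(stats::runif(h * w, -1, 1), h, w))
  cam_result("randomcam", normalize_unit(saliency_map(vals)))
}

#' Compute any registered CAM for an (image, class, model) triple
#'
#' Dispatches `method` to its computation path. `layer` defaults to the
#' model's last capturable layer (final-convolution CAMs are the standard
#' choice). For `randomcam`, `seed` controls the draw.
#'
#' @param method a method id from [cam_methods()].
#' @inheritParams assemble_cam
#' @param seed seed for `randomcam`.
#' @param score_norm passed to [perturbation_cam()] for ScoreCAM.
#' @return A [cam_result()].
#' @export
compute_cam <- function(method, model, image, layer = NULL, class_index = NULL,
                        seed = 1L, score_norm = "softmax") {
  method <- match.arg(method, cam_methods())
  if (is.null(layer))
    layer <- if (!is.null(model$default_layer)) model$default_layer
             else model$layers[length(model$layers)]
  d <- dim(image)
  if (method == "randomcam") return(random_cam(d[1], d[2], seed))
  if (method == "fullgrad") return(fullgrad_map(model, image, class_index))
  if (method %in% c("scorecam", "ablationcam"))
    return(perturbation_cam(method, model, image, layer, class_index,
                            score_norm = score_norm))
  if (method %in% c("eigencam", "eigengradcam")) {
    ci <- if (is.null(class_index)) predict_class(model, image) else class_index
    bundle <- tryCatch(capture(model, image, layer, ci),
                       error = function(e) e)
    if (inherits(bundle, "error"))
      return(cam_result(method, NULL, FALSE, conditionMessage(bundle)))
    return(eigen_cam(method, bundle, d[1], d[2]))
  }
  assemble_cam(method, model, image, layer, class_index)
}
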