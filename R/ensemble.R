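#' Drop invalid CAM results before ensembling
#'
#' Component CAMs that produce an invalid output for a given image and model
#' (all-zero, non-finite, or an unsupported capability) are removed before
#' any ensemble calculation, preserving order. If nothing survives, an error
#' lists the per-method reasons.
#'
#' @param results list of [cam_result()] objects.
#' @return The valid subset, same class of elements, order preserved.
#' @export
drop_invalid <- function(results) {
  ok <- vapply(results, function(r) {
    isTRUE(r$valid) && !is.null(r$map) && is_valid_map(r$map)
  }, logical(1))
  if (!any(ok)) {
    reasons <- vapply(results, function(r) {
      sprintf("%s: %s", r$method,
              if (isTRUE(r$valid)) "degenerate map" else r$reason)
    }, character(1))
    stop("no valid CAM results to ensemble:\n  ",
         paste(reasons, collapse = "\n  "), call. = FALSE)
  }
  results[ok]
}

maps_from <- function(maps) {
  # accepts a list of saliency_maps/matrices or of cam_results
  lapply(maps, function(m) {
    if (inherits(m, "cam_result")) {
      if (!isTRUE(m$valid)) stop("invalid cam_result in map stack", call. = FALSE)
      as_map_matrix(m$map)
    } else as_map_matrix(m)
  })
}

check_same_shape <- function(ms) {
  d1 <- dim(ms[[1]])
  for (m in ms) if (!identical(dim(m), d1))
    stop("all maps must share the same shape", call. = FALSE)
  d1
}

#' Pixelwise mean of normalized saliency maps
#'
#' The simplest ensemble: average the component maps pixel by pixel and
#' min-max normalize the result.
#'
#' @param maps list of normalized saliency maps (equal shapes); also accepts
#'   valid [cam_result()] objects.
#' @return A normalized `saliency_map`.
#' @export
mean_ensemble <- function(maps) {
  ms <- maps_from(maps)
  check_same_shape(ms)
  normalize_unit(Reduce(`+`, ms) / length(ms))
}

#' Transform per-CAM performance values into ensemble weights
#'
#' Converts a vector of CAM performance values (typically combined ROAD
#' scores, which can be negative) into nonnegative weights for the weighted
#' ensemble. `"minmax"` rescales to `[0, 1]` (uniform `1/n` for constant
#' input); `"softmax_amplified"` first multiplies by the smallest power of
#' ten `s >= 1` for which `max |s*v| >= 10` — amplifying small ROAD
#' differences before the softmax sharpens them — then applies a softmax;
#' `"exponential"` is a plain softmax `exp(v)/sum(exp(v))`; `"none"` keeps
#' raw values, shifted up if any are negative.
#'
#' @param road_values numeric vector of finite performance values.
#' @param mode one of `"none"`, `"minmax"`, `"softmax_amplified"`,
#'   `"exponential"`.
#' @return Nonnegative weights, one per value.
#' @export
weight_transform <- function(road_values,
                             mode = c("none", "minmax", "softmax_amplified",
                                      "exponential")) {
  mode <- match.arg(mode)
  v <- road_values
  if (!all(is.finite(v))) stop("weights require finite values", call. = FALSE)
  n <- length(v)
  switch(mode,
    none = if (any(v < 0)) v - min(v) else v,
    minmax = {
      if (max(v) == min(v)) rep(1 / n, n)
      else (v - min(v)) / (max(v) - min(v))
    },
    softmax_amplified = {
      ma <- max(abs(v))
      s <- if (ma == 0) 1 else 10^max(0, ceiling(log10(10 / ma)))
      softmax(s * v)
    },
    exponential = softmax(v))
}

#' Weighted pixelwise mean of saliency maps
#'
#' Combines maps as `sum(w_n * L_n) / sum(w_n)` followed by min-max
#' normalization. With uniform weights this reduces bit-for-bit to
#' [mean_ensemble()]. Weights are typically per-CAM ROAD scores passed
#' through [weight_transform()]; note this makes the weighting
#' evaluation-driven — the weights are computed on the same (image, class,
#' model) triple being explained.
#'
#' @param maps list of normalized saliency maps (equal shapes).
#' @param weights nonnegative weights, one per map, not all zero.
#' @return A normalized `saliency_map`.
#' @export
weighted_ensemble <- function(maps, weights) {
  ms <- maps_from(maps)
  check_same_shape(ms)
  if (length(weights) != length(ms))
    stop("one weight per map is required", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
  acc <- ms[[1]] * weights[1]
  for (i in seq_along(ms)[-1]) acc <- acc + ms[[i]] * weights[i]
  normalize_unit(acc / sum(weights))
}

#' Consensus ensemble: top-k% of pixels in agreement
#'
#' The core consensus formulation: the component maps are summed pixelwise
#' and a threshold keeps only the top-`k`% of summed activations (every
#' other pixel is set to zero). Pixels that only one poorly-behaved
#' component activates are thereby excluded — agreement across components is
#' what survives. At `k = 100` this reduces to a normalized sum. The output
#' is renormalized to `[0, 1]` by default, since retained values otherwise
#' live on a scale that grows with the number of components.
#'
#' @param maps list of normalized saliency maps (equal shapes).
#' @param k top percentage of pixels to keep, in `(0, 100]`.
#' @param renormalize_output min-max normalize the thresholded map.
#' @return A `saliency_map`.
#' @export
consensus_metacam <- function(maps, k, renormalize_output = TRUE) {
  ms <- maps_from(maps)
  check_same_shape(ms)
  total <- Reduce(`+`, ms)
  out <- topk_threshold(saliency_map(total), k)
  if (renormalize_output) normalize_unit(out) else out
}

#' Adaptive top-k threshold search driven by ROAD
#'
#' The best-performing threshold depends on the image, the target class and
#' the model, so it is searched: the candidate map (a consensus over a stack,
#' or a single map thresholded directly) is evaluated with [road_score()] at
#' every `k` in `k_grid`, and the argmax is returned together with the full
#' score table. Ties go to the smallest `k` (the most selective map at equal
#' ROAD), making the search deterministic.
#'
#' @param maps_or_single a list of normalized saliency maps (consensus mode)
#'   or a single `saliency_map` (thresholds that map alone).
#' @param model a [model_handle()].
#' @param image model input image.
#' @param class_index 1-based target class.
#' @param k_grid candidate top-k percentages (default 5, 10, ..., 95).
#' @param config a [road_config()].
#' @param renormalize_output passed to [consensus_metacam()].
#' @return An object of class `adaptive_result` with fields `best_k`,
#'   `best_map`, `best_score` and `scores_by_k` (a data.frame).
#' @export
adaptive_threshold_search <- function(maps_or_single, model, image, class_index,
                                      k_grid = seq(5, 95, by = 5),
                                      config = road_config(),
                                      renormalize_output = TRUE) {
  if (length(k_grid) < 1) stop("k_grid must be nonempty", call. = FALSE)
  k_grid <- sort(unique(k_grid))
  single <- inherits(maps_or_single, "saliency_map") ||
    (is.matrix(maps_or_single) && is.numeric(maps_or_single))
  cand <- function(k) {
    if (single) {
      m <- topk_threshold(maps_or_single, k)
      if (renormalize_output) normalize_unit(m) else m
    } else consensus_metacam(maps_or_single, k, renormalize_output)
  }
  scores <- numeric(length(k_grid))
  maps_cache <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    maps_cache[[i]] <- cand(k_grid[i])
    scores[i] <- road_score(model, image, class_index, maps_cache[[i]],
                            config)$combined
  }
  best <- which.max(scores)          # first max = smallest k on ties
  structure(list(best_k = k_grid[best],
                 best_map = maps_cache[[best]],
                 best_score = scores[best],
                 scores_by_k = data.frame(k = k_grid, road = scores)),
            class = "adaptive_result")
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat(sprintf("adaptive threshold search: best k = %g (ROAD %.4f) over %d candidates\n",
              x$best_k, x$best_score, nrow(x$scores_by_k)))
  invisible(x)
}
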