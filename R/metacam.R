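#' MetaCAM: consensus ensemble explanation of one prediction
#'
#' The main entry point. Computes the requested component CAMs for one
#' (image, class, model) triple, drops invalid ones, and combines the rest:
#'
#' * `mode = "consensus"` (default): pixelwise sum thresholded to the
#'   top-k% of activations. With `k = "auto"` the threshold is chosen by an
#'   adaptive search maximizing the ROAD score over `k_grid`.
#' * `mode = "mean"`: plain pixelwise average.
#' * `mode = "weighted"`: average weighted by each component's own ROAD
#'   score passed through `weight_transform`.
#'
#' The returned object records the final map, the per-method validity, the
#' adaptive score table (consensus mode) and the final ROAD score of the
#' ensemble map.
#'
#' @param model a [model_handle()].
#' @param image model input image (matrix or H x W x C array).
#' @param class_index 1-based target class; default is the model's argmax.
#' @param methods component CAM ids; the default is the union of the
#'   standard experiment groups (see [default_cam_groups()]).
#' @param mode `"consensus"`, `"mean"` or `"weighted"`.
#' @param k `"auto"` for adaptive search, or a fixed top-k percentage.
#' @param k_grid candidate thresholds for `k = "auto"`.
#' @param road a [road_config()].
#' @param weights_transform transform for `"weighted"` mode (see
#'   [weight_transform()]).
#' @param layer capturable layer (default: the model's last).
#' @param seed seed for `randomcam` components.
#' @return An object of class `metacam`.
#' @examples
#' \donttest{
#' model <- train_tiny_model(seed = 1, n_scenes = 200, epochs = 12)
#' scene <- gen_scene(42, with_decoy = TRUE)
#' fit <- metacam(model, scene$image, scene$class_label,
#'                methods = c("gradcam", "hirescam", "layercam"),
#'                k_grid = seq(10, 50, 10))
#' print(fit)
#' }
#' @export
metacam <- function(model, image, class_index = NULL,
                    methods = unlist(lapply(default_cam_groups(), `[[`,
                                            "members")),
                    mode = c("consensus", "mean", "weighted"),
                    k = "auto", k_grid = seq(5, 95, by = 5),
                    road = road_config(), weights_transform = "minmax",
                    layer = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  if (is.null(class_index)) class_index <- predict_class(model, image)
  cams <- compute_cams(model, image, class_index, methods = methods,
                       layer = layer, seed = seed)
  valid <- drop_invalid(cams)
  maps <- lapply(valid, `[[`, "map")
  validity <- data.frame(
    method = names(cams),
    valid = vapply(cams, function(r) isTRUE(r$valid) && !is.null(r$map) &&
                     is_valid_map(r$map), logical(1)),
    reason = vapply(cams, function(r) if (isTRUE(r$valid)) "" else r$reason,
                    character(1)),
    stringsAsFactors = FALSE)
  best_k <- NA_real_; scores_by_k <- NULL; comp_weights <- NULL
  if (mode == "consensus") {
    if (identical(k, "auto")) {
      ad <- adaptive_threshold_search(maps, model, image, class_index,
                                      k_grid = k_grid, config = road)
      map <- ad$best_map; best_k <- ad$best_k; scores_by_k <- ad$scores_by_k
    } else {
      map <- consensus_metacam(maps, k)
      best_k <- k
    }
  } else if (mode == "mean") {
    map <- mean_ensemble(maps)
  } else {
    rv <- vapply(maps, function(m)
      road_score(model, image, class_index, m, road)$combined, numeric(1))
    comp_weights <- weight_transform(rv, weights_transform)
    map <- weighted_ensemble(maps, comp_weights)
  }
  final_road <- road_score(model, image, class_index, map, road)
  structure(list(map = map, mode = mode, k = best_k,
                 scores_by_k = scores_by_k, validity = validity,
                 methods_used = names(valid), weights = comp_weights,
                 road = final_road, class_index = class_index,
                 image = image, seed = seed),
            class = "metacam")
}

#' @export
print.metacam <- function(x, ...) {
  cat(sprintf("MetaCAM (%s) of class %d from %d/%d valid components\n",
              x$mode, x$class_index, length(x$methods_used),
              nrow(x$validity)))
  if (!is.na(x$k)) cat(sprintf("  top-k threshold: %g%%\n", x$k))
  cat(sprintf("  combined ROAD:   %.4f\n", x$road$combined))
  invisible(x)
}

#' @export
summary.metacam <- function(object, ...) {
  cat(sprintf("MetaCAM summary (mode: %s, target class: %d)\n",
              object$mode, object$class_index))
  cat("\nComponent validity:\n")
  print(object$validity, row.names = FALSE)
  if (!is.null(object$weights)) {
    cat("\nComponent weights:\n")
    print(round(stats::setNames(object$weights, object$methods_used), 4))
  }
  if (!is.null(object$scores_by_k)) {
    cat(sprintf("\nAdaptive search (best k = %g):\n", object$k))
    print(object$scores_by_k, row.names = FALSE)
  }
  cat("\nFinal ROAD:\n")
  print(object$road)
  invisible(object)
}

#' @export
plot.metacam <- function(x, alpha = 0.5, ...) {
  img <- x$image
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  v <- as_map_matrix(normalize_unit(x$map))
  blend <- (1 - alpha) * img + alpha * heat_rgb(v)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  graphics::rasterImage(blend, 0, 0, 1, 1)
  graphics::title(sprintf("MetaCAM (%s%s), ROAD %.3f", x$mode,
                          if (!is.na(x$k)) sprintf(", k=%g%%", x$k) else "",
                          x$road$combined))
  invisible(x)
}
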