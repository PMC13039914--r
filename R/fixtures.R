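# Synthetic planted-saliency fixtures: scenes with a known class-defining
# region, controllable synthetic CAM stacks, and a small trainable
# classifier. Everything is a pure function of its seed and parameters, so
# the whole toolkit can be exercised end-to-end with no downloads.

# separable Gaussian blur with edge renormalization
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  kern <- exp(-(-r:r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur1 <- function(x) {   # blur the columns of x
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    wt <- numeric(n)
    for (j in -r:r) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)   # clamp at edges
      out <- out + kern[j + r + 1L] * x[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Generate a planted-saliency scene
#'
#' A scene is a grayscale image in `[0, 1]` containing a bright disc (the
#' class-defining subject) over a smooth textured noise background. The
#' class label is the quadrant holding the disc, which gives spatially
#' localized ground-truth saliency: a CAM explaining the correct prediction
#' should highlight the disc. Optionally a decoy — a dimmer square glyph in
#' a different quadrant, i.e. a plausible subject of another class — is
#' planted too, emulating images that contain two candidate subjects of
#' different classes. Truth and decoy supports are disjoint by construction
#' and both masks are recorded exactly.
#'
#' @param seed integer seed; the scene is a pure function of the arguments.
#' @param size image side in pixels (>= 16).
#' @param n_classes number of quadrant classes (2 to 4).
#' @param with_decoy plant a decoy glyph of a different class.
#' @return An object of class `planted_scene`: `image` (size x size
#'   matrix), `class_label`, `truth_mask`, `decoy_mask` (or `NULL`),
#'   `decoy_class`, `n_classes`.
#' @export
gen_scene <- function(seed, size = 64L, n_classes = 4L, with_decoy = FALSE) {
  if (size < 16) stop("size must be at least 16", call. = FALSE)
  if (n_classes < 2 || n_classes > 4)
    stop("n_classes must be 2, 3 or 4", call. = FALSE)
  size <- as.integer(size)
  with_rng_seed(seed, {
    cls <- sample.int(n_classes, 1)
    half <- size %/% 2L
    # quadrant row/col ranges, order: 1=top-left, 2=top-right, 3=bottom-left,
    # 4=bottom-right (rows increase downward)
    quad <- list(c(1L, half, 1L, half), c(1L, half, half + 1L, size),
                 c(half + 1L, size, 1L, half), c(half + 1L, size, half + 1L, size))
    bg <- gauss_blur(matrix(stats::runif(size^2), size, size), sigma = size / 24)
    bg <- 0.05 + 0.25 * (bg - min(bg)) / (max(bg) - min(bg))
    img <- bg
    place_disc <- function(q, radius) {
      rr <- quad[[q]][1:2]; cc <- quad[[q]][3:4]
      cy <- sample(seq(rr[1] + radius, rr[2] - radius), 1)
      cx <- sample(seq(cc[1] + radius, cc[2] - radius), 1)
      dist2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
      dist2 <= radius^2
    }
    radius <- max(2L, round(size / 8))
    truth <- place_disc(cls, radius)
    img[truth] <- stats::runif(1, 0.8, 1.0)
    decoy <- NULL; decoy_cls <- NA_integer_
    if (with_decoy) {
      decoy_cls <- sample(setdiff(seq_len(n_classes), cls), 1)
      side <- max(2L, round(size / 8))
      rr <- quad[[decoy_cls]][1:2]; cc <- quad[[decoy_cls]][3:4]
      r0 <- sample(seq(rr[1] + 1L, rr[2] - side - 1L), 1)
      c0 <- sample(seq(cc[1] + 1L, cc[2] - side - 1L), 1)
      decoy <- matrix(FALSE, size, size)
      decoy[r0:(r0 + side), c0:(c0 + side)] <- TRUE
      img[decoy] <- stats::runif(1, 0.45, 0.6)
    }
    structure(list(image = img, class_label = cls, truth_mask = truth,
                   decoy_mask = decoy, decoy_class = decoy_cls,
                   n_classes = as.integer(n_classes), seed = seed),
              class = "planted_scene")
  })
}

#' @export
print.planted_scene <- function(x, ...) {
  cat(sprintf("<planted_scene %dx%d, class %d/%d%s>\n",
              nrow(x$image), ncol(x$image), x$class_label, x$n_classes,
              if (!is.null(x$decoy_mask))
                sprintf(", decoy (class %d)", x$decoy_class) else ""))
  invisible(x)
}

#' Specification of one synthetic component CAM
#'
#' Controls the fidelity of a simulated saliency map with respect to the
#' scene's ground truth: `fidelity = 1, noise_level = 0` gives a map
#' proportional to a blurred truth mask; `fidelity = 0, noise_level = 1` a
#' pure random map; `targets_decoy = TRUE` aims the map at the decoy mask
#' instead — the "wrong subject" failure mode of non-discriminative CAMs on
#' two-subject images.
#'
#' @param fidelity in `[0, 1]`.
#' @param noise_level nonnegative noise amplitude.
#' @param targets_decoy highlight the decoy instead of the subject.
#' @return An object of class `synthetic_cam_spec`.
#' @export
synthetic_cam_spec <- function(fidelity, noise_level = 0, targets_decoy = FALSE) {
  stopifnot(fidelity >= 0, fidelity <= 1, noise_level >= 0)
  structure(list(fidelity = fidelity, noise_level = noise_level,
                 targets_decoy = targets_decoy), class = "synthetic_cam_spec")
}

#' Generate a stack of synthetic component CAMs for a scene
#'
#' Each map is `normalize(fidelity * blur(mask) + noise_level * noise)` with
#' the mask chosen per spec (truth or decoy) and independent uniform noise
#' per map (seeded by `seed` plus the map's position).
#'
#' @param scene a [gen_scene()] result.
#' @param specs list of [synthetic_cam_spec()] (nonempty).
#' @param seed integer seed.
#' @return List of normalized `saliency_map`s, one per spec.
#' @export
gen_cam_stack <- function(scene, specs, seed = 1L) {
  if (length(specs) < 1) stop("specs must be nonempty", call. = FALSE)
  size <- nrow(scene$image)
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    mask <- if (isTRUE(sp$targets_decoy)) {
      if (is.null(scene$decoy_mask))
        stop("spec targets the decoy but the scene has none", call. = FALSE)
      scene$decoy_mask
    } else scene$truth_mask
    base <- gauss_blur(mask * 1.0, sigma = size / 16)
    if (max(base) > 0) base <- base / max(base)
    noise <- with_rng_seed(seed + i,
                           matrix(stats::runif(size^2), size, size))
    normalize_unit(saliency_map(sp$fidelity * base + sp$noise_level * noise))
  })
}

#' Train the tiny fixture classifier
#'
#' Generates planted scenes (no decoys), trains the in-package
#' convolutional network (two conv layers, about 1300 parameters) on the
#' quadrant-classification task with Adam, and verifies held-out accuracy.
#' Training is deterministic under `seed` and takes well under two minutes
#' on one CPU at the defaults. Failure to reach `min_accuracy` raises an
#' error — that signals a task/architecture mismatch, not a condition to
#' silence.
#'
#' @param seed integer seed.
#' @param n_scenes total scenes generated (>= 50); 80% train, 20% held out.
#' @param epochs maximum training epochs.
#' @param size scene side in pixels.
#' @param n_classes quadrant classes.
#' @param min_accuracy required held-out accuracy.
#' @return A [model_handle()] with `net`, `holdout_accuracy` and
#'   `default_layer = "conv2"` attached.
#' @export
train_tiny_model <- function(seed = 1L, n_scenes = 400L, epochs = 20L,
                             size = 64L, n_classes = 4L, min_accuracy = 0.9) {
  if (n_scenes < 50) stop("n_scenes must be at least 50", call. = FALSE)
  seed <- as.numeric(seed)        # derived seeds may exceed integer range
  scenes <- lapply(seq_len(n_scenes),
                   function(i) gen_scene(seed * 100003 + i, size = size,
                                         n_classes = n_classes))
  images <- lapply(scenes, function(s) array(s$image, c(size, size, 1L)))
  labels <- vapply(scenes, `[[`, integer(1), "class_label")
  n_tr <- floor(0.8 * n_scenes)
  net <- tiny_cnn_init(seed, n_classes = n_classes, in_hw = size)
  net <- tiny_cnn_fit(net, images[seq_len(n_tr)], labels[seq_len(n_tr)],
                      epochs = epochs, seed = seed)
  acc <- tiny_cnn_accuracy(net, images[(n_tr + 1):n_scenes],
                           labels[(n_tr + 1):n_scenes])
  if (acc < min_accuracy)
    stop(sprintf("fixture model reached only %.1f%% held-out accuracy (need %.0f%%)",
                 100 * acc, 100 * min_accuracy), call. = FALSE)
  handle <- tiny_cnn_handle(net)
  handle$holdout_accuracy <- acc
  handle
}
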