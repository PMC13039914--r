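#' Saliency maps
#'
#' A saliency map is a 2-D grid of real-valued activation intensities over the
#' pixels of an image: the universal currency of this package. Every component
#' CAM method produces one, the consensus ensemble consumes stacks of them, and
#' the ROAD evaluator scores them. Internally a saliency map is a plain numeric
#' matrix of class `"saliency_map"` carrying a `normalized` attribute; pixel
#' indices are row-major, 0-based conceptually but addressed with R's usual
#' 1-based `[row, col]` convention throughout.
#'
#' @param values numeric matrix (height x width) of finite activation values.
#' @param normalized logical; assert that `values` already lie in `[0, 1]`.
#' @return An object of class `saliency_map`.
#' @examples
#' m <- saliency_map(matrix(c(0, 2, 4, 6), 2, 2))
#' normalize_unit(m)
#' @export
saliency_map <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("saliency map must have positive dimensions", call. = FALSE)
  storage.mode(values) <- "double"
  if (normalized && all(is.finite(values))) {
    rng <- range(values)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
      stop("`normalized = TRUE` but values fall outside [0, 1]", call. = FALSE)
  }
  structure(values, class = "saliency_map", normalized = normalized)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map %dx%d%s> range [%.4g, %.4g]\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else "",
              suppressWarnings(min(x)), suppressWarnings(max(x))))
  invisible(x)
}

#' @export
as.matrix.saliency_map <- function(x, ...) {
  m <- unclass(x)
  attr(m, "normalized") <- NULL
  m
}

#' Test whether a saliency map is valid
#'
#' A map is valid when all values are finite and at least one pixel is
#' nonzero. Invalid maps (all-zero, or containing NaN/Inf) are dropped by the
#' ensemble before averaging.
#'
#' @param map a `saliency_map` or numeric matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_map <- function(map) {
  all(is.finite(map)) && any(map != 0)
}

as_map_matrix <- function(map) {
  if (inherits(map, "saliency_map")) {
    m <- unclass(map)
    attr(m, "normalized") <- NULL
    m
  } else if (is.matrix(map) && is.numeric(map)) {
    map
  } else stop("expected a saliency_map or numeric matrix", call. = FALSE)
}

#' Min-max normalize a saliency map to [0, 1]
#'
#' Applies the affine rescale `(v - min) / (max - min)`. A constant map (where
#' `max == min`) maps to the all-zero map by convention; downstream code
#' treats such maps as valid but uninformative, never raising a division
#' error. Idempotent for non-constant maps.
#'
#' @param map a `saliency_map` or numeric matrix with finite values.
#' @return A normalized `saliency_map` of the same shape.
#' @export
normalize_unit <- function(map) {
  v <- as_map_matrix(map)
  if (!all(is.finite(v))) stop("cannot normalize a non-finite map", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    return(saliency_map(matrix(0, nrow(v), ncol(v)), normalized = TRUE))
  }
  saliency_map((v - lo) / (hi - lo), normalized = TRUE)
}

#' Keep only the top-k percent of pixels
#'
#' Retains, verbatim, every pixel whose value is greater than or equal to the
#' `(100 - k)`-th linear-interpolation percentile of all pixel values and sets
#' every other pixel to zero. `k = 100` is the identity. Ties at the threshold
#' are all kept, so the retained set has size at least `floor(k/100 * H * W)`
#' and the rule is independent of pixel traversal order.
#'
#' @param map a `saliency_map` or numeric matrix with finite values.
#' @param k percentage of pixels to keep, in `(0, 100]`.
#' @return A `saliency_map` of the same shape (not renormalized).
#' @export
topk_threshold <- function(map, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0 || k > 100)
    stop("`k` must be a single percentage in (0, 100]", call. = FALSE)
  v <- as_map_matrix(map)
  if (!all(is.finite(v))) stop("cannot threshold a non-finite map", call. = FALSE)
  if (k == 100) return(saliency_map(v))
  t <- stats::quantile(as.vector(v), probs = 1 - k / 100, names = FALSE, type = 7)
  out <- v
  out[out < t] <- 0
  saliency_map(out)
}

#' Bilinear resampling of a saliency map
#'
#' Lifts a feature-map-resolution activation grid to image resolution (or any
#' target size) by bilinear interpolation with half-pixel centre alignment
#' (the source grid's pixel centres cover the same physical extent as the
#' target's). Constant maps stay exactly constant, and a map already at the
#' target size is returned unchanged.
#'
#' @param map a `saliency_map` or numeric matrix.
#' @param target_h,target_w positive target dimensions in pixels.
#' @return A `saliency_map` of shape `target_h` x `target_w`.
#' @export
upsample_bilinear <- function(map, target_h, target_w) {
  if (!is.numeric(target_h) || !is.numeric(target_w) ||
      target_h < 1 || target_w < 1)
    stop("target dimensions must be positive", call. = FALSE)
  target_h <- as.integer(target_h); target_w <- as.integer(target_w)
  v <- as_map_matrix(map)
  h <- nrow(v); w <- ncol(v)
  if (h == target_h && w == target_w) return(saliency_map(v))
  # half-pixel alignment: target centre u maps to source coord (u+0.5)*h/th-0.5
  src_r <- (seq_len(target_h) - 0.5) * h / target_h - 0.5
  src_c <- (seq_len(target_w) - 0.5) * w / target_w - 0.5
  r0 <- pmin(pmax(floor(src_r), 0), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(pmax(floor(src_c), 0), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  # gather the four corner grids via outer indexing (1-based)
  g <- function(ri, ci) v[cbind(rep(ri + 1L, times = target_w),
                                rep(ci + 1L, each = target_h))]
  v00 <- g(r0, c0); v01 <- g(r0, c1); v10 <- g(r1, c0); v11 <- g(r1, c1)
  FR <- rep(fr, times = target_w); FC <- rep(fc, each = target_h)
  out <- (1 - FR) * (1 - FC) * v00 + (1 - FR) * FC * v01 +
    FR * (1 - FC) * v10 + FR * FC * v11
  saliency_map(matrix(out, target_h, target_w))
}

#' Read and write saliency maps as plain-text arrays
#'
#' The on-disk format is a whitespace-separated text file: a first line
#' `H W`, followed by H rows of W numbers. This round-trips losslessly at
#' full double precision and is the only format used in computation; PNG
#' heatmaps ([write_map_png()]) are for visualization only.
#'
#' @param map a `saliency_map` or numeric matrix.
#' @param path file path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   `saliency_map`.
#' @export
write_map <- function(map, path) {
  v <- as_map_matrix(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  utils::write.table(format(v, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
  saliency_map(matrix(vals, dims[1], dims[2], byrow = TRUE))
}

#' Write a saliency map as an 8-bit PNG heatmap
#'
#' Visualization only: quantization to 8 bits is lossy, so PNG output is
#' never read back into any computation path.
#'
#' @param map a `saliency_map` or numeric matrix.
#' @param path output PNG path.
#' @param image optional background image (H x W matrix or H x W x 3 array in
#'   `[0,1]`) to alpha-blend the heatmap over.
#' @param alpha blend weight of the heatmap when `image` is given.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path, image = NULL, alpha = 0.5) {
  v <- as_map_matrix(normalize_unit(map))
  cols <- heat_rgb(v)
  if (!is.null(image)) {
    if (length(dim(image)) == 2L) image <- array(rep(image, 3), c(dim(image), 3))
    cols <- (1 - alpha) * image + alpha * cols
  }
  png::writePNG(cols, path)
  invisible(path)
}

# simple blue->red colormap on [0,1]; presentation only
heat_rgb <- function(v) {
  r <- pmin(1, 2 * v)
  b <- pmin(1, 2 * (1 - v))
  g <- 1 - abs(2 * v - 1)
  array(c(r, g * 0.6, b), c(nrow(v), ncol(v), 3))
}
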