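#' ROAD configuration
#'
#' Settings for the Remove-and-Debias (ROAD) faithfulness metric:
#' perturbation percentiles, the scale of the Gaussian noise added to
#' imputed pixels, and the 8-neighbourhood weights of the linear imputation
#' system (edge-adjacent neighbours get `direct_weight`, corner-adjacent
#' `diagonal_weight`; at interior pixels `4*direct + 4*diagonal = 1`, and
#' weights are renormalized over the neighbours that exist at borders).
#'
#' @param percentiles perturbation percentages, each in `(0, 100)`.
#' @param noise_std standard deviation of imputation noise, in input
#'   intensity units (inputs are unit-scaled, so the default `0.01` is 1% of
#'   the intensity range). `0` makes scoring fully deterministic.
#' @param direct_weight,diagonal_weight neighbour weights.
#' @param seed seed for the imputation noise.
#' @return An object of class `road_config`.
#' @export
road_config <- function(percentiles = c(20, 40, 60, 80), noise_std = 0.01,
                        direct_weight = 1 / 6, diagonal_weight = 1 / 12,
                        seed = 1L) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie in (0, 100)", call. = FALSE)
  if (direct_weight <= 0 || diagonal_weight <= 0)
    stop("neighbour weights must be positive", call. = FALSE)
  structure(list(percentiles = percentiles, noise_std = noise_std,
                 direct_weight = direct_weight,
                 diagonal_weight = diagonal_weight,
                 seed = as.integer(seed)),
            class = "road_config")
}

#' Select the most or least activated pixels of a map
#'
#' Returns the logical mask of the `p`% highest-valued (`which = "most"`,
#' the MRP set) or lowest-valued (`"least"`, LRP) pixels, using the same
#' linear-interpolation percentile and keep-ties rule as
#' [topk_threshold()], so the mask is independent of pixel traversal order.
#'
#' @param map a `saliency_map` or numeric matrix.
#' @param p percentage in `(0, 100)`.
#' @param which `"most"` or `"least"`.
#' @return A logical matrix of the map's shape.
#' @export
select_pixels <- function(map, p, which = c("most", "least")) {
  which <- match.arg(which)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 100)
    stop("`p` must be a single percentage in (0, 100)", call. = FALSE)
  v <- as_map_matrix(map)
  if (!all(is.finite(v))) stop("map must be finite", call. = FALSE)
  if (which == "most") {
    t <- stats::quantile(as.vector(v), 1 - p / 100, names = FALSE, type = 7)
    v >= t
  } else {
    t <- stats::quantile(as.vector(v), p / 100, names = FALSE, type = 7)
    v <= t
  }
}

# sparse linear solve for one channel: masked pixels equal the renormalized
# weighted average of their 8-neighbourhood, unmasked neighbours acting as
# boundary data; a fully masked channel is anchored to the channel mean
impute_channel <- function(ch, mask, direct_w, diag_w) {
  h <- nrow(ch); w <- ncol(ch)
  midx <- which(mask)                      # linear indices of unknowns
  if (length(midx) == 0L) return(ch)
  unknown_id <- integer(h * w)
  unknown_id[midx] <- seq_along(midx)
  mr <- ((midx - 1L) %% h) + 1L
  mc <- ((midx - 1L) %/% h) + 1L
  offs <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                dc = c(0, 0, -1, 1, -1, 1, -1, 1),
                w  = c(rep(direct_w, 4), rep(diag_w, 4)))
  n <- length(midx)
  wsum <- numeric(n)
  rhs <- numeric(n)
  ti <- list(); tj <- list(); tx <- list()
  ti[[1]] <- seq_len(n); tj[[1]] <- seq_len(n); tx[[1]] <- rep(1, n)
  part <- 1L
  for (o in seq_len(nrow(offs))) {
    nr <- mr + offs[o, "dr"]; nc <- mc + offs[o, "dc"]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    if (!any(ok)) next
    nl <- nr[ok] + (nc[ok] - 1L) * h
    wt <- offs[o, "w"]
    wsum[ok] <- wsum[ok] + wt
    nb_unknown <- unknown_id[nl] > 0L
    if (any(nb_unknown)) {
      part <- part + 1L
      ti[[part]] <- which(ok)[nb_unknown]
      tj[[part]] <- unknown_id[nl[nb_unknown]]
      tx[[part]] <- rep(-wt, sum(nb_unknown))
    }
    if (any(!nb_unknown)) {
      ids <- which(ok)[!nb_unknown]
      rhs[ids] <- rhs[ids] + wt * ch[nl[!nb_unknown]]
    }
  }
  if (all(unknown_id > 0L)) {
    # fully masked: add the channel mean as a virtual direct neighbour
    wsum <- wsum + direct_w
    rhs <- rhs + direct_w * mean(ch)
  }
  # renormalize: divide each equation's neighbour weights by its wsum
  ii <- unlist(ti); jj <- unlist(tj); xx <- unlist(tx)
  off <- seq_along(ii) > n                 # first n triplets are the diagonal
  xx[off] <- xx[off] / wsum[ii[off]]
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  b <- rhs / wsum
  sol <- as.numeric(Matrix::solve(A, b))
  out <- ch
  out[midx] <- sol
  out
}

#' Noisy linear imputation of masked pixels
#'
#' Replaces each masked pixel, per channel, by the solution of the sparse
#' linear system in which every masked pixel equals the weighted average of
#' its 8-neighbourhood (weights from `config`, renormalized at borders),
#' with unmasked neighbours as boundary data. Zero-mean Gaussian noise of
#' scale `config$noise_std` is then added to the imputed pixels (drawn under
#' `config$seed`). Unmasked pixels are returned bit-identical. A fully
#' masked image is anchored by treating the channel mean as a virtual
#' neighbour of every pixel.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param mask logical `H x W` matrix of pixels to impute.
#' @param config a [road_config()].
#' @return The perturbed image, same shape as `image`.
#' @export
noisy_linear_impute <- function(image, mask, config = road_config()) {
  two_d <- length(dim(image)) == 2L
  img <- if (two_d) array(image, c(dim(image), 1L)) else image
  if (!identical(dim(mask), dim(img)[1:2]))
    stop("mask shape must match the image", call. = FALSE)
  out <- img
  n_masked <- sum(mask)
  if (n_masked > 0L) {
    for (c_i in seq_len(dim(img)[3])) {
      out[, , c_i] <- impute_channel(img[, , c_i], mask,
                                     config$direct_weight,
                                     config$diagonal_weight)
    }
    if (config$noise_std > 0) {
      noise <- with_rng_seed(config$seed,
        stats::rnorm(n_masked * dim(img)[3], 0, config$noise_std))
      k <- 0L
      midx <- which(mask)
      for (c_i in seq_len(dim(img)[3])) {
        plane <- out[, , c_i]
        plane[midx] <- plane[midx] + noise[k + seq_len(n_masked)]
        out[, , c_i] <- plane
        k <- k + n_masked
      }
    }
  }
  if (two_d) out[, , 1] else out
}

#' ROAD score of a saliency map
#'
#' For each perturbation percentile `p`, the most relevant `p`% of pixels
#' (MRP) and the least relevant `p`% (LRP) are imputed separately and the
#' model's softmax confidence in the target class is measured on each
#' perturbed image. The combined score is the mean over percentiles of
#' `(C_LRP - C_MRP) / 2`: a faithful map loses confidence when its most
#' relevant pixels are removed and keeps it when its least relevant pixels
#' are removed, so larger is better and the score is bounded in
#' `[-0.5, 0.5]`. The mean (rather than the sum) over percentiles keeps the
#' score stable when the percentile set changes; for a fixed set the two
#' differ only by a constant factor and rank maps identically.
#'
#' @param model a [model_handle()].
#' @param image model input image.
#' @param class_index 1-based target class.
#' @param map a valid `saliency_map` at image resolution.
#' @param config a [road_config()].
#' @return An object of class `road_score`: per-percentile LRP/MRP
#'   confidences and the `combined` scalar.
#' @export
road_score <- function(model, image, class_index, map, config = road_config()) {
  v <- as_map_matrix(map)
  if (!all(is.finite(v)))
    stop("cannot score an invalid (non-finite) map", call. = FALSE)
  d <- dim(image)
  if (!identical(dim(v), d[1:2]))
    stop("map resolution must match the image", call. = FALSE)
  c_lrp <- c_mrp <- numeric(length(config$percentiles))
  for (i in seq_along(config$percentiles)) {
    p <- config$percentiles[i]
    img_mrp <- noisy_linear_impute(image, select_pixels(v, p, "most"), config)
    img_lrp <- noisy_linear_impute(image, select_pixels(v, p, "least"), config)
    c_mrp[i] <- predict_confidence(model, img_mrp, class_index)
    c_lrp[i] <- predict_confidence(model, img_lrp, class_index)
  }
  structure(list(percentiles = config$percentiles,
                 c_lrp = c_lrp, c_mrp = c_mrp,
                 combined = mean((c_lrp - c_mrp) / 2)),
            class = "road_score")
}

#' @export
print.road_score <- function(x, ...) {
  cat("ROAD score\n")
  tab <- data.frame(percentile = x$percentiles,
                    C_LRP = round(x$c_lrp, 4), C_MRP = round(x$c_mrp, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("combined: %.4f\n", x$combined))
  invisible(x)
}
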