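# Independent reference implementations used as oracles. These are written
# as direct, naive transcriptions of the definitions (dense solves, double
# loops) and never share code with the package internals they check.

# dense least-squares solve of the imputation system: each masked pixel
# equals the weighted average of its in-bounds 8-neighbourhood, weights
# renormalized per pixel
dense_impute_oracle <- function(img, mask, dw = 1 / 6, gw = 1 / 12) {
  h <- nrow(img); w <- ncol(img)
  midx <- which(mask); n <- length(midx)
  if (n == 0) return(img)
  uid <- integer(h * w); uid[midx] <- seq_len(n)
  A <- diag(n); b <- numeric(n)
  for (q in seq_len(n)) {
    i <- midx[q]; r <- (i - 1) %% h + 1; cc <- (i - 1) %/% h + 1
    nbr <- list(); wts <- numeric()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
      nbr <- c(nbr, list(c(rr, c2)))
      wts <- c(wts, if (dr == 0 || dc == 0) dw else gw)
    }
    wts <- wts / sum(wts)
    for (j in seq_along(nbr)) {
      li <- nbr[[j]][1] + (nbr[[j]][2] - 1) * h
      if (uid[li] > 0) A[q, uid[li]] <- A[q, uid[li]] - wts[j]
      else b[q] <- b[q] + wts[j] * img[li]
    }
  }
  out <- img
  out[midx] <- solve(A, b)
  out
}

# per-pixel bilinear interpolation with half-pixel centre alignment,
# evaluated one output pixel at a time
bilinear_oracle <- function(v, th, tw) {
  h <- nrow(v); w <- ncol(v)
  out <- matrix(0, th, tw)
  for (i in seq_len(th)) for (j in seq_len(tw)) {
    sr <- (i - 0.5) * h / th - 0.5
    sc <- (j - 0.5) * w / tw - 0.5
    r0 <- min(max(floor(sr), 0), h - 1); r1 <- min(r0 + 1, h - 1)
    c0 <- min(max(floor(sc), 0), w - 1); c1 <- min(c0 + 1, w - 1)
    fr <- min(max(sr - r0, 0), 1); fc <- min(max(sc - c0, 0), 1)
    out[i, j] <- (1 - fr) * (1 - fc) * v[r0 + 1, c0 + 1] +
      (1 - fr) * fc * v[r0 + 1, c1 + 1] +
      fr * (1 - fc) * v[r1 + 1, c0 + 1] +
      fr * fc * v[r1 + 1, c1 + 1]
  }
  out
}

iou_of <- function(a, b) sum(a & b) / sum(a | b)

# binarized support of a map at top-k%
support_at_k <- function(map, k) as.matrix(topk_threshold(map, k)) > 0
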