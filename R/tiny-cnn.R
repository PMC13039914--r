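# Minimal convolutional network with exact backpropagation, written against
# base R matrix algebra. It exists so that every CAM method and the ROAD
# evaluator can be exercised end-to-end on a genuinely trained classifier
# without any external deep-learning runtime or downloaded weights.
#
# Architecture (for input H x W x C_in, n_classes outputs):
#   coord augmentation: two fixed planes with normalized row / column
#     coordinates are appended to the input, so channels can encode absolute
#     position (the classification task is position-dependent)
#   conv1: C_in+2 -> c1 channels, 5x5, stride 2, pad 2, ReLU
#   conv2: c1    -> c2 channels, 3x3, stride 2, pad 1, ReLU   <- CAM layer
#   global average pooling, then a dense layer to n_classes logits
#
# The GAP head is the canonical setting for CAMs: the gradient of a logit
# with respect to the CAM layer is spatially constant per channel, so the
# channel-weighted CAM family behaves exactly as on standard GAP networks.
#
# Convolutions are computed by im2col gather + one matrix multiply; the
# gather indices are precomputed per geometry so forward and backward are a
# handful of vectorized operations each.

conv_geom <- function(in_h, in_w, in_c, kh, kw, stride, pad) {
  pad_h <- in_h + 2L * pad; pad_w <- in_w + 2L * pad
  out_h <- (in_h + 2L * pad - kh) %/% stride + 1L
  out_w <- (in_w + 2L * pad - kw) %/% stride + 1L
  off <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * pad_h, "+"))
  off <- as.vector(outer(off, (0:(in_c - 1L)) * pad_h * pad_w, "+"))
  base <- as.vector(outer((0:(out_h - 1L)) * stride + 1L,
                          ((0:(out_w - 1L)) * stride) * pad_h, "+"))
  idx <- outer(off, base, "+")   # (kh*kw*in_c) x (out_h*out_w) padded indices
  list(in_h = in_h, in_w = in_w, in_c = in_c, kh = kh, kw = kw,
       stride = stride, pad = pad, pad_h = pad_h, pad_w = pad_w,
       out_h = out_h, out_w = out_w, idx = idx)
}

conv_pad <- function(g, x) {
  p <- array(0, c(g$pad_h, g$pad_w, g$in_c))
  p[g$pad + seq_len(g$in_h), g$pad + seq_len(g$in_w), ] <- x
  p
}

# x: (in_h, in_w, in_c) -> list(out = (out_h, out_w, K), cols)
conv_forward <- function(g, W, b, x) {
  padded <- conv_pad(g, x)
  cols <- matrix(padded[g$idx], nrow = nrow(g$idx))
  z <- W %*% cols + b                       # K x (oh*ow)
  list(out = array(t(z), c(g$out_h, g$out_w, nrow(W))), cols = cols)
}

# d_out: (out_h, out_w, K) -> grads wrt W, b and (optionally) the input
conv_backward <- function(g, W, cols, d_out, need_input = TRUE) {
  K <- nrow(W)
  dmat <- t(matrix(d_out, ncol = K))        # K x (oh*ow)
  dW <- dmat %*% t(cols)
  db <- rowSums(dmat)
  dx <- NULL
  if (need_input) {
    dcols <- crossprod(W, dmat)             # (kh*kw*in_c) x (oh*ow)
    acc <- rowsum(as.vector(dcols), group = as.vector(g$idx))
    dpad <- numeric(g$pad_h * g$pad_w * g$in_c)
    dpad[as.integer(rownames(acc))] <- acc
    dpad <- array(dpad, c(g$pad_h, g$pad_w, g$in_c))
    dx <- dpad[g$pad + seq_len(g$in_h), g$pad + seq_len(g$in_w), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

coord_planes <- function(h, w) {
  array(c(matrix((seq_len(h) - 0.5) / h, h, w),
          matrix((seq_len(w) - 0.5) / w, h, w, byrow = TRUE)), c(h, w, 2L))
}

augment_coords <- function(net, x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + 2L))
  out[, , seq_len(d[3])] <- x
  out[, , d[3] + 1:2] <- coord_planes(d[1], d[2])
  out
}

tiny_cnn_init <- function(seed, n_classes = 4L, in_hw = 64L, in_c = 1L,
                          c1 = 8L, c2 = 12L) {
  in_aug <- in_c + 2L
  g1 <- conv_geom(in_hw, in_hw, in_aug, 5L, 5L, 2L, 2L)
  g2 <- conv_geom(g1$out_h, g1$out_w, c1, 3L, 3L, 2L, 1L)
  with_rng_seed(seed, {
    par <- list(
      W1 = matrix(stats::rnorm(c1 * 5 * 5 * in_aug, sd = sqrt(2 / (25 * in_aug))),
                  nrow = c1),
      b1 = numeric(c1),
      W2 = matrix(stats::rnorm(c2 * 9 * c1, sd = sqrt(2 / (9 * c1))), nrow = c2),
      b2 = numeric(c2),
      Wf = matrix(stats::rnorm(n_classes * c2, sd = sqrt(1 / c2)),
                  nrow = n_classes),
      bf = numeric(n_classes))
    list(par = par, g1 = g1, g2 = g2,
         n_classes = as.integer(n_classes), in_c = as.integer(in_c),
         input_shape = c(in_hw, in_hw, in_c))
  })
}

tiny_cnn_forward <- function(net, x) {
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  xa <- augment_coords(net, x)
  f1 <- conv_forward(net$g1, net$par$W1, net$par$b1, xa)
  a1 <- pmax(f1$out, 0)
  f2 <- conv_forward(net$g2, net$par$W2, net$par$b2, a1)
  a2 <- pmax(f2$out, 0)
  d2 <- dim(a2)
  flat <- colMeans(matrix(a2, d2[1] * d2[2], d2[3]))   # global average pool
  logits <- as.vector(net$par$Wf %*% flat + net$par$bf)
  list(x = x, cols1 = f1$cols, z1 = f1$out, a1 = a1,
       cols2 = f2$cols, z2 = f2$out, a2 = a2,
       flat = flat, logits = logits)
}

# dlogits -> gradients of sum(dlogits * logits) wrt parameters, layer
# activations and (optionally) the input image
tiny_cnn_backward <- function(net, fw, dlogits, need_input = FALSE) {
  dWf <- outer(dlogits, fw$flat)
  dbf <- dlogits
  dflat <- as.vector(crossprod(net$par$Wf, dlogits))
  d2 <- dim(fw$a2)
  da2 <- aperm(array(rep(dflat / (d2[1] * d2[2]), each = d2[1] * d2[2]),
                     c(d2[1], d2[2], d2[3])), c(1, 2, 3))
  dz2 <- da2 * (fw$z2 > 0)
  bk2 <- conv_backward(net$g2, net$par$W2, fw$cols2, dz2, need_input = TRUE)
  da1 <- bk2$dx
  dz1 <- da1 * (fw$z1 > 0)
  bk1 <- conv_backward(net$g1, net$par$W1, fw$cols1, dz1, need_input = need_input)
  dx <- if (need_input) bk1$dx[, , seq_len(net$in_c), drop = FALSE] else NULL
  list(dW1 = bk1$dW, db1 = bk1$db, dW2 = bk2$dW, db2 = bk2$db,
       dWf = dWf, dbf = dbf,
       da1 = da1, dz1 = dz1, da2 = da2, dz2 = dz2, dx = dx)
}

# Adam update, in place on the parameter list
adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, wd = 1e-4) {
  state$t <- state$t + 1
  for (nm in names(par)) {
    gnm <- paste0("d", nm)
    gr <- grads[[gnm]] + wd * par[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

tiny_cnn_fit <- function(net, images, labels, epochs = 20L, lr = 3e-3,
                         batch = 16L, seed = 1L, stop_acc = 0.995) {
  n <- length(images)
  state <- list(t = 0, m = lapply(net$par, function(p) p * 0),
                v = lapply(net$par, function(p) p * 0))
  with_rng_seed(seed + 7777L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      correct <- 0L
      for (start in seq(1L, n, by = batch)) {
        ids <- ord[start:min(start + batch - 1L, n)]
        acc_gr <- NULL
        for (i in ids) {
          fw <- tiny_cnn_forward(net, images[[i]])
          p <- softmax(fw$logits)
          if (which.max(p) == labels[i]) correct <- correct + 1L
          dlogits <- p
          dlogits[labels[i]] <- dlogits[labels[i]] - 1
          gr <- tiny_cnn_backward(net, fw, dlogits / length(ids))
          if (is.null(acc_gr)) {
            acc_gr <- gr[c("dW1", "db1", "dW2", "db2", "dWf", "dbf")]
          } else {
            for (nm in names(acc_gr)) acc_gr[[nm]] <- acc_gr[[nm]] + gr[[nm]]
          }
        }
        upd <- adam_step(net$par, acc_gr, state, lr)
        net$par <- upd$par
        state <- upd$state
      }
      if (correct / n >= stop_acc) break
    }
  })
  net
}

tiny_cnn_accuracy <- function(net, images, labels) {
  pred <- vapply(images, function(im) which.max(tiny_cnn_forward(net, im)$logits),
                 integer(1))
  mean(pred == labels)
}

# Wrap a trained tiny CNN in the generic adapter contract. Capturable layers
# are the post-ReLU outputs of the two convolutions; CAM gradients are taken
# on the pre-softmax logit of the target class, the standard convention for
# gradient-based CAMs.
tiny_cnn_handle <- function(net) {
  predict_logits <- function(image) {
    if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
    tiny_cnn_forward(net, image)$logits
  }
  capture_fn <- function(image, layer, class_index) {
    fw <- tiny_cnn_forward(net, image)
    dlogits <- numeric(net$n_classes); dlogits[class_index] <- 1
    bk <- tiny_cnn_backward(net, fw, dlogits)
    if (layer == "conv1") list(feature_maps = fw$a1, gradients = bk$da1)
    else list(feature_maps = fw$a2, gradients = bk$da2)
  }
  forward_masked <- function(image, layer, channel_scale) {
    if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
    xa <- augment_coords(net, image)
    f1 <- conv_forward(net$g1, net$par$W1, net$par$b1, xa)
    a1 <- pmax(f1$out, 0)
    if (layer == "conv1")
      a1 <- sweep(a1, 3, channel_scale, "*")
    f2 <- conv_forward(net$g2, net$par$W2, net$par$b2, a1)
    a2 <- pmax(f2$out, 0)
    if (layer == "conv2")
      a2 <- sweep(a2, 3, channel_scale, "*")
    d2 <- dim(a2)
    flat <- colMeans(matrix(a2, d2[1] * d2[2], d2[3]))
    as.vector(net$par$Wf %*% flat + net$par$bf)
  }
  fullgrad_fn <- function(image, class_index) {
    if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
    fw <- tiny_cnn_forward(net, image)
    dlogits <- numeric(net$n_classes); dlogits[class_index] <- 1
    bk <- tiny_cnn_backward(net, fw, dlogits, need_input = TRUE)
    bias_terms <- c(
      lapply(seq_along(net$par$b1), function(k) net$par$b1[k] * bk$dz1[, , k]),
      lapply(seq_along(net$par$b2), function(k) net$par$b2[k] * bk$dz2[, , k]))
    list(input_grad = bk$dx, bias_terms = bias_terms)
  }
  model_handle(
    class_count = net$n_classes,
    input_shape = net$input_shape,
    layers = c("conv1", "conv2"),
    predict_logits = predict_logits,
    capture_fn = capture_fn,
    forward_masked = forward_masked,
    fullgrad_fn = fullgrad_fn,
    meta = list(net = net, default_layer = "conv2"))
}
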