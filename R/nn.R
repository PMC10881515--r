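# Minimal convolution engine used by the backbones: im2col/col2im with
# GEMM-based convolutions, average pooling, and activation functions.
# All spatial arrays are H x W x C; batches are lists or n x H x W x C.

# Pad the spatial dims of an H x W x C array with zeros.
pad_hw <- function(x, top, bottom, left, right) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + top + bottom, d[2] + left + right, d[3]))
  out[top + seq_len(d[1]), left + seq_len(d[2]), ] <- x
  out
}

# TensorFlow-style "same" padding amounts for one dimension.
same_pad <- function(n, k, stride) {
  total <- max((ceiling(n / stride) - 1) * stride + k - n, 0)
  c(floor(total / 2), ceiling(total / 2))
}

# im2col: columns ordered channel-major, then kernel column, then kernel
# row (fastest) so that `matrix(W, kh*kw*C, F)` of an kh x kw x C x F
# kernel array lines up with the patch matrix.
im2col <- function(x, kh, kw, stride = 1, pad = "same") {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (identical(pad, "same")) {
    pv <- same_pad(H, kh, stride); ph <- same_pad(W, kw, stride)
  } else if (identical(pad, "valid")) {
    pv <- c(0L, 0L); ph <- c(0L, 0L)
  } else stop("pad must be 'same' or 'valid'")
  xp <- if (sum(pv) + sum(ph) > 0) pad_hw(x, pv[1], pv[2], ph[1], ph[2])
        else x
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  out <- matrix(0, Ho * Wo, kh * kw * C)
  ri <- (seq_len(Ho) - 1L) * stride
  ci <- (seq_len(Wo) - 1L) * stride
  for (c in seq_len(C)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        col <- (c - 1L) * kh * kw + (dj - 1L) * kh + di
        out[, col] <- as.vector(xp[ri + di, ci + dj, c])
      }
    }
  }
  attr(out, "out_shape") <- c(Ho, Wo)
  out
}

# Scatter-add the columns of a patch-gradient matrix back onto the
# (padded) input; inverse of im2col for backpropagation (stride 1).
col2im <- function(dcols, in_shape, kh, kw, pad = "same") {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  if (identical(pad, "same")) {
    pv <- same_pad(H, kh, 1L); ph <- same_pad(W, kw, 1L)
  } else { pv <- c(0L, 0L); ph <- c(0L, 0L) }
  Hp <- H + sum(pv); Wp <- W + sum(ph)
  Ho <- Hp - kh + 1L; Wo <- Wp - kw + 1L
  dxp <- array(0, dim = c(Hp, Wp, C))
  ri <- seq_len(Ho) - 1L; ci <- seq_len(Wo) - 1L
  for (c in seq_len(C)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        col <- (c - 1L) * kh * kw + (dj - 1L) * kh + di
        dxp[ri + di, ci + dj, c] <- dxp[ri + di, ci + dj, c] +
          matrix(dcols[, col], Ho, Wo)
      }
    }
  }
  dxp[pv[1] + seq_len(H), ph[1] + seq_len(W), , drop = FALSE]
}

# Standard convolution of one H x W x C array.
conv2d <- function(x, W, b = NULL, stride = 1, pad = "same") {
  dw <- dim(W)  # kh x kw x Cin x F
  cols <- im2col(x, dw[1], dw[2], stride, pad)
  os <- attr(cols, "out_shape")
  y <- cols %*% matrix(W, dw[1] * dw[2] * dw[3], dw[4])
  if (!is.null(b)) y <- sweep(y, 2, b, `+`)
  array(y, dim = c(os[1], os[2], dw[4]))
}

# Depthwise convolution: kernel kh x kw x C, one filter per channel.
depthwise_conv2d <- function(x, W, stride = 1, pad = "same") {
  dw <- dim(W); kh <- dw[1]; kw <- dw[2]; C <- dw[3]
  cols <- im2col(x, kh, kw, stride, pad)
  os <- attr(cols, "out_shape")
  out <- matrix(0, nrow(cols), C)
  wm <- matrix(W, kh * kw, C)
  for (c in seq_len(C)) {
    blk <- (c - 1L) * kh * kw + seq_len(kh * kw)
    out[, c] <- cols[, blk, drop = FALSE] %*% wm[, c]
  }
  array(out, dim = c(os[1], os[2], C))
}

# Non-overlapping average pooling by an integer factor.
avg_pool <- function(x, factor) {
  if (factor == 1) return(x)
  d <- dim(x)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  out <- array(0, dim = c(d[1] %/% factor, d[2] %/% factor, d[3]))
  for (di in seq_len(factor)) {
    for (dj in seq_len(factor)) {
      out <- out + x[seq(di, d[1], by = factor), seq(dj, d[2], by = factor),
                     , drop = FALSE]
    }
  }
  out / factor^2
}

# Distribute a pooled gradient uniformly back over each pooling window.
avg_unpool <- function(dy, factor) {
  if (factor == 1) return(dy)
  d <- dim(dy)
  out <- array(0, dim = c(d[1] * factor, d[2] * factor, d[3]))
  g <- dy / factor^2
  for (di in seq_len(factor)) {
    for (dj in seq_len(factor)) {
      out[seq(di, d[1] * factor, by = factor),
          seq(dj, d[2] * factor, by = factor), ] <- g
    }
  }
  out
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigmoid(x)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Global average pooling of H x W x C to a length-C vector.
global_avg_pool <- function(x) apply(x, 3, mean)
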