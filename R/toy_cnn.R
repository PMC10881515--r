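# Desk-scale trainable backbone: a small convolutional network with a
# hand-written backward pass.  Architecture (input s x s x C in [0, 1]):
#   average pre-pool to ~32 px  ->  conv 5x5 -> ReLU -> avgpool 2
#   -> conv 3x3 -> ReLU -> global average pool
#   -> dense (feature layer, default 64 units, ReLU) -> dense softmax.
# The penultimate dense activation is the declared feature layer.

toy_cnn_init <- function(input_side, n_channels, n_classes,
                         n_filters = c(16, 32), dense_dim = 64, seed = 1) {
  pre_pool <- max(1L, input_side %/% 32L)
  s0 <- input_side %/% pre_pool
  if (s0 %% 2 != 0) stopf("input side %d not divisible for pooling",
                          input_side)
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  with_seed(seed, {
    p <- list(
      W1 = array(he(25 * n_channels, 25 * n_channels * n_filters[1]),
                 dim = c(5, 5, n_channels, n_filters[1])),
      b1 = rep(0, n_filters[1]),
      W2 = array(he(9 * n_filters[1], 9 * n_filters[1] * n_filters[2]),
                 dim = c(3, 3, n_filters[1], n_filters[2])),
      b2 = rep(0, n_filters[2]),
      Wd = matrix(he(n_filters[2], n_filters[2] * dense_dim),
                  n_filters[2], dense_dim),
      bd = rep(0, dense_dim),
      Wo = matrix(he(dense_dim, dense_dim * n_classes),
                  dense_dim, n_classes),
      bo = rep(0, n_classes))
    p$pre_pool <- pre_pool
    p$input_side <- as.integer(input_side)
    p$n_channels <- as.integer(n_channels)
    p
  })
}

# Forward pass over a batch (n x s x s x C array).  Returns probs,
# features (dense activations) and, if keep_cache, everything the
# backward pass needs.
toy_cnn_forward <- function(p, xbatch, keep_cache = FALSE) {
  n <- dim(xbatch)[1]
  F1 <- dim(p$W1)[4]; F2 <- dim(p$W2)[4]
  s0 <- p$input_side %/% p$pre_pool
  s1 <- s0 %/% 2
  W1m <- matrix(p$W1, 25 * p$n_channels, F1)
  W2m <- matrix(p$W2, 9 * F1, F2)
  cols1 <- vector("list", n); cols2 <- vector("list", n)
  A1 <- vector("list", n); X2 <- vector("list", n); A2 <- vector("list", n)
  Fmat <- matrix(0, n, F2)
  for (i in seq_len(n)) {
    x <- avg_pool(array(xbatch[i, , , ], dim = dim(xbatch)[-1]), p$pre_pool)
    c1 <- im2col(x, 5, 5, 1, "same")
    a1 <- relu(sweep(c1 %*% W1m, 2, p$b1, `+`))
    a1arr <- array(a1, dim = c(s0, s0, F1))
    x2 <- avg_pool(a1arr, 2)
    c2 <- im2col(x2, 3, 3, 1, "same")
    a2 <- relu(sweep(c2 %*% W2m, 2, p$b2, `+`))
    Fmat[i, ] <- colMeans(a2)
    if (keep_cache) {
      cols1[[i]] <- c1; A1[[i]] <- a1; X2[[i]] <- x2
      cols2[[i]] <- c2; A2[[i]] <- a2
    }
  }
  Hpre <- sweep(Fmat %*% p$Wd, 2, p$bd, `+`)
  H <- relu(Hpre)
  logits <- sweep(H %*% p$Wo, 2, p$bo, `+`)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, features = H)
  if (keep_cache)
    out$cache <- list(cols1 = cols1, A1 = A1, X2 = X2, cols2 = cols2,
                      A2 = A2, Fmat = Fmat, Hpre = Hpre, H = H,
                      W1m = W1m, W2m = W2m, s0 = s0, s1 = s1,
                      F1 = F1, F2 = F2)
  out
}

# Backward pass; dlogits already includes the 1/batch factor.
toy_cnn_backward <- function(p, fw, dlogits) {
  ca <- fw$cache
  n <- nrow(dlogits)
  g <- list()
  g$Wo <- t(ca$H) %*% dlogits
  g$bo <- colSums(dlogits)
  dH <- dlogits %*% t(p$Wo)
  dH[ca$Hpre <= 0] <- 0
  g$Wd <- t(ca$Fmat) %*% dH
  g$bd <- colSums(dH)
  dF <- dH %*% t(p$Wd)
  g$W2 <- array(0, dim = dim(p$W2)); g$b2 <- rep(0, ca$F2)
  g$W1 <- array(0, dim = dim(p$W1)); g$b1 <- rep(0, ca$F1)
  W2g <- matrix(0, 9 * ca$F1, ca$F2)
  W1g <- matrix(0, 25 * p$n_channels, ca$F1)
  for (i in seq_len(n)) {
    # through global average pool and conv2 ReLU
    dA2 <- matrix(dF[i, ] / (ca$s1^2), ca$s1^2, ca$F2, byrow = TRUE)
    dA2[ca$A2[[i]] <= 0] <- 0
    W2g <- W2g + t(ca$cols2[[i]]) %*% dA2
    g$b2 <- g$b2 + colSums(dA2)
    dX2 <- col2im(dA2 %*% t(ca$W2m), c(ca$s1, ca$s1, ca$F1), 3, 3, "same")
    dA1arr <- avg_unpool(dX2, 2)
    dA1 <- matrix(dA1arr, ca$s0^2, ca$F1)
    dA1[ca$A1[[i]] <= 0] <- 0
    W1g <- W1g + t(ca$cols1[[i]]) %*% dA1
    g$b1 <- g$b1 + colSums(dA1)
  }
  g$W2 <- array(W2g, dim = dim(p$W2))
  g$W1 <- array(W1g, dim = dim(p$W1))
  g
}

toy_cnn_sgd_step <- function(p, g, lr) {
  for (nm in c("W1", "b1", "W2", "b2", "Wd", "bd", "Wo", "bo"))
    p[[nm]] <- p[[nm]] - lr * g[[nm]]
  p
}
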