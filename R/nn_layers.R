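# Layer arithmetic for the desk-scale convolutional backbone.  Batches are
# (H, W, C, N) arrays; convolutions are 3x3 with same padding, implemented
# as im2col (compiled) followed by BLAS matrix products.

conv_forward <- function(X, W, b) {
  d <- dim(X)
  M <- conv_im2col(X, d[1], d[2], d[3], d[4])
  Y <- M %*% W
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  A <- array(Y, c(d[1], d[2], d[4], ncol(W)))
  list(out = aperm(A, c(1, 2, 4, 3)), M = M, dims = d)
}

conv_backward <- function(dOut, cache, W) {
  d <- cache$dims
  dY <- matrix(aperm(dOut, c(1, 2, 4, 3)), nrow(cache$M), ncol(W))
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dX <- conv_col2im(dM, d[1], d[2], d[3], d[4])
  dim(dX) <- d
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(X) pmax(X, 0)
relu_backward <- function(dOut, X) dOut * (X > 0)

# 2x2 average pooling (stride 2); H and W must be even.
avgpool_forward <- function(X) {
  d <- dim(X)
  or <- seq(1L, d[1], 2L); oc <- seq(1L, d[2], 2L)
  (X[or, oc, , , drop = FALSE] + X[or + 1L, oc, , , drop = FALSE] +
   X[or, oc + 1L, , , drop = FALSE] + X[or + 1L, oc + 1L, , , drop = FALSE]) / 4
}

avgpool_backward <- function(dOut, in_dims) {
  dX <- array(0, in_dims)
  or <- seq(1L, in_dims[1], 2L); oc <- seq(1L, in_dims[2], 2L)
  g <- dOut / 4
  dX[or, oc, , ] <- g
  dX[or + 1L, oc, , ] <- g
  dX[or, oc + 1L, , ] <- g
  dX[or + 1L, oc + 1L, , ] <- g
  dX
}

# Global average pooling: (H, W, C, N) -> (N, C) feature matrix.
gap_forward <- function(X) {
  d <- dim(X)
  Xm <- X
  dim(Xm) <- c(d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(Xm), d[3], d[4]))
}

gap_backward <- function(dF, in_dims) {
  # dF is (N, C); spread evenly over the spatial grid
  per <- t(dF) / (in_dims[1] * in_dims[2])      # (C, N)
  dX <- array(rep(as.vector(per), each = in_dims[1] * in_dims[2]), in_dims)
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy and logit gradient for integer targets in 1..K.
softmax_xent <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y)] + eps))
  dL <- P
  dL[cbind(seq_len(n), y)] <- dL[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dL / n, probs = P)
}
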