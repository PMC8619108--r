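# Minimal convolutional network engine (base R, BLAS-backed im2col
# convolutions). Supports exactly what the keypoint detector needs:
# 3x3 same-padding convolutions, ReLU/sigmoid, 2x2 max pooling, 2x2 nearest
# upsampling, channel concatenation, binary cross-entropy and Adam.
# Tensors are H x W x C arrays.

nn_im2col <- function(x, k = 3) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  pad <- (k - 1) %/% 2
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  cols <- matrix(0, H * W, k * k * C)
  j <- 0L
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    patch <- xp[dy:(dy + H - 1), dx:(dx + W - 1), , drop = FALSE]
    cols[, j * C + seq_len(C)] <- matrix(patch, H * W, C)
    j <- j + 1L
  }
  cols
}

nn_col2im <- function(cols, H, W, C, k = 3) {
  pad <- (k - 1) %/% 2
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  j <- 0L
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    xp[dy:(dy + H - 1), dx:(dx + W - 1), ] <-
      xp[dy:(dy + H - 1), dx:(dx + W - 1), , drop = FALSE] +
      array(cols[, j * C + seq_len(C)], c(H, W, C))
    j <- j + 1L
  }
  xp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

# forward conv: returns list(out, cache) ; weights W: (k*k*Cin) x Cout, b: Cout
nn_conv_fwd <- function(x, Wm, b, k = 3) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- nn_im2col(x, k)
  out <- cols %*% Wm
  out <- sweep(out, 2, b, `+`)
  list(out = array(out, c(H, W, ncol(Wm))), cols = cols)
}

nn_conv_bwd <- function(dout, cols, Wm, H, W, Cin, k = 3) {
  dmat <- matrix(dout, H * W, dim(dout)[3])
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wm)
  dx <- nn_col2im(dcols, H, W, Cin, k)
  list(dx = dx, dW = dW, db = db)
}

nn_pool_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  a <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  b <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  cc <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  d <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  out <- pmax(a, b, cc, d)
  list(out = out, mask = list(a = out == a, b = out == b, cc = out == cc, d = out == d))
}

nn_pool_bwd <- function(dout, mask, H, W) {
  C <- dim(dout)[3]
  dx <- array(0, c(H, W, C))
  # credit each max once, in fixed position order, to keep gradients exact
  # under ties
  taken <- array(FALSE, dim(dout))
  put <- function(dx, sel, rows, cols) {
    use <- sel & !taken
    taken <<- taken | sel
    sub <- dx[rows, cols, , drop = FALSE]
    sub[use] <- sub[use] + dout[use]
    dx[rows, cols, ] <- sub
    dx
  }
  dx <- put(dx, mask$a, seq(1, H, 2), seq(1, W, 2))
  dx <- put(dx, mask$b, seq(2, H, 2), seq(1, W, 2))
  dx <- put(dx, mask$cc, seq(1, H, 2), seq(2, W, 2))
  dx <- put(dx, mask$d, seq(2, H, 2), seq(2, W, 2))
  dx
}

nn_upsample_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(2 * H, 2 * W, C))
  out[seq(1, 2 * H, 2), seq(1, 2 * W, 2), ] <- x
  out[seq(2, 2 * H, 2), seq(1, 2 * W, 2), ] <- x
  out[seq(1, 2 * H, 2), seq(2, 2 * W, 2), ] <- x
  out[seq(2, 2 * H, 2), seq(2, 2 * W, 2), ] <- x
  out
}

nn_upsample_bwd <- function(dout) {
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  dout[seq(1, H2, 2), seq(1, W2, 2), , drop = FALSE] +
    dout[seq(2, H2, 2), seq(1, W2, 2), , drop = FALSE] +
    dout[seq(1, H2, 2), seq(2, W2, 2), , drop = FALSE] +
    dout[seq(2, H2, 2), seq(2, W2, 2), , drop = FALSE]
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# mean binary cross-entropy over all pixels/channels, on sigmoid outputs
nn_bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
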