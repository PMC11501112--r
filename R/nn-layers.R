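# Neural-network primitives operating on H x W x C arrays (batch of one).
#
# Convolutions are im2col-based so the heavy lifting is a single BLAS
# matrix product; every op returns a cache sufficient for its backward
# pass. These are internal building blocks of the U-Net in unet.R.

im2col3 <- function(x, k = 3L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2 * p, W + 2 * p, C))
  xp[p + (1:H), p + (1:W), ] <- x
  cols <- matrix(0, H * W, k * k * C)
  b <- 1L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    cols[, ((b - 1) * C + 1):(b * C)] <-
      matrix(xp[di + (1:H), dj + (1:W), , drop = FALSE], H * W, C)
    b <- b + 1L
  }
  cols
}

col2im3 <- function(dcols, H, W, C, k = 3L) {
  p <- (k - 1L) %/% 2L
  gxp <- array(0, c(H + 2 * p, W + 2 * p, C))
  b <- 1L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    gxp[di + (1:H), dj + (1:W), ] <-
      gxp[di + (1:H), dj + (1:W), , drop = FALSE] +
      array(dcols[, ((b - 1) * C + 1):(b * C)], c(H, W, C))
    b <- b + 1L
  }
  gxp[p + (1:H), p + (1:W), , drop = FALSE]
}

conv3_fwd <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% W
  y <- sweep(y, 2, b, "+")
  list(out = array(y, c(d[1], d[2], ncol(W))), cols = cols, dims = d)
}

conv3_bwd <- function(cache, W, dout) {
  d <- cache$dims
  dmat <- matrix(dout, d[1] * d[2], length(dout) / (d[1] * d[2]))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, W)
  dx <- col2im3(dcols, d[1], d[2], d[3])
  list(dx = dx, dW = dW, db = db)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  y <- sweep(xm %*% W, 2, b, "+")
  list(out = array(y, c(d[1], d[2], ncol(W))), xm = xm, dims = d)
}

conv1_bwd <- function(cache, W, dout) {
  d <- cache$dims
  dmat <- matrix(dout, d[1] * d[2], length(dout) / (d[1] * d[2]))
  list(dx = array(tcrossprod(dmat, W), d),
       dW = crossprod(cache$xm, dmat),
       db = colSums(dmat))
}

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, mask = x > 0)
}

relu_bwd <- function(cache, dout) dout * cache$mask

# Batch normalization over the spatial extent, per channel.
bn_fwd <- function(x, gamma, beta, training, rmean, rvar,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va
  } else {
    mu <- rmean; va <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  xn <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
  y <- sweep(sweep(xn, 2, gamma, "*"), 2, beta, "+")
  list(out = array(y, d), xn = xn, istd = istd, dims = d,
       rmean = rmean, rvar = rvar, training = training)
}

bn_bwd <- function(cache, gamma, dout) {
  d <- cache$dims
  n <- d[1] * d[2]
  dym <- matrix(dout, n, d[3])
  dgamma <- colSums(dym * cache$xn)
  dbeta <- colSums(dym)
  dxn <- sweep(dym, 2, gamma, "*")
  if (cache$training) {
    # gradient through the batch statistics
    t1 <- sweep(dxn, 2, colMeans(dxn), "-")
    t2 <- sweep(cache$xn, 2, colMeans(dxn * cache$xn), "*")
    dxm <- sweep(t1 - t2, 2, cache$istd, "*")
  } else {
    dxm <- sweep(dxn, 2, cache$istd, "*")
  }
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xr <- array(x, c(2, H / 2, 2, W / 2, C))
  v1 <- array(xr[1, , 1, , ], c(H / 2, W / 2, C))
  v2 <- array(xr[2, , 1, , ], c(H / 2, W / 2, C))
  v3 <- array(xr[1, , 2, , ], c(H / 2, W / 2, C))
  v4 <- array(xr[2, , 2, , ], c(H / 2, W / 2, C))
  m12 <- pmax(v1, v2); m34 <- pmax(v3, v4)
  out <- pmax(m12, m34)
  list(out = out,
       sel = list(a = v1 >= v2, b = v3 >= v4, top = m12 >= m34),
       dims = d)
}

maxpool_bwd <- function(cache, dout) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  s <- cache$sel
  g12 <- dout * s$top; g34 <- dout * !s$top
  gr <- array(0, c(2, H / 2, 2, W / 2, C))
  gr[1, , 1, , ] <- g12 * s$a
  gr[2, , 1, , ] <- g12 * !s$a
  gr[1, , 2, , ] <- g34 * s$b
  gr[2, , 2, , ] <- g34 * !s$b
  array(gr, d)
}

# 2x2 stride-2 transposed convolution; weights are an array
# (4, C_in, C_out) with the first index enumerating the 2x2 output
# sub-positions in column-major (row offset fastest) order.
tconv_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  xm <- matrix(x, H * Wd, Cin)
  out <- array(0, c(2 * H, 2 * Wd, Cout))
  k <- 1L
  for (bj in 1:2) for (ai in 1:2) {
    y <- sweep(xm %*% matrix(W[k, , ], Cin, Cout), 2, b, "+")
    out[seq(ai, 2 * H, 2), seq(bj, 2 * Wd, 2), ] <- array(y, c(H, Wd, Cout))
    k <- k + 1L
  }
  list(out = out, xm = xm, dims = d)
}

tconv_bwd <- function(cache, W, dout) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  dW <- array(0, dim(W))
  db <- numeric(Cout)
  dxm <- matrix(0, H * Wd, Cin)
  k <- 1L
  for (bj in 1:2) for (ai in 1:2) {
    dy <- matrix(dout[seq(ai, 2 * H, 2), seq(bj, 2 * Wd, 2), ], H * Wd, Cout)
    dW[k, , ] <- crossprod(cache$xm, dy)
    db <- db + colSums(dy)
    dxm <- dxm + tcrossprod(dy, matrix(W[k, , ], Cin, Cout))
    k <- k + 1L
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}
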