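# Native neural-network layer primitives.
#
# Activations are stored as arrays [H, W, N, C] (rows, columns, batch,
# channels): the first three dimensions are contiguous in R's column-major
# order, so a kernel-offset slab reshapes to an (H*W*N) x C matrix without
# copying through aperm, and every convolution becomes k^2 dense matrix
# products executed by BLAS. Kernels are [k, k, C_in, C_out].
#
# Convolutions are stride-1. "Same" convolutions zero-pad (odd kernels);
# transposed convolutions are unpadded and grow the output by k - 1 per
# axis. Batch normalisation uses biased batch statistics with running
# moments for inference.

flat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

conv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  pad <- (k - 1L) %/% 2L
  if (pad > 0) {
    xp <- array(0, c(H + 2 * pad, Wd + 2 * pad, N, Cin))
    xp[pad + 1:H, pad + 1:Wd, , ] <- x
  } else xp <- x
  out <- matrix(0, H * Wd * N, Cout)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    xs <- xp[dy + 1:H, dx + 1:Wd, , , drop = FALSE]
    dim(xs) <- c(H * Wd * N, Cin)
    out <- out + xs %*% matrix(W[dy + 1, dx + 1, , ], Cin, Cout)
  }
  out <- out + rep(b, each = H * Wd * N)
  dim(out) <- c(H, Wd, N, Cout)
  list(out = out, xp = xp)
}

conv_backward <- function(cache, W, dout) {
  xp <- cache$xp
  d <- dim(dout); H <- d[1]; Wd <- d[2]; N <- d[3]; Cout <- d[4]
  k <- dim(W)[1]; Cin <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  dflat <- flat3(dout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    xs <- xp[dy + 1:H, dx + 1:Wd, , , drop = FALSE]
    dim(xs) <- c(H * Wd * N, Cin)
    dW[dy + 1, dx + 1, , ] <- crossprod(xs, dflat)
    dslab <- dflat %*% t(matrix(W[dy + 1, dx + 1, , ], Cin, Cout))
    dim(dslab) <- c(H, Wd, N, Cin)
    dxp[dy + 1:H, dx + 1:Wd, , ] <- dxp[dy + 1:H, dx + 1:Wd, , , drop = FALSE] + dslab
  }
  dx <- if (pad > 0) dxp[pad + 1:H, pad + 1:Wd, , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = colSums(dflat))
}

# Transposed convolution (stride 1, no padding): out[i+dy, j+dx] +=
# x[i, j] W[dy, dx], i.e. a full correlation of the zero-padded input with
# the doubly-flipped kernel. Implemented through the gather/flat-matrix
# accumulation path, which avoids 4-D scatter writes.
tconv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  Ho <- H + k - 1L; Wo <- Wd + k - 1L
  xp <- array(0, c(H + 2 * (k - 1), Wd + 2 * (k - 1), N, Cin))
  xp[(k - 1) + 1:H, (k - 1) + 1:Wd, , ] <- x
  Wf <- W[k:1, k:1, , , drop = FALSE]
  out <- matrix(0, Ho * Wo * N, Cout)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    xs <- xp[dy + 1:Ho, dx + 1:Wo, , , drop = FALSE]
    dim(xs) <- c(Ho * Wo * N, Cin)
    out <- out + xs %*% matrix(Wf[dy + 1, dx + 1, , ], Cin, Cout)
  }
  out <- out + rep(b, each = Ho * Wo * N)
  dim(out) <- c(Ho, Wo, N, Cout)
  list(out = out, x = x, xp = xp)
}

tconv_backward <- function(cache, W, dout) {
  x <- cache$x
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  xf <- flat3(x)
  dW <- array(0, dim(W))
  dxf <- matrix(0, nrow(xf), Cin)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    ds <- dout[dy + 1:H, dx + 1:Wd, , , drop = FALSE]
    dim(ds) <- c(H * Wd * N, Cout)
    dW[dy + 1, dx + 1, , ] <- crossprod(xf, ds)
    dxf <- dxf + ds %*% t(matrix(W[dy + 1, dx + 1, , ], Cin, Cout))
  }
  dim(dxf) <- c(H, Wd, N, Cin)
  list(dx = dxf, dW = dW, db = colSums(flat3(dout)))
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(1:d[1], each = 2), rep(1:d[2], each = 2), , , drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  e <- dout[seq(1, d[1], 2), , , , drop = FALSE] +
    dout[seq(2, d[1], 2), , , , drop = FALSE]
  e[, seq(1, d[2], 2), , , drop = FALSE] + e[, seq(2, d[2], 2), , , drop = FALSE]
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  xf <- flat3(x)
  m <- nrow(xf)
  if (training) {
    mu <- colMeans(xf)
    xc <- xf - rep(mu, each = m)
    v <- colMeans(xc * xc)
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- xf - rep(mu, each = m)
    new_mean <- run_mean; new_var <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * rep(ivar, each = m)
  y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  dim(y) <- d
  list(out = y, xhat = xhat, ivar = ivar, dims = d,
       run_mean = new_mean, run_var = new_var)
}

bn_backward <- function(cache, gamma, dout) {
  d <- cache$dims
  df <- flat3(dout)
  m <- nrow(df)
  xhat <- cache$xhat
  dgamma <- colSums(df * xhat)
  dbeta <- colSums(df)
  dxhat <- df * rep(gamma, each = m)
  dx <- (dxhat - rep(colMeans(dxhat), each = m) -
           xhat * rep(colMeans(dxhat * xhat), each = m)) *
    rep(cache$ivar, each = m)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(cache, dout) dout * cache$mask

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy on logits; returns loss and gradient wrt logits.
bce_with_logits <- function(z, y) {
  p <- sigmoid(z)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  n <- length(z)
  list(loss = -sum(y * log(pc) + (1 - y) * log(1 - pc)) / n,
       dz = (p - y) / n, p = p)
}
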