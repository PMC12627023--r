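# Native neural-network primitives on (C,H,W,N) tensors.
#
# Every layer is a plain list of numeric parameter leaves plus a `meta`
# attribute; forward functions return list(out, cache) (and possibly updated
# batch-norm state), backward functions return list(dx, grads) where `grads`
# mirrors the trainable leaves of the layer. Convolutions are computed as
# im2col + one BLAS GEMM; gradients reuse the cached column matrix.

conv_out_side <- function(in_side, k, s, p) (in_side + 2L * p - k) %/% s + 1L

# He-normal initialisation, fan_in = k*k*cin (ReLU networks).
conv_init <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = FALSE) {
  w <- matrix(rnorm(cout * cin * k * k, sd = sqrt(2 / (k * k * cin))),
              nrow = cout)
  layer <- list(W = w)
  if (bias) layer$b <- numeric(cout)
  attr(layer, "meta") <- list(kind = "conv", k = as.integer(k),
                              stride = as.integer(stride), pad = as.integer(pad),
                              cin = as.integer(cin), cout = as.integer(cout))
  layer
}

# Build the GEMM weight matrix from an explicit (kh, kw, cin, cout) kernel
# array; row order must match cpp_im2col (cin fastest, then dy, then dx).
kernel_to_mat <- function(k4) {
  d <- dim(k4)
  t(matrix(aperm(k4, c(3L, 1L, 2L, 4L)), ncol = d[4L]))
}

conv_fwd <- function(layer, x) {
  m <- attr(layer, "meta")
  d <- dim(x)
  if (d[1L] != m$cin)
    stopf("conv expects %d input channels, got %d", m$cin, d[1L])
  cols <- cpp_im2col(x, d[1L], d[2L], d[3L], d[4L], m$k, m$k,
                     m$stride, m$stride, m$pad, m$pad)
  out <- layer$W %*% cols
  oH <- conv_out_side(d[2L], m$k, m$stride, m$pad)
  oW <- conv_out_side(d[3L], m$k, m$stride, m$pad)
  dim(out) <- c(m$cout, oH, oW, d[4L])
  if (!is.null(layer$b)) out <- out + layer$b
  list(out = out, cache = list(cols = cols, xdim = d))
}

conv_bwd <- function(layer, cache, dout, need_dx = TRUE) {
  m <- attr(layer, "meta")
  d <- cache$xdim
  dm <- dout
  dim(dm) <- c(m$cout, length(dout) %/% m$cout)
  grads <- list(W = tcrossprod(dm, cache$cols))
  if (!is.null(layer$b)) grads$b <- rowSums(dm)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(layer$W, dm)
    dx <- cpp_col2im(dcols, d[1L], d[2L], d[3L], d[4L], m$k, m$k,
                     m$stride, m$stride, m$pad, m$pad)
  }
  list(dx = dx, grads = grads)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_init <- function(C) {
  layer <- list(gamma = rep(1, C), beta = numeric(C),
                run_mean = numeric(C), run_var = rep(1, C))
  attr(layer, "meta") <- list(kind = "bn", C = as.integer(C))
  layer
}

# Per-channel batch norm over (H, W, N). In training mode returns the layer
# with refreshed running statistics (biased variance, momentum 0.1); callers
# must thread the returned `layer` back into their parameter tree.
bn_fwd <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- d[1L]
  xm <- x
  dim(xm) <- c(C, length(x) %/% C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    layer$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean + BN_MOMENTUM * mu
    layer$run_var <- (1 - BN_MOMENTUM) * layer$run_var + BN_MOMENTUM * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * istd
  out <- layer$gamma * xhat + layer$beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, istd = istd, d = d),
       layer = layer)
}

bn_bwd <- function(layer, cache, dout) {
  d <- cache$d
  C <- d[1L]
  dm <- dout
  dim(dm) <- c(C, length(dout) %/% C)
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  dxhat <- layer$gamma * dm
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$istd
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_bwd <- function(cache, dout) {
  dout[!cache] <- 0
  dout
}

leaky_fwd <- function(x, slope = 0.01) {
  mask <- x > 0
  x[!mask] <- x[!mask] * slope
  list(out = x, cache = list(mask = mask, slope = slope))
}

leaky_bwd <- function(cache, dout) {
  dout[!cache$mask] <- dout[!cache$mask] * cache$slope
  dout
}

maxpool_fwd <- function(x, k = 3L, s = 2L, p = 1L) {
  d <- dim(x)
  r <- cpp_maxpool_fwd(x, d[1L], d[2L], d[3L], d[4L], k, s, p)
  list(out = r$out, cache = list(argmax = r$argmax, d = d))
}

maxpool_bwd <- function(cache, dout) {
  d <- cache$d
  cpp_maxpool_bwd(dout, cache$argmax, d[1L], d[2L], d[3L], d[4L])
}

gap_fwd <- function(x) {
  d <- dim(x)
  list(out = cpp_gap(x, d[1L], d[2L], d[3L], d[4L]), cache = d)
}

gap_bwd <- function(cache, dg) {
  cpp_gap_bwd(dg, cache[1L], cache[2L], cache[3L], cache[4L])
}

# Dense layer W: out x in (torch-style uniform init).
linear_init <- function(nin, nout, bias = TRUE) {
  bnd <- 1 / sqrt(nin)
  layer <- list(W = matrix(runif(nout * nin, -bnd, bnd), nrow = nout))
  if (bias) layer$b <- runif(nout, -bnd, bnd)
  attr(layer, "meta") <- list(kind = "linear", nin = as.integer(nin),
                              nout = as.integer(nout))
  layer
}

linear_fwd <- function(layer, x) {
  out <- layer$W %*% x
  if (!is.null(layer$b)) out <- out + layer$b
  list(out = out, cache = x)
}

linear_bwd <- function(layer, cache, dout) {
  grads <- list(W = dout %*% t(cache))
  if (!is.null(layer$b)) grads$b <- rowSums(dout)
  list(dx = crossprod(layer$W, dout), grads = grads)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Channel concatenation along dim 1 of (C,H,W,N) tensors.
chan_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L], da[4L]))
  out[seq_len(da[1L]), , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , ] <- b
  out
}

chan_split <- function(x, c1) {
  d <- dim(x)
  list(x[seq_len(c1), , , , drop = FALSE],
       x[(c1 + 1L):d[1L], , , , drop = FALSE])
}
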