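# Independent brute-force oracles (straight loop transcriptions of the module
# definitions) and small fixture builders. These deliberately share no code
# with the package internals they check.

# Plain loop 2-D convolution on an H x W x Cin image with a
# (kh, kw, cin, cout) kernel, zero padding, stride s.
oracle_conv2d <- function(img, kernel, stride = 1L, pad = 0L) {
  d <- dim(img); kd <- dim(kernel)
  oh <- (d[1] + 2 * pad - kd[1]) %/% stride + 1
  ow <- (d[2] + 2 * pad - kd[2]) %/% stride + 1
  out <- array(0, c(oh, ow, kd[4]))
  for (co in seq_len(kd[4])) for (oy in seq_len(oh)) for (ox in seq_len(ow)) {
    acc <- 0
    for (dy in seq_len(kd[1])) for (dx in seq_len(kd[2])) for (ci in seq_len(kd[3])) {
      y <- (oy - 1) * stride - pad + dy
      x <- (ox - 1) * stride - pad + dx
      if (y >= 1 && y <= d[1] && x >= 1 && x <= d[2])
        acc <- acc + img[y, x, ci] * kernel[dy, dx, ci, co]
    }
    out[oy, ox, co] <- acc
  }
  out
}

# Loop transcription of the dual channel attention: sum, spatial mean,
# zero-padded 1-D conv over channels, sigmoid, channel-wise multiply.
oracle_deca <- function(Ff, Fb, kernel) {
  C <- dim(Ff)[3]
  K <- length(kernel); half <- (K - 1) / 2
  desc <- sapply(seq_len(C), function(c) mean(Ff[, , c] + Fb[, , c]))
  w <- numeric(C)
  for (i in seq_len(C)) {
    acc <- 0
    for (m in seq_len(K)) {
      j <- i + (m - 1) - half
      if (j >= 1 && j <= C) acc <- acc + kernel[m] * desc[j]
    }
    w[i] <- 1 / (1 + exp(-acc))
  }
  front <- Ff; back <- Fb
  for (c in seq_len(C)) {
    front[, , c] <- Ff[, , c] * w[c]
    back[, , c] <- Fb[, , c] * w[c]
  }
  list(front = front, back = back, w = w)
}

# Loop transcription of the multi-scale fusion (pairwise softmax scope),
# operating in evaluation mode (batch norm with given running stats).
oracle_mscff <- function(Ff, Fb, p, leaky_slope = 0.01, eps = 1e-5) {
  C <- dim(Ff)[3]
  H <- dim(Ff)[1]; W <- dim(Ff)[2]
  Y <- array(0, c(H, W, 2 * C))
  Y[, , 1:C] <- Ff; Y[, , C + 1:C] <- Fb
  bn_eval <- function(x, bn) {
    for (c in seq_len(dim(x)[3]))
      x[, , c] <- bn$gamma[c] * (x[, , c] - bn$run_mean[c]) /
        sqrt(bn$run_var[c] + eps) + bn$beta[c]
    x
  }
  lrelu <- function(x) ifelse(x > 0, x, leaky_slope * x)
  Y1 <- lrelu(bn_eval(oracle_conv2d(Y, p$k3, pad = 1), p$bn3))
  Y2 <- lrelu(bn_eval(oracle_conv2d(Y, p$k5, pad = 2), p$bn5))
  S <- c(apply(Y1, 3, mean), apply(Y2, 3, mean))
  z <- pmax(p$w1 %*% S + p$b1, 0)
  sp <- as.numeric(p$w2 %*% z + p$b2)
  s1 <- numeric(2 * C); s2 <- numeric(2 * C)
  for (c in seq_len(2 * C)) {
    e1 <- exp(sp[c]); e2 <- exp(sp[c + 2 * C])
    s1[c] <- e1 / (e1 + e2); s2[c] <- e2 / (e1 + e2)
  }
  O <- Y
  for (c in seq_len(2 * C))
    O[, , c] <- Y[, , c] + s1[c] * Y1[, , c] + s2[c] * Y2[, , c]
  O
}

# Recover the (kh, kw, cin, cout) kernel array from a conv layer's GEMM
# matrix (row order: cin fastest, then dy, then dx — the im2col layout).
mscff_kernel_array <- function(conv_layer, k, cin, cout) {
  aperm(array(t(conv_layer$W), c(cin, k, k, cout)), c(2, 3, 1, 4))
}

# Tiny deterministic image-pair fixtures on disk; returns the manifest path.
make_tiny_manifest <- function(dir, n = 3, side = 32, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- labels %||% seq(20, 80, length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    img <- array(runif(side * side * 3), c(side, side, 3))
    fp <- file.path(dir, sprintf("f%02d.png", i))
    bp <- file.path(dir, sprintf("b%02d.png", i))
    write_image(img, fp)
    write_image(1 - img, bp)
    data.frame(sample_id = sprintf("s%02d", i), front_path = basename(fp),
               back_path = basename(bp), moisture_percent = labels[i],
               stringsAsFactors = FALSE)
  })
  mf <- file.path(dir, "manifest.csv")
  write_manifest(do.call(rbind, rows), mf)
  mf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a nested parameter tree into "path" strings for trainable leaves.
leaf_paths <- function(x, prefix = character()) {
  if (is.numeric(x)) return(paste(prefix, collapse = "/"))
  if (!is.list(x)) return(character())
  keys <- names(x) %||% as.character(seq_along(x))
  out <- character()
  for (i in seq_along(x)) {
    if (keys[i] %in% c("run_mean", "run_var")) next
    out <- c(out, leaf_paths(x[[i]], c(prefix, keys[i])))
  }
  out
}
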