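# Multi-scale convolutional feature fusion.
#
# The stage-5 maps of the two branches are concatenated (2C channels), probed
# by parallel 3x3 and 5x5 conv + BN + LeakyReLU branches (each 2C -> 2C), and
# the two scale branches compete per channel: a squeeze bottleneck (two dense
# layers, reduction ratio r) maps the pooled 4C descriptor to logits, a
# softmax turns them into branch weights, and the weighted branch maps are
# added back onto the concatenated input through a residual connection.

#' Initialise an MSCFF layer
#'
#' @param C Per-branch channel count at stage 5 (the module operates on the
#'   `2C`-channel concatenation).
#' @param r Reduction ratio of the squeeze bottleneck (default 16); `4C` must
#'   be divisible by `r`.
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param softmax_scope `"pair"` (default): softmax across the two scale
#'   branches separately for every channel, so the two weights of a channel
#'   sum to one. `"full"`: one softmax over the whole 4C logit vector.
#' @return Parameter list (two conv banks with batch norm, two dense layers).
#' @export
mscff_init <- function(C, r = 16L, leaky_slope = 0.01,
                       softmax_scope = c("pair", "full")) {
  softmax_scope <- match.arg(softmax_scope)
  if (!is_count(C)) stopf("C must be a positive integer")
  C4 <- 4L * C
  if (C4 %% r != 0L)
    stopf("4C = %d must be divisible by the reduction ratio r = %d", C4, r)
  layer <- list(conv3 = conv_init(2L * C, 2L * C, 3L),
                bn3 = bn_init(2L * C),
                conv5 = conv_init(2L * C, 2L * C, 5L),
                bn5 = bn_init(2L * C),
                fc1 = linear_init(C4, C4 %/% r),
                fc2 = linear_init(C4 %/% r, C4))
  # squeeze biases start at zero so an untrained layer weighs branches evenly
  layer$fc1$b[] <- 0
  layer$fc2$b[] <- 0
  attr(layer, "meta") <- list(kind = "mscff", C = as.integer(C),
                              r = as.integer(r), leaky_slope = leaky_slope,
                              softmax_scope = softmax_scope)
  layer
}

#' Softmax branch weights from squeeze logits
#'
#' Splits the length-`4C` logit vector into the 3x3 and 5x5 halves and
#' normalises them with a softmax. Under the default pairwise scope,
#' `S1[c] + S2[c] = 1` exactly for every channel.
#'
#' @param s_prime Numeric vector of length `4C` (or a `4C x N` matrix).
#' @param scope `"pair"` or `"full"`, see [mscff_init()].
#' @return List with `S1` and `S2`, each of length `2C` (entries in (0, 1)).
#' @export
branch_weights <- function(s_prime, scope = c("pair", "full")) {
  scope <- match.arg(scope)
  vec <- is.null(dim(s_prime))
  sp <- if (vec) matrix(s_prime, ncol = 1L) else s_prime
  n4 <- nrow(sp)
  if (n4 %% 2L != 0L) stopf("logit length must be even, got %d", n4)
  C2 <- n4 %/% 2L
  a <- sp[seq_len(C2), , drop = FALSE]
  b <- sp[C2 + seq_len(C2), , drop = FALSE]
  if (scope == "pair") {
    mx <- pmax(a, b)
    ea <- exp(a - mx); eb <- exp(b - mx)
    s1 <- ea / (ea + eb); s2 <- eb / (ea + eb)
  } else {
    mx <- matrix(apply(sp, 2L, max), n4, ncol(sp), byrow = TRUE)
    e <- exp(sp - mx)
    sm <- sweep(e, 2L, colSums(e), "/")
    s1 <- sm[seq_len(C2), , drop = FALSE]
    s2 <- sm[C2 + seq_len(C2), , drop = FALSE]
  }
  if (vec) list(S1 = as.numeric(s1), S2 = as.numeric(s2))
  else list(S1 = s1, S2 = s2)
}

mscff_fwd_chw <- function(layer, Ff, Fb, training = FALSE) {
  check_same_shape(Ff, Fb, "MSCFF branch inputs")
  m <- attr(layer, "meta")
  if (dim(Ff)[1L] != m$C)
    stopf("MSCFF layer built for C = %d per branch, got %d", m$C, dim(Ff)[1L])
  Y <- chan_concat(Ff, Fb)
  c3 <- conv_fwd(layer$conv3, Y); b3 <- bn_fwd(layer$bn3, c3$out, training)
  layer$bn3 <- b3$layer
  l3 <- leaky_fwd(b3$out, m$leaky_slope)
  c5 <- conv_fwd(layer$conv5, Y); b5 <- bn_fwd(layer$bn5, c5$out, training)
  layer$bn5 <- b5$layer
  l5 <- leaky_fwd(b5$out, m$leaky_slope)
  Yhat <- chan_concat(l3$out, l5$out)
  g <- gap_fwd(Yhat)
  f1 <- linear_fwd(layer$fc1, g$out)
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(layer$fc2, r1$out)
  bw <- branch_weights(f2$out, m$softmax_scope)
  d <- dim(Y)
  O <- Y + cpp_chanmul(l3$out, bw$S1, d[1L], d[2L], d[3L], d[4L]) +
    cpp_chanmul(l5$out, bw$S2, d[1L], d[2L], d[3L], d[4L])
  list(out = O, layer = layer,
       cache = list(c3 = c3$cache, b3 = b3$cache, l3 = l3$cache, y1 = l3$out,
                    c5 = c5$cache, b5 = b5$cache, l5 = l5$cache, y2 = l5$out,
                    g = g$cache, gin = g$out, f1 = f1$cache, r1 = r1$cache,
                    f2 = f2$cache, S1 = bw$S1, S2 = bw$S2, d = d))
}

mscff_bwd_chw <- function(layer, cache, dO) {
  m <- attr(layer, "meta")
  d <- cache$d
  dY <- dO
  dS1 <- cpp_chansum_prod(dO, cache$y1, d[1L], d[2L], d[3L], d[4L])
  dS2 <- cpp_chansum_prod(dO, cache$y2, d[1L], d[2L], d[3L], d[4L])
  dy1 <- cpp_chanmul(dO, cache$S1, d[1L], d[2L], d[3L], d[4L])
  dy2 <- cpp_chanmul(dO, cache$S2, d[1L], d[2L], d[3L], d[4L])
  # softmax backward on the branch logits
  if (m$softmax_scope == "pair") {
    da <- cache$S1 * cache$S2 * (dS1 - dS2)
    dsp <- rbind(da, -da)
  } else {
    sm <- rbind(cache$S1, cache$S2)
    dsm <- rbind(dS1, dS2)
    dsp <- sm * (dsm - matrix(colSums(sm * dsm), nrow(sm), ncol(sm), byrow = TRUE))
  }
  f2b <- linear_bwd(layer$fc2, cache$f2, dsp)
  dr1 <- relu_bwd(cache$r1, f2b$dx)
  f1b <- linear_bwd(layer$fc1, cache$f1, dr1)
  dYhat <- gap_bwd(cache$g, f1b$dx)  # 4C channels; split into the 2C halves
  halves <- chan_split(dYhat, d[1L])
  dy1 <- dy1 + halves[[1L]]
  dy2 <- dy2 + halves[[2L]]
  b3b <- bn_bwd(layer$bn3, cache$b3, leaky_bwd(cache$l3, dy1))
  c3b <- conv_bwd(layer$conv3, cache$c3, b3b$dx)
  b5b <- bn_bwd(layer$bn5, cache$b5, leaky_bwd(cache$l5, dy2))
  c5b <- conv_bwd(layer$conv5, cache$c5, b5b$dx)
  dY <- dY + c3b$dx + c5b$dx
  parts <- chan_split(dY, d[1L] %/% 2L)
  list(dFf = parts[[1L]], dFb = parts[[2L]],
       grads = list(conv3 = c3b$grads, bn3 = b3b$grads,
                    conv5 = c5b$grads, bn5 = b5b$grads,
                    fc1 = f1b$grads, fc2 = f2b$grads))
}

#' Multi-scale convolutional feature fusion forward pass
#'
#' Concatenates the two branch maps along channels, extracts 3x3 and 5x5
#' scale branches (conv + BN + LeakyReLU, each `2C -> 2C`), weighs the two
#' branches per channel with softmax weights derived from a pooled squeeze
#' bottleneck, and adds the weighted branches back onto the concatenation.
#' Spatial size is never altered; the output has exactly `2C` channels.
#'
#' @param Ff,Fb `H x W x C` stage-5 feature maps (or `H x W x C x N`).
#' @param params MSCFF layer from [mscff_init()].
#' @param training Batch-norm mode (default `FALSE`: running statistics).
#' @return Fused `H x W x 2C` feature map.
#' @export
mscff_forward <- function(Ff, Fb, params, training = FALSE) {
  check_same_shape(Ff, Fb, "MSCFF branch inputs")
  single <- length(dim(Ff)) == 3L
  r <- mscff_fwd_chw(params, hwc_to_chw(Ff), hwc_to_chw(Fb), training)
  chw_to_hwc(r$out, drop_n = single)
}
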