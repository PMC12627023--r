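# Dual efficient channel attention.
#
# The two branches' same-stage feature maps are summed, globally average
# pooled to a per-channel descriptor, convolved along the channel axis with a
# short adaptive 1-D kernel (zero padding, no bias), squashed by a sigmoid,
# and the resulting weights multiply BOTH branches channel-wise. One weight
# vector per sample; the module adds only K parameters per stage.

#' Adaptive 1-D kernel size for channel attention
#'
#' `t = trunc((log2(C) + b) / gamma)`; the kernel size is `t` if odd,
#' otherwise `t + 1` (never below 1). With the defaults `gamma = 2, b = 1`:
#' C = 64 gives 3, C = 128/256/512 give 5.
#'
#' @param C Number of channels (positive integer).
#' @param gamma,b Rule constants (defaults 2 and 1).
#' @return Odd positive integer kernel size.
#' @export
adaptive_kernel_size <- function(C, gamma = 2, b = 1) {
  if (!is_count(C)) stopf("C must be a positive integer")
  t <- trunc((log2(C) + b) / gamma)
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(1, k))
}

#' Initialise a DECA layer for C channels
#'
#' @param C Channel count of the stage the layer attends over.
#' @param gamma,b Kernel-size rule constants, see [adaptive_kernel_size()].
#' @return Parameter list with the length-K 1-D convolution weights (no bias).
#' @export
deca_init <- function(C, gamma = 2, b = 1) {
  K <- adaptive_kernel_size(C, gamma, b)
  bnd <- 1 / sqrt(K)
  layer <- list(conv = runif(K, -bnd, bnd))
  attr(layer, "meta") <- list(kind = "deca", C = as.integer(C), K = K,
                              gamma = gamma, b = b)
  layer
}

# Banded C x C matrix realising the zero-padded 1-D convolution.
deca_toeplitz <- function(kernel, C) {
  K <- length(kernel)
  half <- (K - 1L) %/% 2L
  tp <- matrix(0, C, C)
  off <- col(tp) - row(tp)
  sel <- abs(off) <= half
  tp[sel] <- kernel[off[sel] + half + 1L]
  tp
}

deca_fwd_chw <- function(layer, Ff, Fb) {
  check_same_shape(Ff, Fb, "DECA branch inputs")
  m <- attr(layer, "meta")
  d <- dim(Ff)
  if (d[1L] != m$C) stopf("DECA layer built for C = %d, got %d", m$C, d[1L])
  P <- Ff + Fb
  g <- gap_fwd(P)
  tp <- deca_toeplitz(layer$conv, m$C)
  w <- sigmoid(tp %*% g$out)
  Ffh <- cpp_chanmul(Ff, w, d[1L], d[2L], d[3L], d[4L])
  Fbh <- cpp_chanmul(Fb, w, d[1L], d[2L], d[3L], d[4L])
  list(front = Ffh, back = Fbh, w = w,
       cache = list(desc = g$out, gcache = g$cache, tp = tp, w = w,
                    Ff = Ff, Fb = Fb, d = d))
}

deca_bwd_chw <- function(layer, cache, dFfh, dFbh) {
  d <- cache$d
  w <- cache$w
  dw <- cpp_chansum_prod(dFfh, cache$Ff, d[1L], d[2L], d[3L], d[4L]) +
    cpp_chansum_prod(dFbh, cache$Fb, d[1L], d[2L], d[3L], d[4L])
  dpre <- dw * w * (1 - w)
  ddesc <- crossprod(cache$tp, dpre)
  K <- length(layer$conv)
  half <- (K - 1L) %/% 2L
  C <- d[1L]
  dk <- numeric(K)
  for (mm in seq_len(K)) {
    sh <- mm - 1L - half              # out[i] uses in[i + sh]
    i <- max(1L, 1L - sh):min(C, C - sh)
    dk[mm] <- sum(dpre[i, , drop = FALSE] * cache$desc[i + sh, , drop = FALSE])
  }
  dP <- gap_bwd(cache$gcache, ddesc)
  dFf <- cpp_chanmul(dFfh, w, d[1L], d[2L], d[3L], d[4L]) + dP
  dFb <- cpp_chanmul(dFbh, w, d[1L], d[2L], d[3L], d[4L]) + dP
  list(dFf = dFf, dFb = dFb, grads = list(conv = dk))
}

#' Dual efficient channel attention forward pass
#'
#' Fuses the two branches' feature maps by element-wise addition, derives a
#' shared per-channel weight vector (global average pool, adaptive-kernel 1-D
#' convolution with zero padding and no bias, sigmoid), and reweights both
#' branches channel-wise. Weights lie strictly in (0, 1); swapping the inputs
#' leaves the weights unchanged and swaps the outputs.
#'
#' @param Ff,Fb `H x W x C` feature maps (or `H x W x C x N` batches) of the
#'   front and back branches at the same stage.
#' @param params DECA layer from [deca_init()]; its kernel length must equal
#'   `adaptive_kernel_size(C)` for the layer's channel count.
#' @return List with `front`, `back` (reweighted maps, same shape as the
#'   inputs) and `w` (length-C weights; `C x N` matrix for batches).
#' @export
deca_forward <- function(Ff, Fb, params) {
  check_same_shape(Ff, Fb, "DECA branch inputs")
  single <- length(dim(Ff)) == 3L
  r <- deca_fwd_chw(params, hwc_to_chw(Ff), hwc_to_chw(Fb))
  w <- if (single) as.numeric(r$w) else r$w
  list(front = chw_to_hwc(r$front, drop_n = single),
       back = chw_to_hwc(r$back, drop_n = single), w = w)
}
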