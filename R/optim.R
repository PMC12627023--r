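# Adam optimiser. Gradient trees mirror the trainable leaves of the parameter
# tree (batch-norm running statistics never appear in gradients and are never
# touched). For speed the update itself is vectorised over one flat parameter
# vector; the tree is re-materialised by a structural walk of the gradient
# skeleton, whose depth-first order matches `unlist()`.

adam_init <- function() list(t = 0L, w = NULL, m = NULL, v = NULL)

ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-8

# Collect the param leaves addressed by the gradient skeleton, in its order.
gather_by_skeleton <- function(p, g) {
  if (is.numeric(g)) return(list(p))
  keys <- names(g) %||% seq_along(g)
  out <- list()
  for (k in keys) out <- c(out, gather_by_skeleton(p[[k]], g[[k]]))
  out
}

# Write the flat vector back into the parameter tree along the skeleton.
scatter_by_skeleton <- function(p, g, w, pos) {
  if (is.numeric(g)) {
    len <- length(g)
    leaf <- w[pos$i + seq_len(len)]
    dim(leaf) <- dim(g)
    pos$i <- pos$i + len
    return(leaf)
  }
  keys <- names(g) %||% seq_along(g)
  for (k in keys) p[[k]] <- scatter_by_skeleton(p[[k]], g[[k]], w, pos)
  p
}

# One Adam update; returns list(params, state).
adam_step <- function(params, grads, state, lr) {
  g <- unlist(grads, use.names = FALSE)
  if (is.null(state$w)) {
    state$w <- unlist(gather_by_skeleton(params, grads), use.names = FALSE)
    state$m <- numeric(length(g))
    state$v <- numeric(length(g))
  }
  state$t <- state$t + 1L
  alpha <- lr * sqrt(1 - ADAM_BETA2^state$t) / (1 - ADAM_BETA1^state$t)
  cpp_adam_update(state$w, state$m, state$v, g, alpha, ADAM_BETA1, ADAM_BETA2,
                  ADAM_EPS)
  pos <- new.env(parent = emptyenv())
  pos$i <- 0L
  params <- scatter_by_skeleton(params, grads, state$w, pos)
  list(params = params, state = state)
}
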