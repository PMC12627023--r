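# Internal helpers: seeded RNG scoping, tensor layout conversion, validation.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so library calls never perturb user code.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed < 2^31 from a base seed and an index.
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 9973) %% 2147483629) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# User-facing images/features are H x W x C arrays (optionally x N); the
# compiled kernels use C x H x W x N. Both converters accept either rank.
hwc_to_chw <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    y <- aperm(x, c(3L, 1L, 2L))
    dim(y) <- c(d[3L], d[1L], d[2L], 1L)
  } else if (length(d) == 4L) {
    y <- aperm(x, c(3L, 1L, 2L, 4L))
  } else stopf("expected a rank-3 or rank-4 array, got rank %d", length(d))
  y
}

chw_to_hwc <- function(x, drop_n = TRUE) {
  d <- dim(x)
  y <- aperm(x, c(2L, 3L, 1L, 4L))
  if (drop_n && d[4L] == 1L) dim(y) <- d[c(2L, 3L, 1L)]
  y
}

check_same_shape <- function(a, b, what = "feature maps") {
  if (!identical(dim(a), dim(b)))
    stopf("%s must share the same shape (got %s vs %s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}
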