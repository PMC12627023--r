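# Residual feature-extraction backbone (depths 18/34/50/101).
#
# Stage numbering follows the conv2_x..conv5_x convention: stage 1 is the
# stem (7x7/2 conv + BN + ReLU + 3x3/2 max pool), stages 2-5 are the four
# residual block groups; spatial side halves per stage from stage 3 on and
# channel width doubles. Two independent instances of these parameters form
# the front and back branches of the dual network.

BLOCK_PLANS <- list(
  `18` = list(blocks = c(2L, 2L, 2L, 2L), kind = "basic"),
  `34` = list(blocks = c(3L, 4L, 6L, 3L), kind = "basic"),
  `50` = list(blocks = c(3L, 4L, 6L, 3L), kind = "bottleneck"),
  `101` = list(blocks = c(3L, 4L, 23L, 3L), kind = "bottleneck")
)

#' Backbone configuration
#'
#' @param depth One of 18, 34, 50, 101. Depths 18/34 use basic residual
#'   blocks (expansion 1), 50/101 bottleneck blocks (expansion 4).
#' @param base_width Channel width of stage 2 before expansion (default 64,
#'   the standard model; smaller values give slim CPU-scale profiles).
#' @param pretrained Reserved flag; random He initialisation is the default
#'   and no downloaded weights are required anywhere in the package.
#' @return List of class `backbone_config` with derived stage widths.
#' @export
backbone_config <- function(depth = 18L, base_width = 64L, pretrained = FALSE) {
  key <- as.character(depth)
  if (!key %in% names(BLOCK_PLANS)) stopf("depth must be one of 18/34/50/101")
  if (!is_count(base_width, 2L)) stopf("base_width must be a positive integer")
  plan <- BLOCK_PLANS[[key]]
  expansion <- if (plan$kind == "basic") 1L else 4L
  planes <- as.integer(base_width * c(1L, 2L, 4L, 8L))
  structure(list(depth = as.integer(depth), base_width = as.integer(base_width),
                 block_kind = plan$kind, blocks = plan$blocks,
                 expansion = expansion, planes = planes,
                 stage_channels = planes * expansion,
                 pretrained = isTRUE(pretrained)),
            class = "backbone_config")
}

#' Per-stage output shapes for a square input
#'
#' @param cfg A [backbone_config()].
#' @param side Input side in pixels (must be divisible by 32).
#' @return Data frame with stage, side and channels columns.
#' @export
stage_shape_plan <- function(cfg, side = 224L) {
  if (side %% 32L != 0L) stopf("input side must be divisible by 32, got %d", side)
  data.frame(stage = 2:5, side = as.integer(side / c(4L, 8L, 16L, 32L)),
             channels = cfg$stage_channels)
}

basic_block_init <- function(cin, planes, stride) {
  bl <- list(conv1 = conv_init(cin, planes, 3L, stride = stride),
             bn1 = bn_init(planes),
             conv2 = conv_init(planes, planes, 3L),
             bn2 = bn_init(planes))
  if (stride != 1L || cin != planes) {
    bl$down_conv <- conv_init(cin, planes, 1L, stride = stride, pad = 0L)
    bl$down_bn <- bn_init(planes)
  }
  attr(bl, "meta") <- list(kind = "basic")
  bl
}

bottleneck_block_init <- function(cin, planes, stride) {
  cout <- planes * 4L
  bl <- list(conv1 = conv_init(cin, planes, 1L, pad = 0L),
             bn1 = bn_init(planes),
             conv2 = conv_init(planes, planes, 3L, stride = stride),
             bn2 = bn_init(planes),
             conv3 = conv_init(planes, cout, 1L, pad = 0L),
             bn3 = bn_init(cout))
  if (stride != 1L || cin != cout) {
    bl$down_conv <- conv_init(cin, cout, 1L, stride = stride, pad = 0L)
    bl$down_bn <- bn_init(cout)
  }
  attr(bl, "meta") <- list(kind = "bottleneck")
  bl
}

#' Initialise one backbone branch
#'
#' Draws He-initialised parameters from the current RNG stream; wrap in a
#' seeded context for reproducibility (the model constructor does).
#'
#' @param cfg A [backbone_config()].
#' @return Nested parameter list: `stem`, `s2` .. `s5`.
#' @export
backbone_init <- function(cfg) {
  params <- list(stem = list(conv = conv_init(3L, cfg$base_width, 7L,
                                              stride = 2L, pad = 3L),
                             bn = bn_init(cfg$base_width)))
  cin <- cfg$base_width
  for (s in 2:5) {
    planes <- cfg$planes[s - 1L]
    nblocks <- cfg$blocks[s - 1L]
    stage <- vector("list", nblocks)
    for (b in seq_len(nblocks)) {
      stride <- if (s > 2L && b == 1L) 2L else 1L
      stage[[b]] <- if (cfg$block_kind == "basic")
        basic_block_init(cin, planes, stride)
      else bottleneck_block_init(cin, planes, stride)
      cin <- planes * cfg$expansion
    }
    params[[paste0("s", s)]] <- stage
  }
  params
}

block_fwd <- function(bl, x, training = FALSE) {
  kind <- attr(bl, "meta")$kind
  c1 <- conv_fwd(bl$conv1, x); b1 <- bn_fwd(bl$bn1, c1$out, training)
  bl$bn1 <- b1$layer
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(bl$conv2, r1$out); b2 <- bn_fwd(bl$bn2, c2$out, training)
  bl$bn2 <- b2$layer
  if (kind == "basic") {
    main <- b2$out
    cache <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                  c2 = c2$cache, b2 = b2$cache)
  } else {
    r2 <- relu_fwd(b2$out)
    c3 <- conv_fwd(bl$conv3, r2$out); b3 <- bn_fwd(bl$bn3, c3$out, training)
    bl$bn3 <- b3$layer
    main <- b3$out
    cache <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                  c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                  c3 = c3$cache, b3 = b3$cache)
  }
  if (!is.null(bl$down_conv)) {
    dc <- conv_fwd(bl$down_conv, x); db <- bn_fwd(bl$down_bn, dc$out, training)
    bl$down_bn <- db$layer
    sc <- db$out
    cache$dc <- dc$cache; cache$db <- db$cache
  } else sc <- x
  ro <- relu_fwd(main + sc)
  cache$ro <- ro$cache
  list(out = ro$out, cache = cache, block = bl)
}

block_bwd <- function(bl, cache, dout) {
  kind <- attr(bl, "meta")$kind
  d <- relu_bwd(cache$ro, dout)
  grads <- list()
  if (kind == "basic") {
    b2b <- bn_bwd(bl$bn2, cache$b2, d)
    c2b <- conv_bwd(bl$conv2, cache$c2, b2b$dx)
    dr1 <- relu_bwd(cache$r1, c2b$dx)
    b1b <- bn_bwd(bl$bn1, cache$b1, dr1)
    c1b <- conv_bwd(bl$conv1, cache$c1, b1b$dx)
    dx <- c1b$dx
    grads$conv1 <- c1b$grads; grads$bn1 <- b1b$grads
    grads$conv2 <- c2b$grads; grads$bn2 <- b2b$grads
  } else {
    b3b <- bn_bwd(bl$bn3, cache$b3, d)
    c3b <- conv_bwd(bl$conv3, cache$c3, b3b$dx)
    dr2 <- relu_bwd(cache$r2, c3b$dx)
    b2b <- bn_bwd(bl$bn2, cache$b2, dr2)
    c2b <- conv_bwd(bl$conv2, cache$c2, b2b$dx)
    dr1 <- relu_bwd(cache$r1, c2b$dx)
    b1b <- bn_bwd(bl$bn1, cache$b1, dr1)
    c1b <- conv_bwd(bl$conv1, cache$c1, b1b$dx)
    dx <- c1b$dx
    grads$conv1 <- c1b$grads; grads$bn1 <- b1b$grads
    grads$conv2 <- c2b$grads; grads$bn2 <- b2b$grads
    grads$conv3 <- c3b$grads; grads$bn3 <- b3b$grads
  }
  if (!is.null(bl$down_conv)) {
    dbb <- bn_bwd(bl$down_bn, cache$db, d)
    dcb <- conv_bwd(bl$down_conv, cache$dc, dbb$dx)
    dx <- dx + dcb$dx
    grads$down_conv <- dcb$grads; grads$down_bn <- dbb$grads
  } else dx <- dx + d
  list(dx = dx, grads = grads)
}

stem_fwd <- function(params, x, training = FALSE) {
  cv <- conv_fwd(params$stem$conv, x)
  bn <- bn_fwd(params$stem$bn, cv$out, training)
  params$stem$bn <- bn$layer
  rl <- relu_fwd(bn$out)
  mp <- maxpool_fwd(rl$out)
  list(out = mp$out,
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache, mp = mp$cache),
       params = params)
}

stem_bwd <- function(params, cache, dout) {
  dmp <- maxpool_bwd(cache$mp, dout)
  drl <- relu_bwd(cache$rl, dmp)
  bnb <- bn_bwd(params$stem$bn, cache$bn, drl)
  # the gradient wrt the input image is never used, skip its GEMM + col2im
  cvb <- conv_bwd(params$stem$conv, cache$cv, bnb$dx, need_dx = FALSE)
  list(dx = NULL, grads = list(stem = list(conv = cvb$grads, bn = bnb$grads)))
}

stage_fwd <- function(stage, x, training = FALSE) {
  caches <- vector("list", length(stage))
  for (b in seq_along(stage)) {
    r <- block_fwd(stage[[b]], x, training)
    x <- r$out
    caches[[b]] <- r$cache
    stage[[b]] <- r$block
  }
  list(out = x, cache = caches, stage = stage)
}

stage_bwd <- function(stage, caches, dout) {
  grads <- vector("list", length(stage))
  for (b in rev(seq_along(stage))) {
    r <- block_bwd(stage[[b]], caches[[b]], dout)
    dout <- r$dx
    grads[[b]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

#' Run one branch and expose every stage's feature map
#'
#' @param image `H x W x 3` array (or `H x W x 3 x N` batch), side divisible
#'   by 32, values typically in `[0, 1]`.
#' @param cfg A [backbone_config()].
#' @param params Branch parameters from [backbone_init()].
#' @param training Use batch statistics in batch norm (default `FALSE`:
#'   running statistics; evaluation mode).
#' @return Named list `s2` .. `s5` of `H x W x C` feature maps (each carries a
#'   `stage_id` attribute).
#' @export
extract_stages <- function(image, cfg, params, training = FALSE) {
  d <- dim(image)
  if (d[1L] != d[2L] || d[1L] %% 32L != 0L)
    stopf("input must be square with side divisible by 32, got %dx%d", d[1L], d[2L])
  x <- hwc_to_chw(image)
  st <- stem_fwd(params, x, training)
  out <- list()
  x <- st$out
  for (s in 2:5) {
    r <- stage_fwd(params[[paste0("s", s)]], x, training)
    x <- r$out
    f <- chw_to_hwc(x, drop_n = length(d) == 3L)
    attr(f, "stage_id") <- s
    out[[paste0("s", s)]] <- f
  }
  out
}

#' Apply the next backbone stage to a (possibly reweighted) feature map
#'
#' Feeds a stage-`s` feature map (s in 2..4) through stage `s + 1`,
#' reproducing the uninterrupted pass exactly when the input is unmodified.
#' The channel attention module uses this to re-enter the backbone after
#' reweighting.
#'
#' @param feature `H x W x C` feature map carrying a `stage_id` attribute
#'   (2, 3 or 4), as returned by [extract_stages()].
#' @param cfg A [backbone_config()].
#' @param params Branch parameters.
#' @param stage_id Stage of `feature`; defaults to its `stage_id` attribute.
#' @param training Batch-norm mode as in [extract_stages()].
#' @return The stage `stage_id + 1` feature map (`H x W x C'`).
#' @export
resume_stage <- function(feature, cfg, params, stage_id = NULL,
                         training = FALSE) {
  stage_id <- stage_id %||% attr(feature, "stage_id")
  if (is.null(stage_id) || !stage_id %in% 2:4)
    stopf("stage_id must be 2, 3 or 4")
  x <- hwc_to_chw(feature)
  if (dim(x)[1L] != cfg$stage_channels[stage_id - 1L])
    stopf("feature has %d channels but stage %d outputs %d", dim(x)[1L],
          stage_id, cfg$stage_channels[stage_id - 1L])
  r <- stage_fwd(params[[paste0("s", stage_id + 1L)]], x, training)
  f <- chw_to_hwc(r$out, drop_n = length(dim(feature)) == 3L)
  attr(f, "stage_id") <- stage_id + 1L
  f
}
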