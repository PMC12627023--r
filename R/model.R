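# Full dual-branch regression network: two independent backbones, channel
# attention interventions at configured stages, multi-scale fusion after
# stage 5, global average pooling and a single affine regression head.
# Labels are rescaled by `target_scale` (default 1/100) for optimisation;
# predictions are rescaled back to percent before metrics.

#' Model configuration
#'
#' @param depth Backbone depth: 18, 34, 50 or 101.
#' @param base_width Stage-2 channel width before expansion (64 = standard;
#'   16 gives a slim CPU-scale profile).
#' @param branch_mode `"dual"`, `"front_only"` or `"back_only"`. The channel
#'   attention and fusion modules require `"dual"`.
#' @param deca_stages Integer subset of `2:4`: stages after which the shared
#'   channel attention reweights both branches (one independent parameter set
#'   per stage). Empty vector disables attention.
#' @param mscff_enabled Use multi-scale fusion after stage 5; otherwise the
#'   stage-5 maps are plainly concatenated.
#' @param deca_replace If `TRUE` (default) the reweighted features replace the
#'   branch features fed to the next stage (the interacting reading); `FALSE`
#'   computes but discards the reweighting, for ablation.
#' @param mscff_r Reduction ratio of the fusion squeeze bottleneck.
#' @param softmax_scope `"pair"` or `"full"` branch softmax, see [mscff_init()].
#' @param leaky_slope LeakyReLU negative slope inside the fusion module.
#' @param target_scale Labels are multiplied by this before optimisation
#'   (default 0.01: percent -> `[0, 1]`).
#' @param seed Seed for parameter initialisation.
#' @return List of class `cadff_config` with the derived head input width.
#' @export
model_config <- function(depth = 18L, base_width = 64L,
                         branch_mode = c("dual", "front_only", "back_only"),
                         deca_stages = c(2L, 3L, 4L), mscff_enabled = TRUE,
                         deca_replace = TRUE, mscff_r = 16L,
                         softmax_scope = "pair", leaky_slope = 0.01,
                         target_scale = 0.01, seed = 1L) {
  branch_mode <- match.arg(branch_mode)
  deca_stages <- sort(unique(as.integer(deca_stages)))
  if (length(deca_stages) && !all(deca_stages %in% 2:4))
    stopf("deca_stages must be a subset of {2, 3, 4}")
  if (branch_mode != "dual" && (length(deca_stages) || isTRUE(mscff_enabled)))
    stopf("deca_stages and mscff_enabled require branch_mode = \"dual\"")
  bb <- backbone_config(depth, base_width)
  c5 <- bb$stage_channels[4L]
  head_dim <- if (branch_mode == "dual") 2L * c5 else c5
  structure(list(depth = bb$depth, base_width = bb$base_width,
                 branch_mode = branch_mode, deca_stages = deca_stages,
                 mscff_enabled = isTRUE(mscff_enabled),
                 deca_replace = isTRUE(deca_replace),
                 mscff_r = as.integer(mscff_r), softmax_scope = softmax_scope,
                 leaky_slope = leaky_slope, target_scale = target_scale,
                 seed = as.integer(seed), backbone = bb,
                 head_input_dim = as.integer(head_dim)),
            class = "cadff_config")
}

#' Initialise a model from its configuration
#'
#' All draws come from a stream seeded with `cfg$seed`, so initialisation is
#' reproducible. The two branches never share parameters.
#'
#' @param cfg A [model_config()].
#' @return List of class `cadff_model` with elements `cfg` and `params`.
#' @export
model_init <- function(cfg) {
  params <- with_rng_seed(cfg$seed, {
    p <- list()
    if (cfg$branch_mode != "back_only") p$front <- backbone_init(cfg$backbone)
    if (cfg$branch_mode != "front_only") p$back <- backbone_init(cfg$backbone)
    if (length(cfg$deca_stages)) {
      p$deca <- list()
      for (s in cfg$deca_stages)
        p$deca[[paste0("s", s)]] <- deca_init(cfg$backbone$stage_channels[s - 1L])
    }
    if (cfg$mscff_enabled)
      p$mscff <- mscff_init(cfg$backbone$stage_channels[4L], r = cfg$mscff_r,
                            leaky_slope = cfg$leaky_slope,
                            softmax_scope = cfg$softmax_scope)
    p$head <- linear_init(cfg$head_input_dim, 1L)
    p
  })
  structure(list(cfg = cfg, params = params), class = "cadff_model")
}

# Internal forward on (C,H,W,N) tensors. Returns scaled predictions (1 x N),
# caches for backward, and the model with refreshed batch-norm state.
model_fwd_chw <- function(model, xf, xb, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  caches <- list(deca = list(), stages_f = list(), stages_b = list())
  use_f <- cfg$branch_mode != "back_only"
  use_b <- cfg$branch_mode != "front_only"
  if (use_f) {
    r <- stem_fwd(p$front, xf, training); p$front <- r$params
    caches$stem_f <- r$cache; xf <- r$out
  }
  if (use_b) {
    r <- stem_fwd(p$back, xb, training); p$back <- r$params
    caches$stem_b <- r$cache; xb <- r$out
  }
  for (s in 2:5) {
    key <- paste0("s", s)
    if (use_f) {
      r <- stage_fwd(p$front[[key]], xf, training)
      p$front[[key]] <- r$stage; caches$stages_f[[key]] <- r$cache; xf <- r$out
    }
    if (use_b) {
      r <- stage_fwd(p$back[[key]], xb, training)
      p$back[[key]] <- r$stage; caches$stages_b[[key]] <- r$cache; xb <- r$out
    }
    if (s %in% cfg$deca_stages) {
      r <- deca_fwd_chw(p$deca[[key]], xf, xb)
      caches$deca[[key]] <- r$cache
      if (cfg$deca_replace) { xf <- r$front; xb <- r$back }
    }
  }
  if (cfg$branch_mode == "dual") {
    if (cfg$mscff_enabled) {
      r <- mscff_fwd_chw(p$mscff, xf, xb, training)
      p$mscff <- r$layer; caches$mscff <- r$cache
      fused <- r$out
    } else fused <- chan_concat(xf, xb)
  } else fused <- if (use_f) xf else xb
  g <- gap_fwd(fused)
  caches$gap <- g$cache
  h <- linear_fwd(p$head, g$out)
  caches$head <- h$cache
  model$params <- p
  list(pred = h$out, caches = caches, model = model)
}

# Internal backward; dpred is 1 x N on the scaled-target scale.
model_bwd_chw <- function(model, caches, dpred) {
  cfg <- model$cfg
  p <- model$params
  grads <- list()
  hb <- linear_bwd(p$head, caches$head, dpred)
  grads$head <- hb$grads
  dfused <- gap_bwd(caches$gap, hb$dx)
  use_f <- cfg$branch_mode != "back_only"
  use_b <- cfg$branch_mode != "front_only"
  if (cfg$branch_mode == "dual") {
    if (cfg$mscff_enabled) {
      mb <- mscff_bwd_chw(p$mscff, caches$mscff, dfused)
      grads$mscff <- mb$grads
      dxf <- mb$dFf; dxb <- mb$dFb
    } else {
      parts <- chan_split(dfused, dim(dfused)[1L] %/% 2L)
      dxf <- parts[[1L]]; dxb <- parts[[2L]]
    }
  } else if (use_f) { dxf <- dfused; dxb <- NULL } else { dxb <- dfused; dxf <- NULL }
  if (use_f) grads$front <- list()
  if (use_b) grads$back <- list()
  if (length(cfg$deca_stages)) grads$deca <- list()
  for (s in 5:2) {
    key <- paste0("s", s)
    if (use_f) {
      r <- stage_bwd(p$front[[key]], caches$stages_f[[key]], dxf)
      grads$front[[key]] <- r$grads; dxf <- r$dx
    }
    if (use_b) {
      r <- stage_bwd(p$back[[key]], caches$stages_b[[key]], dxb)
      grads$back[[key]] <- r$grads; dxb <- r$dx
    }
    sprev <- s - 1L
    if (sprev %in% cfg$deca_stages && cfg$deca_replace) {
      kp <- paste0("s", sprev)
      r <- deca_bwd_chw(p$deca[[kp]], caches$deca[[kp]], dxf, dxb)
      grads$deca[[kp]] <- r$grads
      dxf <- r$dFf; dxb <- r$dFb
    }
  }
  if (use_f) {
    r <- stem_bwd(p$front, caches$stem_f, dxf)
    grads$front$stem <- r$grads$stem
  }
  if (use_b) {
    r <- stem_bwd(p$back, caches$stem_b, dxb)
    grads$back$stem <- r$grads$stem
  }
  grads
}

#' Predict moisture content for image pairs
#'
#' Runs the assembled network on one pair or a batch and returns predictions
#' on the percent scale (internal optimisation happens on
#' `target_scale`-scaled labels).
#'
#' @param model A `cadff_model`.
#' @param front,back `H x W x 3` arrays (or `H x W x 3 x N` batches); the
#'   unused view may be `NULL` in single-branch modes.
#' @param training Batch-norm mode; prediction normally uses `FALSE`.
#' @return Numeric vector of predicted moisture percentages.
#' @export
model_forward <- function(model, front, back = NULL, training = FALSE) {
  if (is.list(front) && !is.null(front$front)) {  # an ImagePair-style list
    back <- front$back; front <- front$front
  }
  xf <- if (!is.null(front)) hwc_to_chw(front) else NULL
  xb <- if (!is.null(back)) hwc_to_chw(back) else NULL
  if (model$cfg$branch_mode != "back_only" && is.null(xf))
    stopf("branch_mode %s requires a front image", model$cfg$branch_mode)
  if (model$cfg$branch_mode != "front_only" && is.null(xb))
    stopf("branch_mode %s requires a back image", model$cfg$branch_mode)
  r <- model_fwd_chw(model, xf, xb, training)
  as.numeric(r$pred) / model$cfg$target_scale
}

#' Mean squared error loss
#'
#' @param y_hat,y Equal-length numeric vectors of predictions and targets.
#' @return `mean((y_hat - y)^2)`.
#' @export
mse_loss <- function(y_hat, y) {
  if (length(y_hat) == 0L || length(y_hat) != length(y))
    stopf("y_hat and y must be nonempty vectors of equal length")
  mean((y_hat - y)^2)
}

count_trainable <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (!is.list(x)) return(0L)
  total <- 0L
  keys <- names(x) %||% rep("", length(x))
  for (i in seq_along(x)) {
    if (keys[i] %in% c("run_mean", "run_var")) next
    total <- total + count_trainable(x[[i]])
  }
  total
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (batch-norm running statistics excluded),
#' decomposed per top-level module.
#'
#' @param model A `cadff_model`, or a `cadff_config` (which is initialised
#'   temporarily just to count).
#' @return List with `total` and a named `modules` vector.
#' @export
parameter_count <- function(model) {
  if (inherits(model, "cadff_config")) model <- model_init(model)
  mods <- vapply(model$params, count_trainable, integer(1L))
  list(total = sum(mods), modules = mods)
}

#' Save / load a model checkpoint
#'
#' Stores the configuration and all parameters (including batch-norm running
#' statistics) in one RDS file, so evaluation is self-describing.
#'
#' @param model A `cadff_model`.
#' @param path Destination file.
#' @return `path` (save) or the restored `cadff_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(cfg = structure(x$cfg, class = "cadff_config"),
                 params = x$params), class = "cadff_model")
}
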