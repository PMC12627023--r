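# Metrics, training loop, k-fold cross-validation and ablation grids.

#' Coefficient of determination
#'
#' `1 - sum((y_hat - y)^2) / sum((mean(y) - y)^2)`. Can be negative for
#' predictors worse than the mean; errors if `y` is constant (undefined
#' denominator).
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @return R-squared.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat))
    stopf("y and y_hat must be nonempty vectors of equal length")
  sstot <- sum((mean(y) - y)^2)
  if (sstot == 0) stopf("y is constant; R^2 denominator is zero")
  1 - sum((y_hat - y)^2) / sstot
}

#' Root-mean-square error
#' @inheritParams r_squared
#' @return RMSE on the scale of `y` (percent for moisture labels).
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat))
    stopf("y and y_hat must be nonempty vectors of equal length")
  sqrt(mean((y_hat - y)^2))
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return MAE on the scale of `y`.
#' @export
mae <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat))
    stopf("y and y_hat must be nonempty vectors of equal length")
  mean(abs(y_hat - y))
}

#' Training configuration
#'
#' Defaults follow the regression protocol: Adam, batch size 16, initial
#' learning rate 1e-4, fixed-epoch training with the best-validation-MAE
#' checkpoint retained.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Seed controlling mini-batch shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L, epochs = 30L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, is_count(batch_size), is_count(epochs, 0L))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Materialise records as an in-memory dataset
#'
#' @param x A manifest data frame (see [load_manifest()]) or an existing
#'   `leaf_dataset`, which is returned unchanged.
#' @param side_px Image side used when decoding records.
#' @return A `leaf_dataset` (`front`/`back` `H x W x 3 x N` arrays, `labels`).
#' @export
as_dataset <- function(x, side_px = 224L) {
  if (inherits(x, "leaf_dataset")) return(x)
  if (!is.data.frame(x)) stopf("expected a manifest data frame or leaf_dataset")
  n <- nrow(x)
  front <- array(0, c(side_px, side_px, 3L, n))
  back <- array(0, c(side_px, side_px, 3L, n))
  labels <- numeric(n)
  for (i in seq_len(n)) {
    p <- load_pair(x[i, ], side_px)
    front[, , , i] <- p$front
    back[, , , i] <- p$back
    labels[i] <- p$label
  }
  structure(list(front = front, back = back, labels = labels,
                 ids = as.character(x$sample_id)),
            class = "leaf_dataset")
}

dataset_n <- function(ds) length(ds$labels)

#' Subset a dataset by sample indices
#' @param ds A `leaf_dataset`.
#' @param idx Integer indices.
#' @return The subsetted `leaf_dataset`.
#' @export
dataset_slice <- function(ds, idx) {
  structure(list(front = ds$front[, , , idx, drop = FALSE],
                 back = ds$back[, , , idx, drop = FALSE],
                 labels = ds$labels[idx], ids = ds$ids[idx]),
            class = "leaf_dataset")
}

#' Evaluate a model on a dataset
#'
#' Predictions run in evaluation mode (batch-norm running statistics frozen)
#' and are rescaled to percent before metrics.
#'
#' @param model A `cadff_model`.
#' @param ds A `leaf_dataset`.
#' @param batch_size Evaluation batch size (memory knob only).
#' @return List of class `metrics_report`: `r2`, `rmse_percent`,
#'   `mae_percent`, `n`, plus the raw `predictions` and `labels`.
#' @export
evaluate_model <- function(model, ds, batch_size = 32L) {
  n <- dataset_n(ds)
  preds <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    preds[idx] <- model_forward(model,
                                ds$front[, , , idx, drop = FALSE],
                                ds$back[, , , idx, drop = FALSE])
  }
  structure(list(r2 = r_squared(ds$labels, preds),
                 rmse_percent = rmse(ds$labels, preds),
                 mae_percent = mae(ds$labels, preds),
                 n = n, predictions = preds, labels = ds$labels),
            class = "metrics_report")
}

#' Train a model with Adam
#'
#' Minimises the mean squared error on `target_scale`-scaled labels over
#' shuffled mini-batches. Per-epoch training loss and validation metrics are
#' recorded; the returned model carries the parameters with the best
#' validation MAE (or the final parameters when no validation set is given).
#' Deterministic given the seeds in `model` and `tc`.
#'
#' @param model A `cadff_model` or a `cadff_config` (initialised internally).
#' @param train_ds,val_ds `leaf_dataset`s (`val_ds` may be `NULL`).
#' @param tc A [train_config()].
#' @param verbose Print one line per epoch to stderr.
#' @return List with `model` (best checkpoint), `final` (last-epoch model)
#'   and `history` (data frame: epoch, train_loss, val_r2/rmse/mae).
#' @export
train_model <- function(model, train_ds, val_ds = NULL, tc = train_config(),
                        verbose = FALSE) {
  if (inherits(model, "cadff_config")) model <- model_init(model)
  cfg <- model$cfg
  n <- dataset_n(train_ds)
  if (n < 1L) stopf("empty training set")
  y_scaled <- train_ds$labels * cfg$target_scale
  state <- adam_init()
  best <- list(mae = Inf, model = model)
  hist <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    perm <- with_rng_seed(sub_seed(tc$seed, epoch), sample.int(n))
    starts <- seq(1L, n, by = tc$batch_size)
    losses <- numeric(length(starts))
    bi <- 0L
    for (start in starts) {
      idx <- perm[start:min(start + tc$batch_size - 1L, n)]
      xf <- hwc_to_chw(train_ds$front[, , , idx, drop = FALSE])
      xb <- hwc_to_chw(train_ds$back[, , , idx, drop = FALSE])
      fw <- model_fwd_chw(model, xf, xb, training = TRUE)
      model <- fw$model
      resid <- as.numeric(fw$pred) - y_scaled[idx]
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      bi <- bi + 1L
      losses[bi] <- loss
      dpred <- matrix(2 * resid / length(resid), nrow = 1L)
      grads <- model_bwd_chw(model, fw$caches, dpred)
      st <- adam_step(model$params, grads, state, tc$learning_rate)
      model$params <- st$params
      state <- st$state
    }
    row <- data.frame(epoch = epoch, train_loss = mean(losses),
                      val_r2 = NA_real_, val_rmse = NA_real_,
                      val_mae = NA_real_)
    if (!is.null(val_ds)) {
      rep <- evaluate_model(model, val_ds)
      row$val_r2 <- rep$r2; row$val_rmse <- rep$rmse_percent
      row$val_mae <- rep$mae_percent
      if (rep$mae_percent < best$mae)
        best <- list(mae = rep$mae_percent, model = model)
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val MAE %s", epoch,
                      row$train_loss,
                      if (is.na(row$val_mae)) "-" else sprintf("%.2f", row$val_mae)))
  }
  history <- if (tc$epochs > 0L) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_loss = numeric(), val_r2 = numeric(),
               val_rmse = numeric(), val_mae = numeric())
  list(model = if (is.finite(best$mae)) best$model else model,
       final = model, history = history)
}

#' k-fold cross-validation
#'
#' Partitions the dataset with [make_cv_folds()] (seeded by `fold_seed`,
#' independent of the model configuration so ablation variants see identical
#' partitions), trains one model per fold, and aggregates validation metrics
#' as mean and sample standard deviation across folds.
#'
#' @param ds A `leaf_dataset` (or manifest data frame, decoded at
#'   `side_px`).
#' @param k Number of folds.
#' @param model_cfg A [model_config()]; each fold gets a distinct
#'   initialisation seed derived from it.
#' @param tc A [train_config()].
#' @param fold_seed Seed for the fold partition.
#' @param side_px Decode size when `ds` is a manifest.
#' @return List of class `cv_summary`: `per_fold` reports, `mean`, `sd`, `k`.
#' @export
run_cv <- function(ds, k = 5L, model_cfg = model_config(), tc = train_config(),
                   fold_seed = 1L, side_px = 224L) {
  ds <- as_dataset(ds, side_px)
  folds <- make_cv_folds(dataset_n(ds), k, fold_seed)
  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    cfg_i <- model_cfg
    cfg_i$seed <- sub_seed(model_cfg$seed, i)
    fit <- train_model(model_init(cfg_i), dataset_slice(ds, folds[[i]]$train),
                       dataset_slice(ds, folds[[i]]$val), tc)
    rep <- evaluate_model(fit$model, dataset_slice(ds, folds[[i]]$val))
    rep$predictions <- NULL; rep$labels <- NULL
    per_fold[[i]] <- rep
  }
  met <- function(f) vapply(per_fold, function(r) r[[f]], numeric(1L))
  structure(list(per_fold = per_fold,
                 mean = c(r2 = mean(met("r2")), rmse = mean(met("rmse_percent")),
                          mae = mean(met("mae_percent"))),
                 sd = c(r2 = sd(met("r2")), rmse = sd(met("rmse_percent")),
                        mae = sd(met("mae_percent"))),
                 k = k, fold_seed = fold_seed),
            class = "cv_summary")
}

#' Named configuration grids for the standard experiments
#'
#' `"components"` builds the six-variant component ablation (front-only,
#' back-only, plain dual, dual + channel attention, dual + fusion, full).
#' `"deca_placement"` builds the eight attention-placement variants over the
#' subsets of stages \{2, 3, 4\} with fusion enabled.
#'
#' @param which Grid name.
#' @param depth,base_width Backbone profile shared by all variants.
#' @param seed Initialisation seed shared by all variants.
#' @return Named list of [model_config()]s.
#' @export
ablation_grid <- function(which = c("components", "deca_placement"),
                          depth = 18L, base_width = 64L, seed = 1L) {
  which <- match.arg(which)
  mk <- function(...) model_config(depth = depth, base_width = base_width,
                                   seed = seed, ...)
  if (which == "components") {
    list(front_only = mk(branch_mode = "front_only", deca_stages = integer(),
                         mscff_enabled = FALSE),
         back_only = mk(branch_mode = "back_only", deca_stages = integer(),
                        mscff_enabled = FALSE),
         dual = mk(deca_stages = integer(), mscff_enabled = FALSE),
         dual_deca = mk(deca_stages = 2:4, mscff_enabled = FALSE),
         dual_mscff = mk(deca_stages = integer(), mscff_enabled = TRUE),
         full = mk(deca_stages = 2:4, mscff_enabled = TRUE))
  } else {
    subsets <- list(none = integer(), s2 = 2L, s3 = 3L, s4 = 4L,
                    s2_s3 = c(2L, 3L), s3_s4 = c(3L, 4L), s2_s4 = c(2L, 4L),
                    s2_s3_s4 = 2:4)
    lapply(subsets, function(s) mk(deca_stages = s, mscff_enabled = TRUE))
  }
}

#' Run an ablation grid under identical folds
#'
#' Every variant is cross-validated on byte-identical train/validation
#' partitions and, when `test_ds` is given, additionally retrained on the
#' full dataset and scored on the independent test set.
#'
#' @param ds Training `leaf_dataset`.
#' @param grid Named list of [model_config()]s (see [ablation_grid()]).
#' @param tc A [train_config()].
#' @param k,fold_seed Cross-validation folds shared by all variants.
#' @param test_ds Optional independent `leaf_dataset`.
#' @return List of class `ablation_result` keyed by variant name, each with
#'   `cv` (a `cv_summary`) and optionally `test` (a `metrics_report`).
#' @export
run_ablation <- function(ds, grid, tc = train_config(), k = 5L,
                         fold_seed = 1L, test_ds = NULL) {
  if (!length(grid)) stopf("grid must be a nonempty named list of configs")
  out <- list()
  for (nm in names(grid)) {
    cfg <- grid[[nm]]
    res <- list(cv = run_cv(ds, k, cfg, tc, fold_seed))
    if (!is.null(test_ds)) {
      fit <- train_model(model_init(cfg), ds, NULL, tc)
      res$test <- evaluate_model(fit$final, test_ds)
      res$test$predictions <- NULL; res$test$labels <- NULL
    }
    out[[nm]] <- res
  }
  structure(out, class = "ablation_result")
}

#' Flatten an ablation result into a table
#' @param res An `ablation_result`.
#' @return Data frame, one row per variant.
#' @export
ablation_table <- function(res) {
  rows <- lapply(names(res), function(nm) {
    r <- res[[nm]]
    row <- data.frame(variant = nm, r2_mean = r$cv$mean[["r2"]],
                      r2_sd = r$cv$sd[["r2"]], mae_mean = r$cv$mean[["mae"]],
                      mae_sd = r$cv$sd[["mae"]], rmse_mean = r$cv$mean[["rmse"]],
                      rmse_sd = r$cv$sd[["rmse"]])
    if (!is.null(r$test)) {
      row$test_r2 <- r$test$r2; row$test_mae <- r$test$mae_percent
      row$test_rmse <- r$test$rmse_percent
    }
    row
  })
  do.call(rbind, rows)
}

#' Serialise a report as deterministic JSON
#'
#' @param x A `metrics_report`, `cv_summary` or `ablation_result`.
#' @return A JSON string (stable for identical inputs, so two runs with the
#'   same seeds compare byte-equal).
#' @export
report_json <- function(x) {
  strip <- function(r) {
    r$predictions <- NULL; r$labels <- NULL
    lapply(unclass(r), function(v) if (is.numeric(v)) unname(v) else v)
  }
  payload <- if (inherits(x, "metrics_report")) strip(x)
  else if (inherits(x, "cv_summary"))
    list(per_fold = lapply(x$per_fold, strip), mean = as.list(x$mean),
         sd = as.list(x$sd), k = x$k)
  else if (inherits(x, "ablation_result"))
    lapply(x, function(r) {
      o <- list(cv = list(mean = as.list(r$cv$mean), sd = as.list(r$cv$sd)))
      if (!is.null(r$test)) o$test <- strip(r$test)
      o
    })
  else unclass(x)
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 12,
                                pretty = TRUE, na = "null"))
}
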