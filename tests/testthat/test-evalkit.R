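test_that("metrics reproduce the hand-derived closed forms", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)     # null model
  expect_equal(r_squared(c(1, 2, 3), c(2, 3, 4)), -0.5) # SSres 3, SStot 2
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(mae(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(rmse(c(0, 0), c(3, -4)), sqrt(25 / 2))
  expect_equal(mae(c(0, 0), c(3, -4)), 3.5)
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), "constant")
  expect_error(rmse(numeric(), numeric()), "nonempty")
})

test_that("rmse dominates mae on random vectors", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    y <- rnorm(n); yh <- rnorm(n)
    expect_gte(rmse(y, yh) - mae(y, yh), -1e-12)
  }
})

tiny_cfg <- model_config(depth = 18L, base_width = 8L, mscff_r = 4L, seed = 5L)
tiny_params <- leaf_render_params(side_px = 32L, noise_sd = 0.02)

test_that("a single batch can be overfit", {
  ds <- synth_dataset(8, tiny_params, seed = 31)
  tc <- train_config(epochs = 120, batch_size = 8L, learning_rate = 1e-3,
                     seed = 3)
  fit <- train_model(tiny_cfg, ds, NULL, tc)
  expect_lt(tail(fit$history$train_loss, 1),
            0.1 * fit$history$train_loss[1])
})

test_that("zero epochs is a no-op and equal seeds reproduce history", {
  ds <- synth_dataset(6, tiny_params, seed = 32)
  m0 <- model_init(tiny_cfg)
  fit0 <- train_model(m0, ds, NULL, train_config(epochs = 0L))
  expect_equal(nrow(fit0$history), 0L)
  expect_equal(fit0$model$params, m0$params)
  tc <- train_config(epochs = 2L, batch_size = 4L, seed = 9)
  f1 <- train_model(model_init(tiny_cfg), ds, dataset_slice(ds, 5:6), tc)
  f2 <- train_model(model_init(tiny_cfg), ds, dataset_slice(ds, 5:6), tc)
  expect_identical(f1$history, f2$history)
})

test_that("target_scale does not affect percent-scale metrics at fixed weights", {
  ds <- synth_dataset(4, tiny_params, seed = 33)
  cfg2 <- tiny_cfg; cfg2$target_scale <- 0.05
  m1 <- model_init(tiny_cfg)
  m2 <- m1; m2$cfg <- cfg2
  # same weights, different internal scale: percent-scale predictions differ
  # only by the deterministic rescaling factor of the head
  m2$params$head$W <- m1$params$head$W * (cfg2$target_scale / tiny_cfg$target_scale)
  m2$params$head$b <- m1$params$head$b * (cfg2$target_scale / tiny_cfg$target_scale)
  r1 <- evaluate_model(m1, ds)
  r2 <- evaluate_model(m2, ds)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-9)
  expect_equal(r1$mae_percent, r2$mae_percent, tolerance = 1e-9)
})

test_that("cross-validation respects fold discipline and aggregates by hand", {
  ds <- synth_dataset(20, tiny_params, seed = 34)
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 2)
  cv <- run_cv(ds, k = 5L, tiny_cfg, tc, fold_seed = 11)
  expect_length(cv$per_fold, 5L)
  expect_equal(sapply(cv$per_fold, `[[`, "n"), rep(4L, 5L))
  r2s <- sapply(cv$per_fold, `[[`, "r2")
  expect_equal(unname(cv$mean["r2"]), mean(r2s))
  expect_equal(unname(cv$sd["r2"]), sd(r2s))
  # fold membership depends only on (n, k, fold_seed)
  expect_identical(make_cv_folds(20, 5, 11), make_cv_folds(20, 5, 11))
})

test_that("a one-variant ablation grid yields a one-row table", {
  ds <- synth_dataset(8, tiny_params, seed = 35)
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 2)
  grid <- list(dual = tiny_cfg)
  res <- run_ablation(ds, grid, tc, k = 2L, fold_seed = 3)
  tab <- ablation_table(res)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$variant, "dual")
  expect_error(run_ablation(ds, list(), tc), "nonempty")
})

test_that("ablation grids enumerate the documented variants", {
  g1 <- ablation_grid("components")
  expect_named(g1, c("front_only", "back_only", "dual", "dual_deca",
                     "dual_mscff", "full"))
  expect_equal(g1$front_only$branch_mode, "front_only")
  expect_false(g1$dual$mscff_enabled)
  expect_equal(g1$full$deca_stages, 2:4)
  g2 <- ablation_grid("deca_placement")
  expect_length(g2, 8L)
  stages <- lapply(g2, `[[`, "deca_stages")
  expect_equal(unname(sort(sapply(stages, length))), c(0, 1, 1, 1, 2, 2, 2, 3))
  expect_true(all(sapply(g2, `[[`, "mscff_enabled")))
})
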