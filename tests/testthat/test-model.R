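slim_cfg <- function(seed = 5L, ...) model_config(depth = 18L, base_width = 8L,
                                                  mscff_r = 4L, seed = seed, ...)

test_that("configuration invariants and derived head width", {
  expect_equal(model_config(18, 64)$head_input_dim, 1024L)
  expect_equal(model_config(18, 64, branch_mode = "front_only",
                            deca_stages = integer(),
                            mscff_enabled = FALSE)$head_input_dim, 512L)
  expect_error(model_config(branch_mode = "front_only"), "dual")
  expect_error(model_config(deca_stages = c(2, 5)), "subset")
})

test_that("zero images with a zero head reduce to the head bias", {
  m <- model_init(slim_cfg())
  m$params$head$W[] <- 0
  m$params$head$b <- 0.42
  z <- array(0, c(32, 32, 3))
  pred <- model_forward(m, z, z)
  expect_equal(pred, 0.42 / m$cfg$target_scale, tolerance = 1e-9)
})

test_that("mse_loss matches hand evaluation", {
  expect_equal(mse_loss(c(2, 3), c(2, 3)), 0)
  expect_equal(mse_loss(0, 1), 1)
  expect_equal(mse_loss(c(0, 0), c(1, 3)), 5)
  expect_error(mse_loss(numeric(), numeric()), "nonempty")
})

test_that("forward is deterministic and both views are live", {
  m <- model_init(slim_cfg())
  set.seed(1)
  f <- array(runif(32 * 32 * 3), c(32, 32, 3))
  b <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(model_forward(m, f, b), model_forward(m, f, b))
  # perturbing only the back image must change a dual prediction
  b2 <- b; b2[1:8, 1:8, ] <- 1 - b2[1:8, 1:8, ]
  expect_false(isTRUE(all.equal(model_forward(m, f, b),
                                model_forward(m, f, b2))))
  f2 <- f; f2[1:8, 1:8, ] <- 1 - f2[1:8, 1:8, ]
  expect_false(isTRUE(all.equal(model_forward(m, f, b),
                                model_forward(m, f2, b))))
})

test_that("parameter counts nest across the ablation variants", {
  grid <- ablation_grid("components", depth = 18L, base_width = 8L)
  grid <- lapply(grid, function(cfg) { cfg$mscff_r <- 4L; cfg })
  counts <- sapply(grid, function(cfg) parameter_count(model_config(
    depth = cfg$depth, base_width = cfg$base_width,
    branch_mode = cfg$branch_mode, deca_stages = cfg$deca_stages,
    mscff_enabled = cfg$mscff_enabled, mscff_r = 4L, seed = 1))$total)
  expect_lt(counts[["front_only"]], counts[["dual"]])
  expect_lt(counts[["back_only"]], counts[["dual"]])
  expect_lt(counts[["dual"]], counts[["dual_deca"]])
  expect_lt(counts[["dual"]], counts[["dual_mscff"]])
  expect_lt(counts[["dual_deca"]], counts[["full"]])
  expect_lt(counts[["dual_mscff"]], counts[["full"]])
  # structural nesting: every baseline leaf path exists in the richer models
  pm <- function(cfg) model_init(model_config(
    depth = cfg$depth, base_width = cfg$base_width,
    branch_mode = cfg$branch_mode, deca_stages = cfg$deca_stages,
    mscff_enabled = cfg$mscff_enabled, mscff_r = 4L, seed = 1))$params
  paths <- lapply(grid[c("dual", "dual_deca", "dual_mscff", "full")],
                  function(cfg) leaf_paths(pm(cfg)))
  expect_true(all(paths$dual %in% paths$dual_deca))
  expect_true(all(paths$dual %in% paths$dual_mscff))
  expect_true(all(paths$dual_deca %in% paths$full))
  expect_true(all(paths$dual_mscff %in% paths$full))
  # head parameter count is input width + bias
  m <- model_init(slim_cfg())
  pc <- parameter_count(m)
  expect_equal(unname(pc$modules["head"]), m$cfg$head_input_dim + 1L)
  expect_equal(pc$total, sum(pc$modules))
})

test_that("analytic gradients match directional finite differences", {
  m <- model_init(slim_cfg(seed = 7L))
  set.seed(42)
  xf <- cadffnet:::hwc_to_chw(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  xb <- cadffnet:::hwc_to_chw(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  y <- c(0.3, 0.7)
  lossfn <- function(mm) {
    fw <- cadffnet:::model_fwd_chw(mm, xf, xb, training = TRUE)
    mean((as.numeric(fw$pred) - y)^2)
  }
  fw <- cadffnet:::model_fwd_chw(m, xf, xb, training = TRUE)
  gr <- cadffnet:::model_bwd_chw(fw$model, fw$caches,
                                 matrix(as.numeric(fw$pred) - y, nrow = 1))
  setp <- function(pl, path, val) {
    if (length(path) == 1) { pl[[path[[1]]]] <- val; return(pl) }
    pl[[path[[1]]]] <- setp(pl[[path[[1]]]], path[-1], val)
    pl
  }
  getp <- function(pl, path) { for (k in path) pl <- pl[[k]]; pl }
  paths <- list(list("head", "W"), list("deca", "s3", "conv"),
                list("mscff", "fc1", "W"), list("mscff", "conv5", "W"),
                list("front", "s2", 1, "conv1", "W"),
                list("back", "s5", 2, "bn2", "gamma"),
                list("front", "stem", "conv", "W"))
  eps <- 1e-6
  for (pth in paths) {
    leaf <- getp(m$params, pth)
    g <- getp(gr, pth)
    dir <- rnorm(length(leaf))
    dir <- dir / sqrt(sum(dir^2))  # unit step keeps kink-crossing noise small
    dim(dir) <- dim(leaf)
    m1 <- m; m1$params <- setp(m$params, pth, leaf + eps * dir)
    m2 <- m; m2$params <- setp(m$params, pth, leaf - eps * dir)
    num <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
    ana <- sum(g * dir)  # dpred = resid equals dL/dpred = 2*resid/n at n = 2
    expect_equal(ana, num, tolerance = 1e-3,
                 info = paste(unlist(pth), collapse = "/"))
  }
})

test_that("checkpoints round-trip through RDS", {
  m <- model_init(slim_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  set.seed(3)
  f <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(model_forward(m, f, f), model_forward(m2, f, f))
})
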