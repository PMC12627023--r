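test_that("adaptive kernel size follows the truncate-then-odd rule", {
  # brute-force evaluation of the stated rule, independent of the package
  brute <- function(C, gamma = 2, b = 1) {
    t <- trunc((log2(C) + b) / gamma)
    max(1, if (t %% 2 == 1) t else t + 1)
  }
  expect_equal(adaptive_kernel_size(2), 1L)
  expect_equal(adaptive_kernel_size(64), 3L)
  expect_equal(adaptive_kernel_size(128), 5L)
  expect_equal(adaptive_kernel_size(256), 5L)
  expect_equal(adaptive_kernel_size(512), 5L)
  for (C in c(1:20, 2^(5:11)))
    expect_equal(adaptive_kernel_size(C), brute(C), info = paste("C =", C))
  # always odd, at least 1
  ks <- sapply(1:300, adaptive_kernel_size)
  expect_true(all(ks %% 2 == 1 & ks >= 1))
  expect_error(adaptive_kernel_size(0), "positive")
})

test_that("degenerate inputs produce the closed-form weights", {
  layer <- withr::with_seed(1, deca_init(4))
  z <- array(0, c(3, 3, 4))
  r <- deca_forward(z, z, layer)
  expect_equal(r$w, rep(0.5, 4))
  expect_equal(r$front, z)
  # zero kernel: w = sigmoid(0) = 0.5, outputs are the inputs halved
  layer0 <- layer
  layer0$conv[] <- 0
  set.seed(2)
  Ff <- array(rnorm(36), c(3, 3, 4)); Fb <- array(rnorm(36), c(3, 3, 4))
  r0 <- deca_forward(Ff, Fb, layer0)
  expect_equal(r0$w, rep(0.5, 4))
  expect_equal(r0$front, Ff / 2)
  expect_equal(r0$back, Fb / 2)
})

test_that("deca_forward matches the loop oracle on random small instances", {
  set.seed(99)
  for (i in 1:25) {
    C <- sample(c(2L, 4L, 8L), 1)
    H <- sample(1:4, 1); W <- sample(1:4, 1)
    layer <- deca_init(C)
    Ff <- array(rnorm(H * W * C), c(H, W, C))
    Fb <- array(rnorm(H * W * C), c(H, W, C))
    got <- deca_forward(Ff, Fb, layer)
    want <- oracle_deca(Ff, Fb, layer$conv)
    expect_lt(max(abs(got$front - want$front)), 1e-6)
    expect_lt(max(abs(got$back - want$back)), 1e-6)
    expect_lt(max(abs(got$w - want$w)), 1e-6)
  }
})

test_that("weights stay in (0,1), modulation is shared and symmetric", {
  set.seed(5)
  layer <- deca_init(8)
  Ff <- array(rnorm(2 * 3 * 8, sd = 3), c(2, 3, 8))
  Fb <- array(rnorm(2 * 3 * 8, sd = 3), c(2, 3, 8))
  r <- deca_forward(Ff, Fb, layer)
  expect_true(all(r$w > 0 & r$w < 1))
  expect_true(all(abs(r$front) <= abs(Ff) + 1e-12))
  # shared modulation: same per-channel ratio on both branches
  for (c in 1:8) {
    expect_equal(r$front[, , c] / Ff[, , c],
                 matrix(r$w[c], 2, 3), tolerance = 1e-12)
    expect_equal(r$back[, , c] / Fb[, , c],
                 matrix(r$w[c], 2, 3), tolerance = 1e-12)
  }
  # symmetry: swapping inputs swaps outputs, weights unchanged
  rs <- deca_forward(Fb, Ff, layer)
  expect_equal(rs$w, r$w)
  expect_equal(rs$front, r$back)
  expect_equal(rs$back, r$front)
})

test_that("batched and per-sample attention agree", {
  set.seed(6)
  layer <- deca_init(4)
  Ff <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  Fb <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  rb <- deca_forward(Ff, Fb, layer)
  for (n in 1:2) {
    rn <- deca_forward(Ff[, , , n], Fb[, , , n], layer)
    expect_equal(rb$front[, , , n], rn$front, tolerance = 1e-12)
    expect_equal(unname(rb$w[, n]), rn$w, tolerance = 1e-12)
  }
  expect_error(deca_forward(Ff, Fb[, , 1:2, , drop = FALSE], layer), "shape")
})
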