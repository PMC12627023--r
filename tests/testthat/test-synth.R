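noise_free <- function(side = 64L, mode = "joint")
  leaf_render_params(side_px = side, noise_sd = 0, mode = mode)

test_that("rendering is bit-identical under a fixed seed", {
  p <- leaf_render_params(side_px = 48L, noise_sd = 0.03)
  a <- render_pair(42, p, seed = 9)
  b <- render_pair(42, p, seed = 9)
  expect_identical(a, b)
  c <- render_pair(42, p, seed = 10)
  expect_false(identical(a$front, c$front))
})

test_that("interpolation endpoints are exact in noise-free joint mode", {
  p <- noise_free(48L)
  s <- render_pair(100, p, seed = 1)
  for (ch in 1:3) {
    vals <- s$front[, , ch][s$mask_front]
    expect_true(all(abs(vals - p$color_wet[ch]) < 1e-12))
  }
  expect_equal(unname(view_information_summary(s)["back_vein_gap"]), 0,
               tolerance = 1e-12)
  s0 <- render_pair(0, p, seed = 1)
  vals0 <- s0$front[, , 1][s0$mask_front]
  expect_true(all(abs(vals0 - p$color_dry[1]) < 1e-12))
})

test_that("appearance statistics are strictly monotone in the label", {
  p <- noise_free(64L)
  stats <- sapply(c(10, 30, 50, 70, 90),
                  function(l) view_information_summary(render_pair(l, p, seed = 3)))
  expect_true(all(diff(stats["front_green_mean", ]) > 0))
  expect_true(all(diff(stats["back_vein_gap", ]) < 0))
  # curl: lamina width grows with the label
  widths <- sapply(c(10, 50, 90), function(l) {
    m <- render_pair(l, p, seed = 3)$mask_front
    max(rowSums(m))
  })
  expect_true(all(diff(widths) > 0))
})

test_that("split mode confines each latent to its own view", {
  p <- noise_free(48L, mode = "split")
  # same front latent, different back latent -> identical front views
  a <- render_pair(0, p, seed = 5, latents = c(0.8, 0.1))
  b <- render_pair(0, p, seed = 5, latents = c(0.8, 0.9))
  expect_identical(a$front, b$front)
  expect_false(identical(a$back, b$back))
  # same back latent, different front latent -> identical back views
  c <- render_pair(0, p, seed = 5, latents = c(0.2, 0.4))
  d <- render_pair(0, p, seed = 5, latents = c(0.9, 0.4))
  expect_identical(c$back, d$back)
  # label is the symmetric mean of the latents
  expect_equal(a$label, 100 * mean(c(0.8, 0.1)))
  # extreme split sample maximises both statistics at once
  s <- render_pair(0, p, seed = 5, latents = c(1, 0))
  st <- view_information_summary(s)
  expect_equal(unname(st["front_green_mean"]), p$color_wet[2], tolerance = 1e-12)
  gaps <- sapply(seq(0, 1, by = 0.25), function(lb)
    view_information_summary(render_pair(0, p, seed = 5,
                                         latents = c(1, lb)))["back_vein_gap"])
  expect_equal(unname(st["back_vein_gap"]), max(gaps), tolerance = 1e-12)
})

test_that("generate_dataset writes a loadable, deterministic dataset", {
  p <- leaf_render_params(side_px = 32L, noise_sd = 0.02)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(10, d1, p, label_range = c(10, 90), seed = 7)
  m2 <- generate_dataset(10, d2, p, label_range = c(10, 90), seed = 7)
  recs <- load_manifest(m1)
  expect_equal(nrow(recs), 10L)
  expect_equal(length(list.files(d1, pattern = "\\.png$")), 20L)
  expect_true(all(recs$moisture_percent >= 10 & recs$moisture_percent <= 90))
  # byte-identical across runs with the same seed
  expect_identical(readLines(m1), readLines(m2))
  f1 <- sort(list.files(d1, pattern = "png$"))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # PNG round trip preserves pixels to 8-bit quantisation
  pair <- load_pair(recs[1, ], side_px = 32L)
  direct <- render_pair(recs$moisture_percent[1], p, seed = cadffnet:::sub_seed(7, 1))
  expect_lt(max(abs(pair$front - direct$front)), 1 / 255)
})

test_that("in-memory and on-disk generators agree up to quantisation", {
  p <- leaf_render_params(side_px = 32L, noise_sd = 0.02)
  ds <- synth_dataset(5, p, label_range = c(10, 90), seed = 7)
  dir <- withr::local_tempdir()
  recs <- load_manifest(generate_dataset(5, dir, p, label_range = c(10, 90), seed = 7))
  expect_equal(ds$labels, recs$moisture_percent)
  pair <- load_pair(recs[3, ], side_px = 32L)
  expect_lt(max(abs(ds$front[, , , 3] - pair$front)), 1 / 255)
})

test_that("labels outside [0, 100] are rejected", {
  expect_error(render_pair(101, noise_free(48L)), "label")
  expect_error(render_pair(-2, noise_free(48L)), "label")
})
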