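# Deterministic synthetic dual-view leaf renderer.
#
# Each sample is an elliptical "leaf" on a white background. As the governing
# moisture latent (in [0,1]) decreases: the lamina colour moves linearly from
# a wet green to a dry brown, the lamina narrows horizontally (inward curl),
# and on the back view dark veins gain contrast against the lightened lamina.
# The generator's job is statistical structure, not botany: every
# latent-to-appearance map is linear, and every byte of output is a pure
# function of (arguments, seed).

#' Rendering parameters for the synthetic leaf generator
#'
#' @param side_px Image side in pixels (default 224, the model input size).
#' @param color_wet,color_dry RGB triples in `[0,1]` for a fully hydrated
#'   (green) and fully dry (brown) lamina; the fill colour is their linear
#'   interpolation along the moisture latent.
#' @param back_lightening Fraction in `[0,1]` by which the back lamina colour
#'   is pushed toward white (the abaxial surface is paler).
#' @param curl_min_width_frac Horizontal width fraction of the lamina at
#'   latent 0 (fully curled); width grows linearly to 1 at latent 1.
#' @param vein_count Number of lateral vein pairs drawn on the back view.
#' @param vein_contrast_max Maximum relative darkening of vein pixels (reached
#'   at latent 0); the vein/lamina gap scales with `(1 - latent)`.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise added to
#'   both views (clipped to `[0,1]`).
#' @param illumination_jitter Half-range of a per-view multiplicative
#'   brightness factor `1 + U(-j, j)`. Default 0 so noise-free renders hit the
#'   colour endpoints exactly.
#' @param mode `"joint"`: one latent drives both views (label = 100*latent).
#'   `"split"`: two independent latents, one visible only in the front view
#'   and one only in the back; label = 100 * mean(latents), which caps the
#'   variance any single view can explain at one half.
#' @return A list of class `leaf_render_params`.
#' @export
leaf_render_params <- function(side_px = 224L,
                               color_wet = c(0.20, 0.55, 0.15),
                               color_dry = c(0.45, 0.33, 0.12),
                               back_lightening = 0.25,
                               curl_min_width_frac = 0.45,
                               vein_count = 6L,
                               vein_contrast_max = 0.5,
                               noise_sd = 0.02,
                               illumination_jitter = 0,
                               mode = c("joint", "split")) {
  mode <- match.arg(mode)
  stopifnot(is_count(side_px, 16L), length(color_wet) == 3L,
            length(color_dry) == 3L, all(color_wet >= 0 & color_wet <= 1),
            all(color_dry >= 0 & color_dry <= 1),
            back_lightening >= 0, back_lightening <= 1,
            curl_min_width_frac > 0, curl_min_width_frac <= 1,
            is_count(vein_count, 0L), vein_contrast_max >= 0,
            vein_contrast_max <= 1, noise_sd >= 0, illumination_jitter >= 0)
  structure(list(side_px = as.integer(side_px), color_wet = color_wet,
                 color_dry = color_dry, back_lightening = back_lightening,
                 curl_min_width_frac = curl_min_width_frac,
                 vein_count = as.integer(vein_count),
                 vein_contrast_max = vein_contrast_max, noise_sd = noise_sd,
                 illumination_jitter = illumination_jitter, mode = mode),
            class = "leaf_render_params")
}

# Elliptical lamina mask for a given governing latent (curl narrows width).
leaf_mask <- function(side, latent, curl_min_width_frac) {
  wf <- curl_min_width_frac + (1 - curl_min_width_frac) * latent
  cx <- (side + 1) / 2
  cy <- (side + 1) / 2
  ax <- 0.32 * side * wf   # horizontal semi-axis (shrinks as the leaf curls)
  ay <- 0.42 * side        # vertical semi-axis
  xs <- matrix(rep(seq_len(side), each = side), nrow = side)   # column index
  ys <- matrix(rep(seq_len(side), times = side), nrow = side)  # row index
  ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
}

# Rasterise midrib + lateral veins inside the mask; returns a logical matrix.
# Layout (lateral heights, slopes) is jittered from the current RNG stream.
vein_mask <- function(side, mask, vein_count) {
  vm <- matrix(FALSE, side, side)
  cx <- round((side + 1) / 2)
  half <- max(1L, round(side / 150))
  cols <- pmax(1L, pmin(side, (cx - half):(cx + half)))
  vm[, cols] <- TRUE
  if (vein_count > 0L) {
    ys <- round(seq(0.22, 0.78, length.out = vein_count) * side +
                  runif(vein_count, -0.02, 0.02) * side)
    slopes <- 0.45 + runif(vein_count, -0.1, 0.1)
    tt <- seq(0, 0.35 * side, by = 0.5)
    for (i in seq_len(vein_count)) {
      for (sgn in c(-1, 1)) {
        x <- round(cx + sgn * tt)
        y <- round(ys[i] + slopes[i] * tt)
        ok <- x >= 1 & x <= side & y >= 1 & y <= side
        vm[cbind(y[ok], x[ok])] <- TRUE
      }
    }
  }
  vm & mask
}

fill_view <- function(side, mask, color) {
  img <- array(1, c(side, side, 3L))
  for (c in 1:3) {
    plane <- img[, , c]
    plane[mask] <- color[c]
    img[, , c] <- plane
  }
  img
}

clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

#' Render one synthetic front/back leaf pair
#'
#' Fully deterministic given `(label_percent, params, seed)`. In `"joint"`
#' mode both views are governed by `label_percent / 100`. In `"split"` mode
#' two latents govern the two views independently; by default they are drawn
#' (seeded) uniformly subject to averaging to the label, or can be supplied
#' explicitly via `latents`.
#'
#' @param label_percent Moisture label in `[0, 100]`.
#' @param params A [leaf_render_params()] list.
#' @param seed Integer seed (vein jitter, illumination, pixel noise).
#' @param latents Optional `c(latent_front, latent_back)` in `[0,1]` for split
#'   mode; when supplied, the label is recomputed as `100 * mean(latents)`.
#' @return A list of class `leaf_sample`: `front`, `back` (`side x side x 3`
#'   arrays), `label`, `latent_front`, `latent_back`, plus the logical masks
#'   `mask_front`, `mask_back`, `veins_back` used by
#'   [view_information_summary()].
#' @export
render_pair <- function(label_percent, params = leaf_render_params(),
                        seed = 1L, latents = NULL) {
  if (!is.null(latents)) {
    stopifnot(length(latents) == 2L, all(latents >= 0 & latents <= 1))
    label_percent <- 100 * mean(latents)
  }
  if (!is.finite(label_percent) || label_percent < 0 || label_percent > 100)
    stopf("label_percent must lie in [0, 100], got %s", format(label_percent))
  side <- params$side_px
  with_rng_seed(seed, {
    if (is.null(latents)) {
      if (params$mode == "joint") {
        latents <- rep(label_percent / 100, 2L)
      } else {
        z <- label_percent / 50  # latents sum to z, each in [0,1]
        lo <- max(0, z - 1); hi <- min(1, z)
        lf <- runif(1L, lo, hi)
        latents <- c(lf, z - lf)
      }
    }
    lf <- latents[1L]; lb <- latents[2L]
    col_f <- params$color_dry + lf * (params$color_wet - params$color_dry)
    col_b0 <- params$color_dry + lb * (params$color_wet - params$color_dry)
    col_b <- col_b0 + params$back_lightening * (1 - col_b0)
    mask_f <- leaf_mask(side, lf, params$curl_min_width_frac)
    mask_b <- leaf_mask(side, lb, params$curl_min_width_frac)
    veins <- vein_mask(side, mask_b, params$vein_count)
    front <- fill_view(side, mask_f, col_f)
    back <- fill_view(side, mask_b, col_b)
    gap_rel <- (1 - lb) * params$vein_contrast_max
    vcol <- col_b * (1 - gap_rel)
    for (c in 1:3) {
      plane <- back[, , c]
      plane[veins] <- vcol[c]
      back[, , c] <- plane
    }
    if (params$illumination_jitter > 0) {
      front <- front * (1 + runif(1L, -1, 1) * params$illumination_jitter)
      back <- back * (1 + runif(1L, -1, 1) * params$illumination_jitter)
    }
    if (params$noise_sd > 0) {
      front <- front + rnorm(length(front), sd = params$noise_sd)
      back <- back + rnorm(length(back), sd = params$noise_sd)
    }
    structure(list(front = clip01(front), back = clip01(back),
                   label = label_percent, latent_front = lf, latent_back = lb,
                   mask_front = mask_f, mask_back = mask_b, veins_back = veins),
              class = "leaf_sample")
  })
}

#' Per-view appearance statistics of a synthetic sample
#'
#' Returns the mean green-channel value over the front lamina and the mean
#' absolute intensity gap between vein pixels and the surrounding lamina on
#' the back — the two statistics whose monotone dependence on the moisture
#' latents the generator guarantees.
#'
#' @param sample A `leaf_sample` from [render_pair()].
#' @return Named numeric vector `c(front_green_mean, back_vein_gap)`.
#' @export
view_information_summary <- function(sample) {
  g <- sample$front[, , 2L]
  front_green <- mean(g[sample$mask_front])
  intensity <- (sample$back[, , 1L] + sample$back[, , 2L] + sample$back[, , 3L]) / 3
  lamina <- sample$mask_back & !sample$veins_back
  gap <- if (!any(sample$veins_back)) 0 else
    mean(abs(intensity[sample$veins_back] - mean(intensity[lamina])))
  c(front_green_mean = front_green, back_vein_gap = gap)
}

#' Generate a synthetic dataset on disk
#'
#' Samples `n` labels, renders each pair, writes PNGs plus a manifest CSV in
#' the [load_manifest()] dialect. Deterministic given `seed`.
#'
#' In joint mode labels are uniform on `label_range`; in split mode the two
#' view latents are i.i.d. uniform on `[0,1]` and the label is their mean
#' scaled to percent (`label_range` is ignored — the cap on single-view
#' explainable variance is the point of that mode).
#'
#' @param n Number of samples.
#' @param out_dir Output directory (created if needed).
#' @param params A [leaf_render_params()] list.
#' @param label_range Numeric `c(low, high)` within `[0, 100]`.
#' @param seed Integer seed.
#' @return Path of the written manifest CSV.
#' @export
generate_dataset <- function(n, out_dir, params = leaf_render_params(),
                             label_range = c(0, 100), seed = 1L) {
  stopifnot(is_count(n), length(label_range) == 2L,
            label_range[1L] >= 0, label_range[2L] <= 100,
            label_range[1L] < label_range[2L])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  draws <- with_rng_seed(seed, {
    if (params$mode == "joint")
      list(labels = runif(n, label_range[1L], label_range[2L]), latents = NULL)
    else
      list(labels = NULL,
           latents = matrix(runif(2L * n), ncol = 2L))
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- if (params$mode == "joint")
      render_pair(draws$labels[i], params, seed = sub_seed(seed, i))
    else
      render_pair(0, params, seed = sub_seed(seed, i),
                  latents = draws$latents[i, ])
    id <- sprintf("leaf_%05d", i)
    fp <- file.path(out_dir, paste0(id, "_front.png"))
    bp <- file.path(out_dir, paste0(id, "_back.png"))
    write_image(s$front, fp)
    write_image(s$back, bp)
    rows[[i]] <- data.frame(sample_id = id,
                            front_path = basename(fp), back_path = basename(bp),
                            moisture_percent = s$label,
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write_manifest(do.call(rbind, rows), manifest)
  manifest
}

#' Generate a synthetic dataset in memory
#'
#' Same sampling scheme as [generate_dataset()] but returns loaded tensors
#' directly (no PNG round trip), the form consumed by [train_model()].
#'
#' @inheritParams generate_dataset
#' @return A `leaf_dataset`: list with `front`, `back`
#'   (`side x side x 3 x n` arrays), `labels` (percent), and `ids`.
#' @export
synth_dataset <- function(n, params = leaf_render_params(),
                          label_range = c(0, 100), seed = 1L) {
  stopifnot(is_count(n))
  draws <- with_rng_seed(seed, {
    if (params$mode == "joint")
      list(labels = runif(n, label_range[1L], label_range[2L]), latents = NULL)
    else list(labels = NULL, latents = matrix(runif(2L * n), ncol = 2L))
  })
  side <- params$side_px
  front <- array(0, c(side, side, 3L, n))
  back <- array(0, c(side, side, 3L, n))
  labels <- numeric(n)
  for (i in seq_len(n)) {
    s <- if (params$mode == "joint")
      render_pair(draws$labels[i], params, seed = sub_seed(seed, i))
    else
      render_pair(0, params, seed = sub_seed(seed, i),
                  latents = draws$latents[i, ])
    front[, , , i] <- s$front
    back[, , , i] <- s$back
    labels[i] <- s$label
  }
  structure(list(front = front, back = back, labels = labels,
                 ids = sprintf("leaf_%05d", seq_len(n))),
            class = "leaf_dataset")
}
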