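# Image decode/encode and bilinear resampling. Images are H x W x 3 numeric
# arrays in [0, 1] (the convention of the png package).

#' Read a PNG or JPEG image as an H x W x 3 array in \[0, 1\]
#'
#' Grayscale inputs are replicated to 3 channels; an alpha channel is dropped.
#' The format is chosen by file extension (`.png`, `.jpg`, `.jpeg`).
#'
#' @param path Image file path.
#' @return `H x W x 3` numeric array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stopf("cannot decode PNG %s: %s", path,
                                             conditionMessage(e))),
    jpg = ,
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) stopf("cannot decode JPEG %s: %s", path,
                                              conditionMessage(e))),
    stopf("unsupported image extension '%s' for %s (PNG/JPEG only)", ext, path))
  d <- dim(img)
  if (is.null(d) || length(d) == 2L) {           # grayscale matrix
    img <- array(rep(as.numeric(img), 3L), c(dim(as.matrix(img)), 3L))
  } else if (d[3L] == 1L) {
    img <- array(rep(img[, , 1L], 3L), c(d[1L], d[2L], 3L))
  } else if (d[3L] >= 4L) {
    img <- img[, , 1:3, drop = FALSE]            # drop alpha
  } else if (d[3L] == 2L) {                      # gray + alpha
    img <- array(rep(img[, , 1L], 3L), c(d[1L], d[2L], 3L))
  }
  img
}

#' Write an H x W x 3 array in \[0, 1\] as an 8-bit PNG
#'
#' @param img `H x W x 3` numeric array; values are clipped to `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Bilinear resize of an H x W x C image
#'
#' Half-pixel-centre convention (`src = (dst + 0.5) * scale - 0.5`) with edge
#' clamping, matching the common image-library default.
#'
#' @param img `H x W x C` numeric array.
#' @param side_px Output side, or `c(height, width)`.
#' @return Resized array, `side_px` on each spatial side.
#' @export
resize_bilinear <- function(img, side_px) {
  d <- dim(img)
  oh <- as.integer(side_px[1L])
  ow <- as.integer(if (length(side_px) > 1L) side_px[2L] else side_px[1L])
  if (d[1L] == oh && d[2L] == ow) return(img)
  src_of <- function(o, n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sy <- src_of(oh, oh, d[1L]); sx <- src_of(ow, ow, d[2L])
  y0 <- pmin(floor(sy), d[1L] - 1); x0 <- pmin(floor(sx), d[2L] - 1)
  y1 <- pmin(y0 + 1, d[1L] - 1);    x1 <- pmin(x0 + 1, d[2L] - 1)
  wy <- sy - y0; wx <- sx - x0
  out <- array(0, c(oh, ow, d[3L]))
  for (c in seq_len(d[3L])) {
    p <- img[, , c]
    a <- p[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx) +
      p[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx) +
      p[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx) +
      p[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
    out[, , c] <- a
  }
  out
}
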