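# Paired-image manifests, moisture labels, and cross-validation folds.

MANIFEST_COLS <- c("sample_id", "front_path", "back_path", "moisture_percent")

#' Moisture content from fresh and dry mass
#'
#' Gravimetric moisture content of a leaf as a percentage of fresh mass:
#' `100 * (m_fresh - m_dry) / m_fresh`.
#'
#' @param m_fresh Fresh mass in grams; must be strictly positive.
#' @param m_dry Dry mass in grams; must satisfy `0 <= m_dry <= m_fresh`.
#' @return Moisture content in percent, in `[0, 100]`. Vectorised.
#' @examples
#' compute_moisture(10, 2)  # 80
#' @export
compute_moisture <- function(m_fresh, m_dry) {
  if (any(!is.finite(m_fresh)) || any(m_fresh <= 0))
    stopf("m_fresh must be finite and > 0")
  if (any(!is.finite(m_dry)) || any(m_dry < 0))
    stopf("m_dry must be finite and >= 0")
  if (any(m_dry > m_fresh))
    stopf("m_dry exceeds m_fresh")
  100 * (m_fresh - m_dry) / m_fresh
}

#' Read a paired-image manifest
#'
#' The manifest is a UTF-8 CSV with header columns
#' `sample_id,front_path,back_path,moisture_percent`. Relative image paths are
#' resolved against the manifest's directory.
#'
#' @param path Path to the CSV file.
#' @param check_paths If `TRUE` (default), verify that every referenced image
#'   file exists; the error names the offending row.
#' @return A data frame of sample records in file order (possibly 0 rows).
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLS, names(df))
  if (length(miss))
    stopf("manifest %s is missing column(s): %s", path, paste(miss, collapse = ", "))
  df <- df[MANIFEST_COLS]
  if (nrow(df) == 0L) return(df)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$front_path <- resolve(df$front_path)
  df$back_path <- resolve(df$back_path)
  bad <- which(!is.finite(df$moisture_percent) | df$moisture_percent < 0 |
                 df$moisture_percent > 100)
  if (length(bad))
    stopf("row %d: moisture_percent %s outside [0, 100]", bad[1L],
          format(df$moisture_percent[bad[1L]]))
  if (check_paths) {
    for (i in seq_len(nrow(df))) {
      for (col in c("front_path", "back_path")) {
        if (!file.exists(df[[col]][i]))
          stopf("row %d: %s does not exist: %s", i, col, df[[col]][i])
      }
    }
  }
  df
}

#' Write a paired-image manifest
#'
#' @param records Data frame with the manifest columns (see [load_manifest()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  miss <- setdiff(MANIFEST_COLS, names(records))
  if (length(miss)) stopf("records missing column(s): %s", paste(miss, collapse = ", "))
  write.csv(records[MANIFEST_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load, resize and scale an image pair
#'
#' Decodes both views of a sample record, converts to 3-channel RGB in
#' `[0, 1]`, and bilinearly resizes to `side_px` x `side_px`.
#'
#' @param rec One-row data frame (or list) with `front_path`, `back_path` and
#'   `moisture_percent`.
#' @param side_px Output side length in pixels (default 224, the model input).
#' @return List with elements `front`, `back` (`side_px x side_px x 3` arrays
#'   in `[0, 1]`) and `label` (percent moisture, carried through unchanged).
#' @export
load_pair <- function(rec, side_px = 224L) {
  if (!is_count(side_px)) stopf("side_px must be a positive integer")
  list(front = resize_bilinear(read_image(rec$front_path), side_px),
       back = resize_bilinear(read_image(rec$back_path), side_px),
       label = as.numeric(rec$moisture_percent))
}

#' k-fold cross-validation partitions
#'
#' Seeded uniform shuffle followed by contiguous slicing into `k` folds whose
#' sizes differ by at most one; each record lands in exactly one validation
#' set. Deterministic given `seed`.
#'
#' @param n Number of records, or a data frame of records.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle.
#' @return List of `k` elements, each `list(train = <indices>, val = <indices>)`.
#' @export
make_cv_folds <- function(n, k = 5L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (!is_count(n)) stopf("n must be a positive integer")
  if (!is_count(k, 2L)) stopf("k must be an integer >= 2")
  if (k > n) stopf("k = %d exceeds the number of records (%d)", k, n)
  perm <- with_rng_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = setdiff(seq_len(n), val), val = val)
  })
}
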