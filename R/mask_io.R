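#' Binary vessel mask
#'
#' Container for a 2-D boolean raster of vessel membership. The coordinate
#' convention throughout the package is `(row, col)`, 0-based externally
#' (file formats) but stored 1-based as ordinary R matrix indices; row 1 is
#' the image top.
#'
#' @param pixels logical matrix (rows x cols); any non-logical input is
#'   coerced with `!= 0`.
#' @param image_id character scalar identifying the image.
#' @param pixel_size_um physical pixel edge length in micrometers, or `NA`
#'   when uncalibrated. All tortuosity metrics are dimensionless or in pixel
#'   units, so this is optional metadata only.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, image_id = "image", pixel_size_um = NA_real_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "double"
    pixels <- pixels != 0
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("mask must have positive dimensions")
  if (!is.na(pixel_size_um) && pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(
    list(pixels = pixels, image_id = as.character(image_id)[1],
         pixel_size_um = pixel_size_um),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s: %d x %d, %d vessel px (%.2f%%)\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Optic-disc center
#'
#' @param row,col 0-based pixel coordinates of the disc center (row 0 = top).
#' @param image_id image the coordinates belong to.
#' @return A one-row data frame with columns `image_id`, `row`, `col`.
#' @export
disc_center <- function(row, col, image_id = "image") {
  row <- as.numeric(row); col <- as.numeric(col)
  if (is.na(row) || is.na(col) || row < 0 || col < 0)
    stop("disc center coordinates must be non-negative reals")
  data.frame(image_id = as.character(image_id), row = row, col = col,
             stringsAsFactors = FALSE)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , , drop = TRUE]
    img
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , , drop = TRUE]
    img
  } else {
    stop(sprintf("unsupported raster format '%s' (use PNG or TIFF): %s", ext, path))
  }
}

#' Load a binary vessel mask from PNG or TIFF
#'
#' Reads a single-channel raster (or a multi-channel raster whose channels
#' are identical, e.g. an RGB export of a grayscale mask) and binarizes it:
#' pixels with 8-bit intensity `>= threshold` become vessel.
#'
#' @param path path to a PNG or TIFF file.
#' @param threshold intensity threshold on the 0--255 scale (default 1, i.e.
#'   any nonzero pixel is vessel -- segmentations exported from binary
#'   editing tools are 0/255 by construction).
#' @param image_id image identifier; defaults to the file name without
#'   extension.
#' @param pixel_size_um optional physical calibration.
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, threshold = 1, image_id = NULL, pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop(sprintf("mask file does not exist: %s", path))
  if (threshold < 1) stop("threshold must be >= 1 (8-bit scale)")
  img <- read_raster(path)
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    ref <- img[, , 1]
    for (k in seq_len(nch)[-1]) {
      if (max(abs(img[, , k] - ref)) > 1e-9)
        stop(sprintf("multi-channel mask with differing channels: %s", path))
    }
    img <- ref
  }
  px <- round(img * 255) >= threshold
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  binary_mask(px, image_id = image_id, pixel_size_um = pixel_size_um)
}

#' Write a binary mask to PNG
#'
#' @param mask a [binary_mask()].
#' @param path output PNG path; vessel pixels are written as 255.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

#' Load optic-disc center coordinates
#'
#' Accepts a CSV with header `image_id,row,col` or a JSON array of objects
#' with those keys. Coordinates are 0-based `(row, col)` with row 0 at the
#' image top; files recorded as `(x, y)` image coordinates can be converted
#' with `xy_order = TRUE`, which swaps the two columns on load.
#'
#' @param path CSV or JSON file path.
#' @param xy_order logical; set `TRUE` when the file stores `(x, y)` =
#'   `(col, row)` order.
#' @return A data frame with columns `image_id`, `row`, `col`, one row per
#'   image.
#' @export
load_disc_centers <- function(path, xy_order = FALSE) {
  if (!file.exists(path)) stop(sprintf("disc-center file does not exist: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) df <- data.frame(image_id = character(), row = numeric(), col = numeric())
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("image_id", "row", "col")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("disc-center file missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (xy_order) {
    tmp <- df$row; df$row <- df$col; df$col <- tmp
  }
  df$row <- as.numeric(df$row); df$col <- as.numeric(df$col)
  dup <- unique(df$image_id[duplicated(df$image_id)])
  if (length(dup) > 0)
    stop(sprintf("duplicate image_id in disc-center file: %s", paste(dup, collapse = ", ")))
  df[, need]
}

#' Write a results table to CSV
#'
#' Records must be homogeneous (same keys); `image_id`, when present, is
#' moved to the first column so tables from different stages align.
#'
#' @param results a data frame, or a list of named lists (records).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.data.frame(results)) {
    if (nrow(results) == 0) stop("cannot write an empty results table")
    df <- results
  } else {
    if (length(results) == 0) stop("cannot write an empty results table")
    keys <- names(results[[1]])
    for (i in seq_along(results)) {
      extra <- c(setdiff(names(results[[i]]), keys), setdiff(keys, names(results[[i]])))
      if (length(extra) > 0)
        stop(sprintf("record %d has mismatched key(s): %s", i, paste(unique(extra), collapse = ", ")))
    }
    df <- do.call(rbind, lapply(results, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if ("image_id" %in% names(df))
    df <- df[, c("image_id", setdiff(names(df), "image_id")), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load an image-to-group assignment table
#'
#' @param path CSV with header `image_id,condition` and optionally
#'   `timepoint` and `pair_key` columns.
#' @return data frame with at least `image_id` and `condition`.
#' @export
load_group_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("group table missing column(s): %s", paste(missing_cols, collapse = ", ")))
  dup <- unique(df$image_id[duplicated(df$image_id)])
  if (length(dup) > 0)
    stop(sprintf("duplicate image_id in group table: %s", paste(dup, collapse = ", ")))
  df
}
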