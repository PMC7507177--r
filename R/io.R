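#' Intensity image container
#'
#' Wraps a 2D matrix of unit-range intensities together with the physical
#' pixel size. All pipeline functions consume this container; [load_image()]
#' builds it from a file, [intensity_image()] from an in-memory matrix.
#'
#' @param pixels Numeric matrix with values in \[0, 1\] (rows = image rows).
#' @param pixel_size_um Physical edge length of one (square) pixel, in
#'   micrometers.
#' @param source_bit_depth Bit depth of the originating raster (8 or 16).
#' @return An object of class `reaver_image` with fields `pixels`,
#'   `pixel_size_um`, `source_bit_depth`.
#' @export
intensity_image <- function(pixels, pixel_size_um, source_bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3x3 pixels", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a positive scalar", call. = FALSE)
  if (!source_bit_depth %in% c(8L, 16L))
    stop("'source_bit_depth' must be 8 or 16", call. = FALSE)
  structure(list(pixels = pixels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 source_bit_depth = as.integer(source_bit_depth)),
            class = "reaver_image")
}

#' @export
print.reaver_image <- function(x, ...) {
  cat(sprintf("reaver intensity image: %d x %d px, %.4g um/px, %d-bit source\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$source_bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

png_bit_depth <- function(path) {
  # IHDR bit depth is the 25th byte of the file (after the 8-byte signature,
  # 4-byte length, 4-byte chunk type, and 8 bytes of width/height)
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("not a PNG file: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(px, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
    list(pixels = px, bits = as.integer(bits), scaled = FALSE)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    list(pixels = px, bits = png_bit_depth(path), scaled = TRUE)
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)",
         call. = FALSE)
  }
}

#' Load a grayscale microscopy image
#'
#' Reads an 8- or 16-bit TIFF or PNG and normalizes intensities to \[0, 1\] by
#' dividing by the dtype maximum (255 or 65535), so that the default
#' segmentation threshold is meaningful regardless of bit depth. Pixel size is
#' always user-supplied; embedded metadata is ignored.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size_um Physical pixel size in micrometers per pixel.
#' @param channel For multichannel images, which channel to extract (1-based).
#'   Multichannel input without an explicit channel is an error; channels are
#'   never merged silently.
#' @return A `reaver_image` (see [intensity_image()]).
#' @export
load_image <- function(path, pixel_size_um, channel = NULL) {
  r <- read_raster(path)
  px <- r$pixels
  if (length(dim(px)) == 3L) {
    if (is.null(channel))
      stop("image has ", dim(px)[3L],
           " channels; supply 'channel' explicitly", call. = FALSE)
    if (channel < 1L || channel > dim(px)[3L])
      stop("channel ", channel, " out of range", call. = FALSE)
    px <- px[, , channel]
  }
  if (!r$bits %in% c(8L, 16L))
    stop("unsupported bit depth: ", r$bits, call. = FALSE)
  if (!r$scaled) px <- px / (2^r$bits - 1)
  intensity_image(px, pixel_size_um, r$bits)
}

#' Save or load a binary mask
#'
#' Masks are written as 8-bit single-channel rasters with values 0/255 so the
#' round trip through disk is pixel-exact.
#'
#' @param mask Logical matrix.
#' @param path Destination (`.png`, `.tif`/`.tiff`).
#' @return `save_mask()` returns `path` invisibly; `load_mask()` returns a
#'   logical matrix.
#' @export
save_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported mask format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  r <- read_raster(path)
  px <- r$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (!r$scaled) px <- px / (2^r$bits - 1)
  px > 0.5
}

#' Save an intensity image
#'
#' Writes a `reaver_image` (or unit-range matrix) as a 16-bit TIFF or PNG.
#'
#' @param img A `reaver_image` or numeric matrix in \[0, 1\].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  px <- if (inherits(img, "reaver_image")) img$pixels else img
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(px, path)
  } else {
    stop("unsupported image format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write a vessel-metrics table to CSV
#'
#' @param rows A data frame as returned by [vessel_metrics_row()] /
#'   [run_batch()], or a list of such rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(rows, path) {
  cols <- c("image_id", "vessel_length_density_mm_per_mm2",
            "vessel_area_fraction", "mean_vessel_diameter_um",
            "branchpoint_count")
  if (is.data.frame(rows)) {
    df <- rows
  } else if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
  } else {
    df <- do.call(rbind, lapply(rows, as.data.frame))
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0)
    stop("metrics table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
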