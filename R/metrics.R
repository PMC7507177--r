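#' Vessel area fraction
#'
#' Fraction of image pixels classified as vessel.
#'
#' @param seg Logical matrix (or `reaver_segmentation`).
#' @return A number in \[0, 1\].
#' @export
vessel_area_fraction <- function(seg) {
  m <- if (inherits(seg, "reaver_segmentation")) seg$mask else seg
  stopifnot(is.matrix(m), is.logical(m))
  mean(m)
}

#' Vessel length density
#'
#' Total centerline length per unit tissue area, in mm/mm^2. Length is the
#' centerline pixel count converted to mm (no diagonal correction, by
#' definition of the metric); area is the full image field of view.
#'
#' @param centerline Logical matrix (or `reaver_centerline`).
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @return Length density in mm/mm^2.
#' @export
vessel_length_density <- function(centerline, pixel_size_um) {
  m <- if (inherits(centerline, "reaver_centerline")) centerline$centerline
       else centerline
  stopifnot(is.matrix(m), is.logical(m), pixel_size_um > 0)
  if (length(m) == 0L) stop("zero-size image", call. = FALSE)
  len_mm <- sum(m) * pixel_size_um * 1e-3
  area_mm2 <- nrow(m) * ncol(m) * pixel_size_um^2 * 1e-6
  len_mm / area_mm2
}

#' Mean vessel diameter
#'
#' The Euclidean distance transform of the segmentation, sampled at the
#' centerline pixels, gives local radii; diameters are `2 * radius - 1`
#' pixels (the subtraction removes the double-counted center pixel),
#' converted to micrometers. The mean pools all centerline pixels.
#'
#' @param seg Logical matrix (or `reaver_segmentation`).
#' @param centerline Logical matrix (or `reaver_centerline`).
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @return Mean diameter in micrometers; `NA_real_` (with a warning) for an
#'   empty centerline.
#' @export
mean_vessel_diameter <- function(seg, centerline, pixel_size_um) {
  sm <- if (inherits(seg, "reaver_segmentation")) seg$mask else seg
  cm <- if (inherits(centerline, "reaver_centerline")) centerline$centerline
        else centerline
  stopifnot(is.matrix(sm), is.logical(sm), identical(dim(sm), dim(cm)),
            pixel_size_um > 0)
  if (!any(cm)) {
    warning("empty centerline: mean vessel diameter is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  edt <- euclidean_distance_map(sm)
  mean(2 * edt[cm] - 1) * pixel_size_um
}

#' Branchpoint count
#'
#' @param x A `reaver_centerline` (or a logical centerline matrix, in which
#'   case branchpoints are detected first).
#' @return Integer count of branchpoints (border excluded).
#' @export
branchpoint_count <- function(x) {
  bp <- if (inherits(x, "reaver_centerline")) x$branchpoints
        else find_branchpoints(x)
  nrow(bp)
}

#' Pixel/micrometer unit conversions
#'
#' @param length_px,area_px Quantity in pixels / squared pixels.
#' @param pixel_size_um Pixel size in micrometers per pixel (> 0).
#' @return The quantity in micrometers / squared micrometers.
#' @examples
#' px_to_um(3, 40 / 128)    # thickness threshold at 20x -> 0.9375 um
#' px_to_um(11, 40 / 128)   # smoothing filter at 20x -> 3.4375 um
#' @export
px_to_um <- function(length_px, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  length_px * pixel_size_um
}

#' @rdname px_to_um
#' @export
px_area_to_um2 <- function(area_px, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  area_px * pixel_size_um^2
}

#' Compute the four vessel-architecture metrics
#'
#' @param seg A `reaver_segmentation` or logical matrix.
#' @param cl A `reaver_centerline` or logical matrix.
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @param image_id Identifier for the metrics row.
#' @return A one-row data frame with columns `image_id`,
#'   `vessel_length_density_mm_per_mm2`, `vessel_area_fraction`,
#'   `mean_vessel_diameter_um`, `branchpoint_count`.
#' @export
vessel_metrics_row <- function(seg, cl, pixel_size_um, image_id = "image") {
  sm <- if (inherits(seg, "reaver_segmentation")) seg$mask else seg
  cm <- if (inherits(cl, "reaver_centerline")) cl$centerline else cl
  data.frame(
    image_id = image_id,
    vessel_length_density_mm_per_mm2 =
      vessel_length_density(cm, pixel_size_um),
    vessel_area_fraction = vessel_area_fraction(sm),
    mean_vessel_diameter_um = suppressWarnings(
      mean_vessel_diameter(sm, cm, pixel_size_um)),
    branchpoint_count = if (inherits(cl, "reaver_centerline"))
      branchpoint_count(cl) else branchpoint_count(cm),
    stringsAsFactors = FALSE
  )
}
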