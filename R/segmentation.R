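#' Background subtraction
#'
#' Subtracts a heavily blurred background estimate from a lightly blurred copy
#' of the image, isolating structures brighter than their local surroundings.
#' Values may be negative; they are kept as-is (thresholding later treats them
#' identically either way).
#'
#' @param img A `reaver_image` or numeric matrix.
#' @param light_k Light averaging filter size in pixels (must be smaller than
#'   `heavy_k`).
#' @param heavy_k Heavy (background) averaging filter size in pixels.
#' @return Numeric matrix of the same shape.
#' @export
background_subtract <- function(img, light_k, heavy_k) {
  px <- if (inherits(img, "reaver_image")) img$pixels else img
  if (light_k >= heavy_k)
    stop("'light_k' must be strictly smaller than 'heavy_k'", call. = FALSE)
  box_blur(px, light_k) - box_blur(px, heavy_k)
}

#' Segment vessels in an intensity image
#'
#' Stage one of the pipeline. In order: (1) background subtraction
#' (light vs heavy averaging filter); (2) threshold the result at
#' `grey_to_binary_threshold` (strictly greater-than); (3) 8-neighborhood
#' filter keeping pixels with >= 4 true neighbors; (4) removal of 8-connected
#' components smaller than `min_connected_component_area`; (5) local-majority
#' boundary smoothing (`smooth_filter_size` square, fraction 0.5); (6) filling
#' of holes smaller than `hole_fill_area_seg`; (7) one thinning iteration to
#' compensate the net one-pixel dilation introduced by the smoothing steps;
#' (8) a final small-component removal.
#'
#' @param img A `reaver_image`.
#' @param params A `reaver_params` object.
#' @return An object of class `reaver_segmentation`: a list with `mask`
#'   (logical matrix), `background_subtracted` (numeric matrix, diagnostic),
#'   `params_used`, and `pixel_size_um`.
#' @seealso [extract_centerline()], [vessel_metrics_row()]
#' @export
segment_vessels <- function(img, params = reaver_params()) {
  stopifnot(inherits(img, "reaver_image"))
  validate_params(params)
  if (params$averaging_filter_size > min(dim(img$pixels)))
    stop("image (", paste(dim(img$pixels), collapse = "x"),
         ") is smaller than the averaging filter (",
         params$averaging_filter_size, ")", call. = FALSE)
  sub <- background_subtract(img$pixels, params$light_blur_size,
                             params$averaging_filter_size)
  m <- sub > params$grey_to_binary_threshold
  m <- neighbor_filter(m, "keep_if", 4L)
  m <- remove_small_components(m, params$min_connected_component_area)
  m <- local_majority_smooth(m, params$smooth_filter_size, 0.5)
  m <- fill_small_holes(m, params$hole_fill_area_seg)
  m <- bwmorph_op(m, "thin", 1L)
  m <- remove_small_components(m, params$min_connected_component_area)
  structure(list(mask = m,
                 background_subtracted = sub,
                 params_used = params,
                 pixel_size_um = img$pixel_size_um),
            class = "reaver_segmentation")
}

#' @export
print.reaver_segmentation <- function(x, ...) {
  cat(sprintf("reaver segmentation: %d x %d px, area fraction %.4f\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask)))
  invisible(x)
}

# step (2) of segment_vessels in isolation; used to check threshold
# monotonicity where the contract pins it (the initial mask, not the
# end-to-end result)
initial_threshold_mask <- function(img, params) {
  sub <- background_subtract(
    if (inherits(img, "reaver_image")) img$pixels else img,
    params$light_blur_size, params$averaging_filter_size)
  sub > params$grey_to_binary_threshold
}
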