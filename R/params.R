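#' Algorithm parameters
#'
#' Constructs the validated set of tunable parameters controlling the
#' segmentation and centerline stages. Defaults are the algorithm's published
#' batch-mode defaults; the light blur, hole-fill areas and smoothing filter
#' size are fixed internals of the published pipeline exposed here for
#' completeness.
#'
#' @param averaging_filter_size Side length in pixels of the heavy averaging
#'   filter that estimates the low-frequency background (default 128).
#' @param grey_to_binary_threshold Scalar threshold applied to the
#'   background-subtracted image, on the unit intensity scale (default 0.045).
#' @param min_connected_component_area Minimum area in pixels of an 8-connected
#'   foreground component; smaller components are discarded (default 1600).
#' @param wire_dilation_threshold Number of 3x3 dilation passes applied to the
#'   segmentation before centerline extraction (default 0, i.e. none).
#' @param vessel_thickness_threshold Minimum mean vessel radius in pixels for a
#'   centerline segment to be kept (default 3).
#' @param light_blur_size Side length in pixels of the light averaging filter
#'   applied before background estimation; 3 gives the 8-neighborhood
#'   averaging kernel (default 3).
#' @param hole_fill_area_seg Holes (4-connected background components) smaller
#'   than this many pixels are filled during segmentation (default 800).
#' @param hole_fill_area_centerline Hole-fill area used while preparing the
#'   mask for skeletonization (default 80).
#' @param smooth_filter_size Side length in pixels of the local-majority
#'   boundary smoothing filter (default 11).
#'
#' @return An object of class `reaver_params` (a named list).
#' @examples
#' p <- reaver_params()
#' p$grey_to_binary_threshold
#' @export
reaver_params <- function(averaging_filter_size = 128,
                          grey_to_binary_threshold = 0.045,
                          min_connected_component_area = 1600,
                          wire_dilation_threshold = 0,
                          vessel_thickness_threshold = 3,
                          light_blur_size = 3,
                          hole_fill_area_seg = 800,
                          hole_fill_area_centerline = 80,
                          smooth_filter_size = 11) {
  p <- list(
    averaging_filter_size = as.integer(averaging_filter_size),
    grey_to_binary_threshold = as.numeric(grey_to_binary_threshold),
    min_connected_component_area = as.integer(min_connected_component_area),
    wire_dilation_threshold = as.integer(wire_dilation_threshold),
    vessel_thickness_threshold = as.numeric(vessel_thickness_threshold),
    light_blur_size = as.integer(light_blur_size),
    hole_fill_area_seg = as.integer(hole_fill_area_seg),
    hole_fill_area_centerline = as.integer(hole_fill_area_centerline),
    smooth_filter_size = as.integer(smooth_filter_size)
  )
  class(p) <- "reaver_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "reaver_params"))
  pos <- c("averaging_filter_size", "min_connected_component_area",
           "light_blur_size", "hole_fill_area_seg",
           "hole_fill_area_centerline", "smooth_filter_size")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] < 1L)
      stop("parameter '", f, "' must be a positive integer", call. = FALSE)
  }
  if (!is.finite(p$wire_dilation_threshold) || p$wire_dilation_threshold < 0L)
    stop("'wire_dilation_threshold' must be >= 0", call. = FALSE)
  if (!is.finite(p$vessel_thickness_threshold) ||
      p$vessel_thickness_threshold < 0)
    stop("'vessel_thickness_threshold' must be >= 0", call. = FALSE)
  t <- p$grey_to_binary_threshold
  if (!is.finite(t) || t <= 0 || t >= 1)
    stop("'grey_to_binary_threshold' must lie in (0, 1)", call. = FALSE)
  if (p$light_blur_size >= p$averaging_filter_size)
    stop("'light_blur_size' must be smaller than 'averaging_filter_size'",
         call. = FALSE)
  invisible(p)
}

#' @export
print.reaver_params <- function(x, ...) {
  cat("reaver algorithm parameters:\n")
  for (f in names(x)) cat(sprintf("  %-30s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read or write parameters as a JSON configuration file
#'
#' The JSON object uses exactly the field names of [reaver_params()]; absent
#' fields fall back to defaults, unknown fields are an error.
#'
#' @param path Path to a JSON file.
#' @param params A `reaver_params` object.
#' @return `read_params_json()` returns a `reaver_params` object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(reaver_params))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown parameter field(s) in config: ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(reaver_params, raw)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
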