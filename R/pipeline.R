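#' Analyze one intensity image end to end
#'
#' Runs segmentation, centerline extraction and metric computation.
#'
#' @param img A `reaver_image`.
#' @param params A `reaver_params`.
#' @param image_id Identifier used in the metrics row.
#' @return A list with `segmentation` (`reaver_segmentation`), `centerline`
#'   (`reaver_centerline`) and `metrics` (one-row data frame).
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(topology = "y_junction", seed = 1))
#' res <- reaver_analyze(ph$image)
#' res$metrics
#' }
#' @export
reaver_analyze <- function(img, params = reaver_params(),
                           image_id = "image") {
  seg <- segment_vessels(img, params)
  cl <- extract_centerline(seg, params)
  list(segmentation = seg,
       centerline = cl,
       metrics = vessel_metrics_row(seg, cl, img$pixel_size_um, image_id))
}

#' Batch-process a set of images
#'
#' Processes each input image with the same parameters, writing per-image
#' segmentation and centerline masks, a branch/endpoint CSV, a consolidated
#' metrics CSV and a JSON sidecar of the parameters used. Per-image failures
#' are logged and skipped; the run is deterministic and order-preserving.
#'
#' @param input_paths Character vector of image paths.
#' @param pixel_size_um Pixel size in micrometers per pixel (shared).
#' @param params A `reaver_params`.
#' @param output_dir Output directory (created if absent).
#' @param channel Optional channel index for multichannel inputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `metrics` (data frame, one row per
#'   successfully processed image) and `failures` (named character vector of
#'   error messages). An error is raised if no input exists.
#' @export
run_batch <- function(input_paths, pixel_size_um,
                      params = reaver_params(),
                      output_dir = ".", channel = NULL, quiet = FALSE) {
  validate_params(params)
  missing_in <- input_paths[!file.exists(input_paths)]
  if (length(input_paths) == 0L || length(missing_in) == length(input_paths))
    stop("no readable input images", call. = FALSE)
  if (length(missing_in) > 0L)
    warning("missing input(s): ", paste(missing_in, collapse = ", "),
            call. = FALSE)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  write_params_json(params, file.path(output_dir, "params.json"))
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           ...)
  rows <- list()
  failures <- character(0)
  for (path in input_paths) {
    id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      say("processing ", basename(path))
      img <- load_image(path, pixel_size_um, channel)
      out <- reaver_analyze(img, params, image_id = id)
      save_mask(out$segmentation$mask,
                file.path(output_dir, paste0(id, "_seg.png")))
      save_mask(out$centerline$centerline,
                file.path(output_dir, paste0(id, "_centerline.png")))
      pts <- rbind(
        if (nrow(out$centerline$branchpoints) > 0L)
          data.frame(type = "branch", out$centerline$branchpoints),
        if (nrow(out$centerline$endpoints) > 0L)
          data.frame(type = "end", out$centerline$endpoints)
      )
      if (is.null(pts))
        pts <- data.frame(type = character(0), row = integer(0),
                          col = integer(0))
      utils::write.csv(pts, file.path(output_dir, paste0(id, "_points.csv")),
                       row.names = FALSE)
      out$metrics
    }, error = function(e) {
      say("FAILED on ", basename(path), ": ", conditionMessage(e))
      failures[[path]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  metrics <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(image_id = character(0),
               vessel_length_density_mm_per_mm2 = numeric(0),
               vessel_area_fraction = numeric(0),
               mean_vessel_diameter_um = numeric(0),
               branchpoint_count = integer(0))
  write_metrics_table(metrics, file.path(output_dir, "metrics.csv"))
  invisible(list(metrics = metrics, failures = failures))
}
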