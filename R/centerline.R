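## Stage two: skeletonization and refinement.
##
## The segmentation is smoothed and bridged, thinned to a unit-width
## centerline (with replicate padding so vessels crossing the image border
## keep centerline pixels at the border), radii are sampled from the
## Euclidean distance transform of the *unsmoothed* segmentation, the
## centerline is cut at branchpoints into segments, segments thinner than the
## thickness threshold are pruned, and branch/endpoints are reported away
## from the image border.

#' Pre-smooth a segmentation for skeletonization
#'
#' Applies, in order: eight iterations of the set-if-4-neighbors filter;
#' four applications of the ordered pair bridge-then-fill; one 3x3 majority
#' filter (>= 5 of 9); hole filling below `hole_fill_area`.
#'
#' @param mask Logical matrix.
#' @param hole_fill_area Holes smaller than this are filled (default 80).
#' @return Logical matrix.
#' @export
presmooth_for_skeleton <- function(mask, hole_fill_area = 80L) {
  for (i in 1:8) mask <- neighbor_filter(mask, "set_if", 4L)
  for (i in 1:4) {
    mask <- bwmorph_op(mask, "bridge", 1L)
    mask <- bwmorph_op(mask, "fill", 1L)
  }
  mask <- bwmorph_op(mask, "majority", 1L)
  fill_small_holes(mask, hole_fill_area)
}

#' Initial centerline of a segmentation
#'
#' Pre-smooths the mask and thins it to a fixed point with replicate padding.
#'
#' @inheritParams presmooth_for_skeleton
#' @return Unit-width logical matrix.
#' @export
initial_centerline <- function(mask, hole_fill_area = 80L) {
  thin_replicate_pad(presmooth_for_skeleton(mask, hole_fill_area))
}

#' Sample vessel radii along a centerline
#'
#' The Euclidean distance transform of the segmentation (distance to the
#' nearest background pixel) evaluated at centerline pixels is the local
#' vessel radius in pixels.
#'
#' @param seg_mask Logical matrix, the segmentation.
#' @param centerline Logical matrix, the (unit-width) centerline.
#' @return A data frame with columns `row`, `col`, `radius_px`, ordered
#'   row-major. Centerline pixels outside the segmentation get radius 0 and
#'   raise a warning.
#' @export
sample_radii <- function(seg_mask, centerline) {
  stopifnot(identical(dim(seg_mask), dim(centerline)))
  if (!any(centerline))
    return(data.frame(row = integer(0), col = integer(0),
                      radius_px = numeric(0)))
  edt <- euclidean_distance_map(seg_mask)
  px <- which(centerline, arr.ind = TRUE)
  px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
  r <- edt[px]
  if (any(r == 0))
    warning(sum(r == 0), " centerline pixel(s) fall outside the segmentation;",
            " radius 0 recorded", call. = FALSE)
  data.frame(row = as.integer(px[, 1L]), col = as.integer(px[, 2L]),
             radius_px = as.numeric(r))
}

# skeleton pixels with >= 3 true skeleton 8-neighbors (no border exclusion;
# used structurally to cut the centerline into segments)
branch_pixels <- function(centerline) {
  centerline & (neighbor_count(centerline) >= 3L)
}

#' Cut a centerline into vessel segments at its branchpoints
#'
#' Branch pixels (>= 3 skeleton neighbors) are removed; each remaining
#' 8-connected component is one vessel segment with the mean of the sampled
#' radii over its pixels.
#'
#' @param centerline Unit-width logical matrix.
#' @param radius_map Data frame from [sample_radii()].
#' @return A list of segments, each a list with `pixels` (two-column matrix of
#'   row/col) and `mean_radius_px`.
#' @export
split_into_segments <- function(centerline, radius_map) {
  bp <- branch_pixels(centerline)
  rest <- centerline & !bp
  lab <- label_components(rest, 8L)
  nseg <- max(lab)
  if (nseg == 0L) return(list())
  rad <- matrix(0, nrow(centerline), ncol(centerline))
  rad[cbind(radius_map$row, radius_map$col)] <- radius_map$radius_px
  out <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    px <- which(lab == s, arr.ind = TRUE)
    px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
    out[[s]] <- list(pixels = unname(px),
                     mean_radius_px = mean(rad[px]))
  }
  out
}

#' Prune centerline segments thinner than a radius threshold
#'
#' Segments whose mean radius falls strictly below `thickness_threshold` are
#' deleted. Branch pixels are restored where at least two surviving segments
#' still touch them (keeping the network connected without resurrecting
#' pruned spurs), and the result is cleaned with one spur pass, one clean
#' pass, and a final thinning to convergence.
#'
#' @param centerline Unit-width logical matrix.
#' @param radius_map Data frame from [sample_radii()].
#' @param thickness_threshold Minimum mean segment radius in pixels (>= 0).
#' @return Logical matrix.
#' @export
prune_thin_segments <- function(centerline, radius_map, thickness_threshold) {
  stopifnot(thickness_threshold >= 0)
  segs <- split_into_segments(centerline, radius_map)
  bp <- branch_pixels(centerline)
  keep <- matrix(FALSE, nrow(centerline), ncol(centerline))
  for (s in segs) {
    if (s$mean_radius_px >= thickness_threshold) keep[s$pixels] <- TRUE
  }
  # restore each 8-connected cluster of branch pixels iff >= 2 surviving
  # segments touch the cluster (interior cluster pixels touch other cluster
  # pixels rather than segments, so restoration must act per cluster)
  lab <- label_components(bp, 8L)
  if (max(lab) > 0L) {
    surviving <- Filter(function(s) s$mean_radius_px >= thickness_threshold,
                        segs)
    for (k in seq_len(max(lab))) {
      cpx <- which(lab == k, arr.ind = TRUE)
      n_touch <- 0L
      for (s in surviving) {
        touch <- FALSE
        for (i in seq_len(nrow(cpx))) {
          d <- pmax(abs(s$pixels[, 1L] - cpx[i, 1L]),
                    abs(s$pixels[, 2L] - cpx[i, 2L]))
          if (any(d <= 1L)) { touch <- TRUE; break }
        }
        if (touch) n_touch <- n_touch + 1L
        if (n_touch >= 2L) break
      }
      if (n_touch >= 2L) keep[cpx] <- TRUE
    }
  }
  keep <- bwmorph_op(keep, "spur", 1L)
  keep <- bwmorph_op(keep, "clean", 1L)
  bwmorph_op(keep, "thin", Inf)
}

#' Locate branchpoints / endpoints of a centerline
#'
#' Branch pixels are centerline pixels with at least three true 8-neighbors
#' on the centerline. A digital junction is usually represented by a small
#' cluster of 2-4 mutually adjacent branch pixels, so one branchpoint is
#' reported per 8-connected cluster (its first pixel in row-major order);
#' this makes the count equal the number of network junctions. Endpoints have
#' exactly one true 8-neighbor. Pixels on the outermost image row or column
#' are excluded, because border effects there produce false positives.
#' Coordinates are reported in row-major order.
#'
#' @param centerline Unit-width logical matrix.
#' @return An integer matrix with columns `row`, `col`.
#' @export
find_branchpoints <- function(centerline) {
  sel <- branch_pixels(centerline)
  h <- nrow(sel); w <- ncol(sel)
  sel[c(1L, h), ] <- FALSE
  sel[, c(1L, w)] <- FALSE
  lab <- label_components(sel, 8L)
  n <- max(lab)
  out <- matrix(integer(0), 0L, 2L)
  if (n > 0L) {
    px <- which(sel, arr.ind = TRUE)
    px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
    first <- !duplicated(lab[px])
    out <- px[first, , drop = FALSE]
    out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  }
  colnames(out) <- c("row", "col")
  out
}

#' @rdname find_branchpoints
#' @export
find_endpoints <- function(centerline) {
  sel <- centerline & (neighbor_count(centerline) == 1L)
  exclude_border(sel)
}

exclude_border <- function(sel) {
  h <- nrow(sel); w <- ncol(sel)
  sel[c(1L, h), ] <- FALSE
  sel[, c(1L, w)] <- FALSE
  px <- which(sel, arr.ind = TRUE)
  px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
  colnames(px) <- c("row", "col")
  px
}

#' Extract the refined vessel centerline
#'
#' Runs the full second stage on a segmentation mask: optional wire dilation,
#' pre-smoothing, replicate-padded thinning, radius sampling from the
#' distance transform of the stage-one segmentation, thickness-based segment
#' pruning, and branch/endpoint detection.
#'
#' @param seg Either a `reaver_segmentation` or a logical matrix.
#' @param params A `reaver_params` object.
#' @return An object of class `reaver_centerline`: list with `centerline`
#'   (unit-width logical matrix), `radius_map` (data frame row/col/radius_px
#'   over the final centerline), `branchpoints`, `endpoints` (integer
#'   matrices), and `segments` (as [split_into_segments()]).
#' @export
extract_centerline <- function(seg, params = reaver_params()) {
  mask <- if (inherits(seg, "reaver_segmentation")) seg$mask else seg
  stopifnot(is.matrix(mask), is.logical(mask))
  validate_params(params)
  if (params$wire_dilation_threshold > 0L)
    mask <- dilate3(mask, params$wire_dilation_threshold)
  cl <- initial_centerline(mask, params$hole_fill_area_centerline)
  rm0 <- suppressWarnings(sample_radii(mask, cl))
  cl <- prune_thin_segments(cl, rm0, params$vessel_thickness_threshold)
  rmap <- suppressWarnings(sample_radii(mask, cl))
  structure(list(centerline = cl,
                 radius_map = rmap,
                 branchpoints = find_branchpoints(cl),
                 endpoints = find_endpoints(cl),
                 segments = split_into_segments(cl, rmap)),
            class = "reaver_centerline")
}

#' @export
print.reaver_centerline <- function(x, ...) {
  cat(sprintf(
    "reaver centerline: %d px, %d segment(s), %d branchpoint(s), %d endpoint(s)\n",
    sum(x$centerline), length(x$segments), nrow(x$branchpoints),
    nrow(x$endpoints)))
  invisible(x)
}
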