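## Synthetic vascular phantoms.
##
## A phantom is a planar network of straight tube segments with known
## diameters. The ground truth is analytic: the segmentation truth is the
## union of stadium footprints (all pixels within diameter/2 of a segment
## axis), the centerline truth is the thinned rasterization of the axes, and
## the expected metrics follow from arc lengths, drawn diameters and
## junction count. The rendered image emulates a maximum-intensity-projection
## confocal field: bright tube plateaus over a dim, slowly varying
## background, a small optical blur, and additive Gaussian noise.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic vascular phantom
#'
#' @param image_shape Integer vector (rows, cols) in pixels.
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @param topology One of `"single_tube"`, `"y_junction"`, `"grid"`,
#'   `"random_tree"`.
#' @param n_branches Number of tube segments (random_tree) or lines per
#'   direction (grid).
#' @param diameter_range_px Numeric length-2; drawn diameters are odd pixel
#'   values inside this range (odd diameters are recovered exactly by the
#'   `2*EDT - 1` estimator on axis-aligned tubes).
#' @param plateau_intensity Added intensity on the tube footprint, in (0, 1].
#' @param background_level Constant background intensity, in \[0, 1).
#' @param background_gradient_amplitude Peak amplitude of the low-frequency
#'   background variation (plane plus sinusoid).
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param angle_jitter_deg Half-width in degrees of the uniform angular jitter
#'   applied to tube directions. The default 0 keeps tubes axis-aligned,
#'   where the pixel-count length and `2*EDT - 1` diameter estimators are
#'   free of discretization bias and the analytic truth is exact.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(512L, 512L),
                         pixel_size_um = 1,
                         topology = c("random_tree", "single_tube",
                                      "y_junction", "grid"),
                         n_branches = 6L,
                         diameter_range_px = c(7, 15),
                         plateau_intensity = 0.8,
                         background_level = 0.05,
                         background_gradient_amplitude = 0.1,
                         noise_sigma = 0,
                         angle_jitter_deg = 0,
                         seed = 0L) {
  topology <- match.arg(topology)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 64L),
            pixel_size_um > 0,
            n_branches >= 1L,
            length(diameter_range_px) == 2L,
            diameter_range_px[1L] >= 1,
            diameter_range_px[2L] >= diameter_range_px[1L],
            plateau_intensity > 0, plateau_intensity <= 1,
            background_level >= 0, background_level < 1,
            background_gradient_amplitude >= 0,
            noise_sigma >= 0, angle_jitter_deg >= 0, angle_jitter_deg <= 30)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 topology = topology,
                 n_branches = as.integer(n_branches),
                 diameter_range_px = diameter_range_px,
                 plateau_intensity = plateau_intensity,
                 background_level = background_level,
                 background_gradient_amplitude = background_gradient_amplitude,
                 noise_sigma = noise_sigma,
                 angle_jitter_deg = angle_jitter_deg,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

odd_diameters <- function(range) {
  lo <- ceiling(range[1L]); hi <- floor(range[2L])
  cand <- seq(lo, hi)
  cand <- cand[cand %% 2 == 1]
  if (length(cand) == 0L) cand <- round((lo + hi) / 2)
  cand
}

# sample() resamples from 1:x when x is a length-1 vector; pick() does not
pick <- function(x) x[sample.int(length(x), 1L)]

seg_len <- function(s) sqrt(sum((s$p2 - s$p1)^2))

# distance from points (n x 2 matrix, row/col) to a segment p1-p2
point_segment_dist <- function(pts, p1, p2) {
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 == 0) return(sqrt((pts[, 1L] - p1[1L])^2 + (pts[, 2L] - p1[2L])^2))
  t <- ((pts[, 1L] - p1[1L]) * v[1L] + (pts[, 2L] - p1[2L]) * v[2L]) / L2
  t <- pmin(1, pmax(0, t))
  dr <- pts[, 1L] - (p1[1L] + t * v[1L])
  dc <- pts[, 2L] - (p1[2L] + t * v[2L])
  sqrt(dr^2 + dc^2)
}

#' Sample a phantom network
#'
#' Generates the tube-segment graph for a [phantom_spec()]: straight segments
#' with endpoints, diameters, and junction vertices. Junctions are kept at
#' least 24 px apart, all tubes stay inside a 24-px margin, and the random
#' tree grows branches perpendicular to their parent (plus the optional
#' angular jitter of the spec; the axis-aligned default keeps the analytic
#' expected metrics free of discretization bias).
#'
#' @param spec A `phantom_spec`.
#' @return A list with `segments` (each: `p1`, `p2` (row/col), `diameter_px`),
#'   `junctions` (matrix row/col), `junction_count`.
#' @export
sample_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, sample_network_impl(spec))
}

sample_network_impl <- function(spec) {
  H <- spec$image_shape[1L]; W <- spec$image_shape[2L]
  M <- 24
  diams <- odd_diameters(spec$diameter_range_px)
  ja <- spec$angle_jitter_deg * pi / 180
  jit <- function() if (ja > 0) stats::runif(1, -ja, ja) else 0

  if (spec$topology == "single_tube") {
    r0 <- stats::runif(1, 0.35 * H, 0.65 * H)
    segs <- list(list(p1 = c(r0, M), p2 = c(r0, W - M),
                      diameter_px = pick(diams)))
    return(list(segments = segs,
                junctions = matrix(numeric(0), 0L, 2L),
                junction_count = 0L))
  }

  if (spec$topology == "y_junction") {
    ctr <- c(H / 2, W / 2)
    base_angles <- c(-pi / 2, pi / 6, 5 * pi / 6)
    arm_len <- 0.5 * (min(H, W) / 2 - M) + 0.3 * (min(H, W) / 2 - M)
    segs <- lapply(base_angles, function(a) {
      a <- a + stats::runif(1, -pi / 18, pi / 18)
      tip <- ctr + arm_len * c(sin(a), cos(a))
      list(p1 = ctr, p2 = tip, diameter_px = pick(diams))
    })
    return(list(segments = segs,
                junctions = matrix(ctr, 1L, 2L),
                junction_count = 1L))
  }

  if (spec$topology == "grid") {
    k <- spec$n_branches
    rows <- seq(M, H - M, length.out = k + 2L)[2:(k + 1L)]
    cols <- seq(M, W - M, length.out = k + 2L)[2:(k + 1L)]
    segs <- c(
      lapply(rows, function(r) list(p1 = c(r, M), p2 = c(r, W - M),
                                    diameter_px = pick(diams))),
      lapply(cols, function(c0) list(p1 = c(M, c0), p2 = c(H - M, c0),
                                     diameter_px = pick(diams)))
    )
    jn <- as.matrix(expand.grid(rows, cols))
    colnames(jn) <- NULL
    return(list(segments = segs, junctions = jn,
                junction_count = as.integer(k * k)))
  }

  ## random_tree: a near-horizontal trunk plus near-perpendicular branches
  theta0 <- jit()
  span <- W - 2 * M
  r_mid <- stats::runif(1, 0.4 * H, 0.6 * H)
  dr_half <- tan(theta0) * span / 2
  p1 <- c(r_mid - dr_half, M); p2 <- c(r_mid + dr_half, W - M)
  trunk_d <- max(diams)
  segs <- list(list(p1 = p1, p2 = p2, diameter_px = trunk_d))
  angles <- atan2(p2[1L] - p1[1L], p2[2L] - p1[2L])
  junctions <- matrix(numeric(0), 0L, 2L)
  attempts <- 0L
  while (length(segs) < spec$n_branches && attempts < 400L) {
    attempts <- attempts + 1L
    pi_idx <- sample(length(segs), 1L)
    par <- segs[[pi_idx]]
    t <- stats::runif(1, 0.15, 0.85)
    a <- par$p1 + t * (par$p2 - par$p1)
    if (nrow(junctions) > 0L &&
        min(sqrt((junctions[, 1L] - a[1L])^2 +
                   (junctions[, 2L] - a[2L])^2)) < 24) next
    ang <- angles[pi_idx] + sample(c(-1, 1), 1L) * pi / 2 + jit()
    dirv <- c(sin(ang), cos(ang))
    L <- stats::runif(1, 110, 200)
    # truncate to stay within the margin
    for (axis in 1:2) {
      lim <- if (axis == 1L) c(M, H - M) else c(M, W - M)
      if (dirv[axis] > 1e-9) L <- min(L, (lim[2L] - a[axis]) / dirv[axis])
      if (dirv[axis] < -1e-9) L <- min(L, (lim[1L] - a[axis]) / dirv[axis])
    }
    if (L < 80) next
    tip <- a + L * dirv
    dmax_child <- min(max(diams), par$diameter_px)
    dcand <- diams[diams <= dmax_child]
    d <- if (length(dcand) > 0L) pick(dcand) else min(diams)
    # clearance from every non-parent segment along the proposed branch
    steps <- seq(0, L, by = 2)
    pts <- cbind(a[1L] + steps * dirv[1L], a[2L] + steps * dirv[2L])
    ok <- TRUE
    for (j in seq_along(segs)) {
      if (j == pi_idx) next
      clr <- (d + segs[[j]]$diameter_px) / 2 + 8
      if (min(point_segment_dist(pts, segs[[j]]$p1, segs[[j]]$p2)) < clr) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    segs[[length(segs) + 1L]] <- list(p1 = a, p2 = tip, diameter_px = d)
    angles <- c(angles, ang)
    junctions <- rbind(junctions, a)
  }
  if (length(segs) < spec$n_branches)
    stop("could not place ", spec$n_branches,
         " branches in the image; relax the spec", call. = FALSE)
  rownames(junctions) <- NULL
  list(segments = segs, junctions = junctions,
       junction_count = nrow(junctions))
}

# integer pixels of the straight line p1-p2 (Bresenham-style supercover of
# rounded endpoints)
rasterize_axis <- function(p1, p2) {
  r1 <- round(p1[1L]); c1 <- round(p1[2L])
  r2 <- round(p2[1L]); c2 <- round(p2[2L])
  n <- max(abs(r2 - r1), abs(c2 - c1)) + 1L
  cbind(round(seq(r1, r2, length.out = n)),
        round(seq(c1, c2, length.out = n)))
}

#' Rasterize a phantom network into ground-truth masks
#'
#' The segmentation truth is the union of stadium footprints (pixels whose
#' center lies within diameter/2 of a segment axis); the centerline truth is
#' the unit-width thinning of the rasterized axes.
#'
#' @param network As returned by [sample_network()].
#' @param image_shape Integer (rows, cols).
#' @return List with logical matrices `truth_seg` and `truth_centerline`.
#' @export
rasterize_network <- function(network, image_shape) {
  H <- image_shape[1L]; W <- image_shape[2L]
  seg <- matrix(FALSE, H, W)
  cl <- matrix(FALSE, H, W)
  for (s in network$segments) {
    rad <- s$diameter_px / 2
    r_lo <- max(1L, floor(min(s$p1[1L], s$p2[1L]) - rad - 1))
    r_hi <- min(H, ceiling(max(s$p1[1L], s$p2[1L]) + rad + 1))
    c_lo <- max(1L, floor(min(s$p1[2L], s$p2[2L]) - rad - 1))
    c_hi <- min(W, ceiling(max(s$p1[2L], s$p2[2L]) + rad + 1))
    rr <- r_lo:r_hi; cc <- c_lo:c_hi
    pts <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
    d <- point_segment_dist(pts, s$p1, s$p2)
    hit <- pts[d <= rad, , drop = FALSE]
    seg[hit] <- TRUE
    ax <- rasterize_axis(s$p1, s$p2)
    ax <- ax[ax[, 1L] >= 1L & ax[, 1L] <= H &
               ax[, 2L] >= 1L & ax[, 2L] <= W, , drop = FALSE]
    cl[ax] <- TRUE
  }
  list(truth_seg = seg, truth_centerline = bwmorph_op(cl, "thin", Inf))
}

gaussian_blur <- function(img, sigma = 0.5, radius = 2L) {
  w <- stats::dnorm(seq(-radius, radius), sd = sigma)
  w <- w / sum(w)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(w)) {
    out <- out + w[i] * pad_crop_shift(img, seq(-radius, radius)[i], 0L)
  }
  img <- out
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(w)) {
    out <- out + w[i] * pad_crop_shift(img, 0L, seq(-radius, radius)[i])
  }
  out
}

# shift with replicate padding (used by the separable Gaussian)
pad_crop_shift <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Render a phantom into an intensity image
#'
#' background + low-frequency gradient + plateau on the tube footprint,
#' blurred with a small Gaussian (optical blur surrogate, sigma 0.5 px over a
#' 2-px support), plus additive Gaussian noise, clipped to \[0, 1\].
#'
#' @param truth_seg Logical matrix (rasterized tube footprint).
#' @param spec A `phantom_spec`.
#' @return A `reaver_image`.
#' @export
render_phantom <- function(truth_seg, spec) {
  with_seed(spec$seed + 1L, {
    H <- nrow(truth_seg); W <- ncol(truth_seg)
    xn <- matrix(rep(seq_len(W) / W, each = H), H, W)
    yn <- matrix(seq_len(H) / H, H, W)
    grad <- spec$background_gradient_amplitude *
      (0.5 * xn + 0.25 * (1 + sin(2 * pi * yn)))
    img <- spec$background_level + grad +
      spec$plateau_intensity * truth_seg
    img <- gaussian_blur(img, sigma = 0.5, radius = 2L)
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
    img <- pmin(pmax(img, 0), 1)
    intensity_image(img, spec$pixel_size_um, 16L)
  })
}

#' Analytic expected metrics of a phantom
#'
#' Area fraction is exact from the rasterized truth; length density comes
#' from the Euclidean arc length of the axes; mean diameter is the
#' arc-length-weighted mean of the drawn diameters (what the
#' centerline-sampled `2*EDT - 1` estimator measures); branchpoints equal the
#' graph junction count.
#'
#' @param phantom A `reaver_phantom` (or a list with `network`, `truth_seg`).
#' @param image_id Identifier for the row.
#' @return A one-row data frame in the layout of [vessel_metrics_row()].
#' @export
analytic_metrics <- function(phantom, image_id = "phantom") {
  net <- phantom$network
  seg <- phantom$truth_seg
  px_um <- phantom$spec$pixel_size_um
  lens <- vapply(net$segments, seg_len, numeric(1))
  diams <- vapply(net$segments, function(s) s$diameter_px, numeric(1))
  H <- nrow(seg); W <- ncol(seg)
  data.frame(
    image_id = image_id,
    vessel_length_density_mm_per_mm2 =
      (sum(lens) * px_um * 1e-3) / (H * W * px_um^2 * 1e-6),
    vessel_area_fraction = mean(seg),
    mean_vessel_diameter_um = sum(lens * diams) / sum(lens) * px_um,
    branchpoint_count = net$junction_count,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete phantom
#'
#' Samples the network, rasterizes the ground truth, renders the image, and
#' attaches the analytic expected metrics.
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `reaver_phantom`: list with `spec`, `network`,
#'   `truth_seg`, `truth_centerline`, `image` (a `reaver_image`), and
#'   `expected_metrics` (one-row data frame).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  net <- sample_network(spec)
  ras <- rasterize_network(net, spec$image_shape)
  ph <- structure(list(spec = spec,
                       network = net,
                       truth_seg = ras$truth_seg,
                       truth_centerline = ras$truth_centerline,
                       image = render_phantom(ras$truth_seg, spec)),
                  class = "reaver_phantom")
  ph$expected_metrics <- analytic_metrics(
    ph, image_id = paste0(spec$topology, "_seed", spec$seed))
  ph
}

#' @export
print.reaver_phantom <- function(x, ...) {
  cat(sprintf("reaver phantom: %s, %d segment(s), %d junction(s), %dx%d px\n",
              x$spec$topology, length(x$network$segments),
              x$network$junction_count, nrow(x$truth_seg), ncol(x$truth_seg)))
  print(x$expected_metrics)
  invisible(x)
}
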