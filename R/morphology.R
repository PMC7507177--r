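## Binary-morphology primitives with pinned semantics.
##
## Conventions used throughout:
##   * masks are logical matrices; foreground connectivity is 8, background
##     (hole) connectivity is 4 (the standard dual pair);
##   * neighbor counts are over the 8-neighborhood, self excluded, off-image
##     neighbors count as false;
##   * averaging filters use edge-replication padding, with the window origin
##     at offset floor(k/2) so even kernel sizes are allowed.

pad_replicate <- function(m, top, bottom = top, left = top, right = top) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, top), seq_len(h), rep(h, bottom))
  ci <- c(rep(1L, left), seq_len(w), rep(w, right))
  m[ri, ci, drop = FALSE]
}

# out[i, j] = m[i + dr, j + dc], off-image entries = fill
shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r_dst <- max(1L, 1L - dr):min(h, h - dr)
  c_dst <- max(1L, 1L - dc):min(w, w - dc)
  if (length(r_dst) < 1L || length(c_dst) < 1L) return(out)
  out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  out
}

#' Box (averaging) filter with replicate padding
#'
#' Each output pixel is the exact mean of the k-by-k window whose origin sits
#' at offset `floor(k/2)`, with borders padded by edge replication. Means are
#' computed with a summed-area table, so the cost is independent of `k`.
#'
#' @param img Numeric matrix.
#' @param k Window side length in pixels (>= 1, <= both image dimensions;
#'   even sizes allowed).
#' @return Numeric matrix of the same shape.
#' @export
box_blur <- function(img, k) {
  stopifnot(is.matrix(img))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (k > min(dim(img)))
    stop("filter size ", k, " exceeds image dimensions ",
         paste(dim(img), collapse = "x"), call. = FALSE)
  if (k == 1L) return(img)
  h <- nrow(img); w <- ncol(img)
  o <- k %/% 2L
  p <- pad_replicate(img, top = o, bottom = k - 1L - o,
                     left = o, right = k - 1L - o)
  # zero-prefixed 2D cumulative sum
  s <- matrix(0, h + k, w + k)
  s[-1L, -1L] <- apply(p, 2L, cumsum)
  s[-1L, -1L] <- t(apply(s[-1L, -1L, drop = FALSE], 1L, cumsum))
  ri <- seq_len(h); ci <- seq_len(w)
  (s[ri + k, ci + k] - s[ri, ci + k] - s[ri + k, ci] + s[ri, ci]) / (k * k)
}

# number of true 8-neighbors of each pixel (self excluded)
neighbor_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- as.integer(mask)
  acc <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  acc
}

#' Neighbor-count filter
#'
#' The 8-neighborhood convolution-and-threshold step of the pipeline:
#' `keep_if` retains a true pixel only if it has at least `min_neighbors` true
#' neighbors (it can only remove pixels); `set_if` turns on any pixel with at
#' least `min_neighbors` true neighbors (it can only add pixels).
#'
#' @param mask Logical matrix.
#' @param mode `"keep_if"` or `"set_if"`.
#' @param min_neighbors Integer in \[0, 8\].
#' @return Logical matrix.
#' @export
neighbor_filter <- function(mask, mode = c("keep_if", "set_if"),
                            min_neighbors = 4L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mask), is.logical(mask),
            min_neighbors >= 0L, min_neighbors <= 8L)
  enough <- neighbor_count(mask) >= min_neighbors
  if (mode == "keep_if") mask & enough else mask | enough
}

#' Label connected components
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (foreground convention) or 4 (background convention).
#' @return Integer matrix of component labels (0 = background), labels
#'   consecutive from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  if (connectivity == 4L) return(relabel_consecutive(lab))
  # merge 4-connected labels that touch diagonally to get 8-connectivity
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1L, -1L])),  # SE diagonal
    cbind(as.vector(lab[-h, -1L]), as.vector(lab[-1L, -w]))   # SW diagonal
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    parent <- seq_len(max(lab))
    find_root <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      a <- find_root(pairs[r, 1L]); b <- find_root(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_along(parent), find_root, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Remove small connected components
#'
#' Drops every 8-connected foreground component whose pixel area is strictly
#' less than `min_area` (a component of exactly `min_area` pixels survives).
#'
#' @param mask Logical matrix.
#' @param min_area Minimum surviving area in pixels (>= 1).
#' @return Logical matrix, a subset of the input.
#' @export
remove_small_components <- function(mask, min_area) {
  stopifnot(min_area >= 1L)
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Fill small holes
#'
#' Sets to true every 4-connected component of the complement whose area is
#' strictly less than `max_area`. Note the rule is purely by area: a small
#' border-touching background pocket is filled too.
#'
#' @param mask Logical matrix.
#' @param max_area Holes with area < `max_area` are filled.
#' @return Logical matrix, a superset of the input.
#' @export
fill_small_holes <- function(mask, max_area) {
  stopifnot(max_area >= 1L)
  lab <- label_components(!mask, 4L)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  small <- which(areas < max_area)
  mask | matrix(lab %in% small, nrow(mask), ncol(mask))
}

#' Local-majority boundary smoothing
#'
#' The complement of the mask is box-blurred with a k-square averaging filter
#' and thresholded above `frac`; the result is complemented back. A pixel is
#' therefore foreground iff the local complement fraction does not exceed
#' `frac`, which smooths ragged segmentation borders while leaving straight
#' boundaries in place.
#'
#' @param mask Logical matrix.
#' @param k Filter side length in pixels.
#' @param frac Complement-fraction threshold in (0, 1); 0.5 gives majority.
#' @return Logical matrix.
#' @export
local_majority_smooth <- function(mask, k, frac = 0.5) {
  stopifnot(frac > 0, frac < 1)
  comp <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  !(box_blur(comp, k) > frac)
}

## ---- MATLAB-semantics binary ops ------------------------------------------

# neighbor offsets in Guo-Hall order: p2..p9 = N, NE, E, SE, S, SW, W, NW
gh_offsets <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                   c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

gh_neighbors <- function(mask) {
  lapply(gh_offsets, function(o) shift_mat(mask, o[1L], o[2L], FALSE))
}

# Lookup tables over the 256 neighbor configurations (bit k-1 = gh_offsets
# cell k). Component counting among the 8 cells of the punctured 3x3
# neighborhood underlies both 'bridge' and the simple-pixel test.
lut_env <- new.env(parent = emptyenv())

config_ncomp <- function(adjacent, restrict_to = NULL) {
  coords <- do.call(rbind, gh_offsets)
  lut <- integer(256L)
  for (cfg in 0:255) {
    on <- which(bitwAnd(cfg, bitwShiftL(1L, 0:7)) != 0L)
    if (length(on) == 0L) { lut[cfg + 1L] <- 0L; next }
    seen <- rep(FALSE, length(on))
    comp_id <- integer(length(on))
    ncomp <- 0L
    for (s in seq_along(on)) {
      if (seen[s]) next
      ncomp <- ncomp + 1L
      queue <- s
      seen[s] <- TRUE
      comp_id[s] <- ncomp
      while (length(queue) > 0L) {
        cur <- queue[1L]; queue <- queue[-1L]
        for (t in seq_along(on)) {
          if (!seen[t] && adjacent(coords[on[cur], ], coords[on[t], ])) {
            seen[t] <- TRUE
            comp_id[t] <- ncomp
            queue <- c(queue, t)
          }
        }
      }
    }
    if (is.null(restrict_to)) {
      lut[cfg + 1L] <- ncomp
    } else {
      lut[cfg + 1L] <- length(unique(comp_id[on %in% restrict_to]))
    }
  }
  lut
}

# number of 8-connected components among the true neighbor cells
fg_ncomp_lut <- function() {
  if (is.null(lut_env$fg)) {
    lut_env$fg <- config_ncomp(function(a, b) max(abs(a - b)) <= 1L)
  }
  lut_env$fg
}

# number of 4-connected background components in the punctured neighborhood
# that are 4-adjacent to the center (i.e. contain an edge cell; edge cells
# are gh cells 1, 3, 5, 7 = N, E, S, W)
bg_ncomp_lut <- function() {
  if (is.null(lut_env$bg)) {
    lut_env$bg <- config_ncomp(function(a, b) sum(abs(a - b)) == 1L,
                               restrict_to = c(1L, 3L, 5L, 7L))
  }
  lut_env$bg
}

neighbor_config_index <- function(nb) {
  idx <- matrix(1L, nrow(nb[[1]]), ncol(nb[[1]]))
  for (b in 1:8) idx <- idx + as.integer(nb[[b]]) * bitwShiftL(1L, b - 1L)
  idx
}

bwmorph_once <- function(mask, kind) {
  nb <- gh_neighbors(mask)
  cnt <- neighbor_count(mask)
  switch(kind,
    bridge = {
      lut <- fg_ncomp_lut()
      ncomp <- matrix(lut[neighbor_config_index(nb)], nrow(mask), ncol(mask))
      mask | (!mask & ncomp >= 2L)
    },
    fill = mask | (!mask & nb[[1]] & nb[[3]] & nb[[5]] & nb[[7]]),
    majority = (cnt + as.integer(mask)) >= 5L,
    clean = mask & cnt >= 1L,
    spur = mask & cnt >= 2L,
    thin = thin_cycle(mask),
    stop("unknown bwmorph kind: ", kind, call. = FALSE)
  )
}

# Per-pixel test: is the true pixel (r, c) (8,4)-simple and not an endpoint?
# Simplicity is relative to the image embedded in an infinite background
# plane (off-image cells count as background, the bwmorph convention):
# exactly one foreground component among its neighbors, and exactly one
# background component 4-adjacent to it.
pixel_simple_nonend <- function(mask, r, c) {
  h <- nrow(mask); w <- ncol(mask)
  fg_idx <- 1L; bg_idx <- 1L; cnt <- 0L
  for (b in 1:8) {
    o <- gh_offsets[[b]]
    rr <- r + o[1L]; cc <- c + o[2L]
    if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && mask[rr, cc]) {
      fg_idx <- fg_idx + bitwShiftL(1L, b - 1L)
      cnt <- cnt + 1L
    } else {
      bg_idx <- bg_idx + bitwShiftL(1L, b - 1L)
    }
  }
  cnt >= 2L && fg_ncomp_lut()[fg_idx] == 1L && bg_ncomp_lut()[bg_idx] == 1L
}

# vectorized simplicity ingredients for every pixel: foreground component
# count t8, background component count t4 (4-adjacent to center; off-image
# cells count as background), and true-neighbor count
simplicity_fields <- function(mask) {
  nb <- gh_neighbors(mask)
  idx_fg <- 1 + nb[[1]] + 2 * nb[[2]] + 4 * nb[[3]] + 8 * nb[[4]] +
    16 * nb[[5]] + 32 * nb[[6]] + 64 * nb[[7]] + 128 * nb[[8]]
  cnt <- nb[[1]] + nb[[2]] + nb[[3]] + nb[[4]] +
    nb[[5]] + nb[[6]] + nb[[7]] + nb[[8]]
  # bg bits are the complement of the fg bits (off-image cells, which carry
  # fg bit 0, count as background)
  idx_bg <- 257 - idx_fg
  t8 <- fg_ncomp_lut()[idx_fg]; dim(t8) <- dim(mask)
  t4 <- bg_ncomp_lut()[idx_bg]; dim(t4) <- dim(mask)
  list(t8 = t8, t4 = t4, cnt = cnt, nb = nb)
}

# One full thinning iteration: the two Guo-Hall subiterations, with deletion
# additionally gated on in-image (8,4)-simplicity and endpoint preservation.
# Within a subiteration the candidate set is applied in four parity waves
# ((odd/even row) x (odd/even column)); same-parity pixels are never
# 8-adjacent, so deleting a wave in parallel -- after re-checking simplicity
# against the current mask -- is equivalent to deleting its pixels one at a
# time. Every actual deletion is a simple-pixel deletion, so in-image
# topology (foreground 8-components, background 4-components) is preserved
# exactly.
thin_cycle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  rpar <- matrix(seq_len(h) %% 2L == 1L, h, w)
  cpar <- matrix(rep(seq_len(w) %% 2L == 1L, each = h), h, w)
  waves <- list(rpar & cpar, rpar & !cpar, !rpar & cpar, !rpar & !cpar)
  for (sub in 1:2) {
    f <- simplicity_fields(mask)
    nb <- f$nb
    n1 <- (nb[[8]] | nb[[1]]) + (nb[[2]] | nb[[3]]) +
      (nb[[4]] | nb[[5]]) + (nb[[6]] | nb[[7]])
    n2 <- (nb[[1]] | nb[[2]]) + (nb[[3]] | nb[[4]]) +
      (nb[[5]] | nb[[6]]) + (nb[[7]] | nb[[8]])
    nmin <- pmin(n1, n2)
    ghm <- if (sub == 1L) (nb[[5]] | nb[[6]] | !nb[[8]]) & nb[[7]]
           else (nb[[1]] | nb[[2]] | !nb[[4]]) & nb[[3]]
    cand <- mask & (f$t8 == 1L) & (f$t4 == 1L) & (f$cnt >= 2L) &
      (nmin >= 2L) & (nmin <= 3L) & !ghm
    if (!any(cand)) next
    g <- f
    stale <- FALSE
    for (wv in waves) {
      sel <- cand & wv
      if (!any(sel)) next
      if (stale) { g <- simplicity_fields(mask); stale <- FALSE }
      del <- sel & g$t8 == 1L & g$t4 == 1L & g$cnt >= 2L
      if (any(del)) {
        mask <- mask & !del
        stale <- TRUE
      }
    }
  }
  mask
}

# after directional thinning has converged, any residual 2x2 block is
# resolved by sequential (row-major) deletion of simple non-endpoint pixels
# belonging to such blocks; sequential simple-point deletion is topology-safe
collapse_blocks <- function(mask) {
  repeat {
    blk <- two_by_two_blocks(mask)
    if (!any(blk)) return(mask)
    cand <- which(blk, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    changed <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      if (!pixel_in_block(mask, r, c)) next
      if (pixel_simple_nonend(mask, r, c)) {
        mask[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) return(mask)  # no simple pixel available; leave as is
  }
}

# pixels participating in some 2x2 all-true block
two_by_two_blocks <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < 2L || w < 2L) return(mask & FALSE)
  tl <- mask[-h, -w] & mask[-h, -1L] & mask[-1L, -w] & mask[-1L, -1L]
  out <- matrix(FALSE, h, w)
  out[-h, -w] <- out[-h, -w] | tl
  out[-h, -1L] <- out[-h, -1L] | tl
  out[-1L, -w] <- out[-1L, -w] | tl
  out[-1L, -1L] <- out[-1L, -1L] | tl
  out & mask
}

pixel_in_block <- function(mask, r, c) {
  h <- nrow(mask); w <- ncol(mask)
  for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
    r0 <- r + dr; c0 <- c + dc
    if (r0 >= 1L && c0 >= 1L && r0 + 1L <= h && c0 + 1L <= w &&
        mask[r0, c0] && mask[r0 + 1L, c0] && mask[r0, c0 + 1L] &&
        mask[r0 + 1L, c0 + 1L])
      return(TRUE)
  }
  FALSE
}

#' MATLAB-style binary morphological operations
#'
#' Implements the classic `bwmorph` operations used by the pipeline, with the
#' following per-kind contracts (all on logical matrices):
#' \describe{
#'   \item{bridge}{a false pixel becomes true iff its true 8-neighbors fall in
#'     at least two 8-connected groups within the 3x3 neighborhood (center
#'     removed); true pixels never change.}
#'   \item{fill}{a false pixel becomes true iff all four 4-neighbors are true.}
#'   \item{majority}{a pixel is true iff at least 5 of the 9 pixels of its
#'     3x3 neighborhood (self included) are true.}
#'   \item{clean}{removes isolated true pixels (0 true 8-neighbors).}
#'   \item{spur}{removes endpoint pixels (<= 1 true 8-neighbor), once per
#'     iteration.}
#'   \item{thin}{homotopic thinning; one iteration is a cycle of four
#'     directional subiterations each deleting simple non-endpoint border
#'     pixels in parallel. With `n_iter = Inf` it runs to a fixed point that
#'     is unit-width (no 2x2 all-true block), idempotent, and preserves the
#'     number of 8-connected foreground and 4-connected background
#'     components.}
#' }
#'
#' @param mask Logical matrix.
#' @param kind One of `"bridge"`, `"fill"`, `"majority"`, `"clean"`,
#'   `"spur"`, `"thin"`.
#' @param n_iter Number of iterations, or `Inf` to iterate to a fixed point.
#' @return Logical matrix.
#' @export
bwmorph_op <- function(mask, kind = c("bridge", "fill", "majority", "clean",
                                      "spur", "thin"),
                       n_iter = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(mask), is.logical(mask), n_iter >= 1L)
  if (is.finite(n_iter)) {
    for (i in seq_len(n_iter)) {
      new <- bwmorph_once(mask, kind)
      if (identical(new, mask)) break
      mask <- new
    }
  } else if (kind == "thin") {
    mask <- thin_converge(mask)
  } else {
    repeat {
      new <- bwmorph_once(mask, kind)
      if (identical(new, mask)) break
      mask <- new
    }
  }
  mask
}

# Thinning to convergence is distance-ordered: simple non-endpoint pixels
# are deleted in increasing order of their distance-transform value (ties
# broken by parity waves with re-checks), so the surviving skeleton follows
# the ridge of the distance transform instead of drifting toward one side
# in corridors between junctions. The result is a fixed point of the
# per-iteration thinning as well: both delete only simple non-endpoint
# pixels, so a mask without any such pixel is stable under either.
thin_converge <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  rpar <- matrix(seq_len(h) %% 2L == 1L, h, w)
  cpar <- matrix(rep(seq_len(w) %% 2L == 1L, each = h), h, w)
  waves <- list(rpar & cpar, rpar & !cpar, !rpar & cpar, !rpar & !cpar)
  repeat {
    changed_any <- FALSE
    edt <- euclidean_distance_map(mask)
    levels <- sort(unique(edt[mask & is.finite(edt)]))
    for (lev in levels) {
      at_level <- mask & edt <= lev + 1e-9
      repeat {
        f <- simplicity_fields(mask)
        cand <- at_level & mask &
          (f$t8 == 1L) & (f$t4 == 1L) & (f$cnt >= 2L)
        if (!any(cand)) break
        g <- f
        stale <- FALSE
        changed <- FALSE
        for (wv in waves) {
          sel <- cand & wv
          if (!any(sel)) next
          if (stale) { g <- simplicity_fields(mask); stale <- FALSE }
          del <- sel & g$t8 == 1L & g$t4 == 1L & g$cnt >= 2L
          if (any(del)) {
            mask <- mask & !del
            stale <- TRUE
            changed <- TRUE
            changed_any <- TRUE
          }
        }
        if (!changed) break
      }
    }
    new <- collapse_blocks(mask)
    if (!identical(new, mask)) { mask <- new; changed_any <- TRUE }
    if (!changed_any) break
  }
  mask
}

#' Thinning with replicate padding
#'
#' Pads the mask by edge replication before thinning to a fixed point and
#' crops back, so centerlines of vessels that cross the image border extend
#' all the way to the border instead of retracting inward. The pad width is
#' adaptive: one more than the largest vessel radius present (from the
#' distance transform), which is what end-retraction scales with.
#'
#' @param mask Logical matrix.
#' @return Logical matrix (unit-width skeleton).
#' @export
thin_replicate_pad <- function(mask) {
  if (!any(mask)) return(mask)
  d <- euclidean_distance_map(mask)
  dmax <- suppressWarnings(max(d[is.finite(d)]))
  pad <- max(1L, as.integer(ceiling(ifelse(is.finite(dmax), dmax, 1))) + 1L)
  h <- nrow(mask); w <- ncol(mask)
  p <- pad_replicate(mask, pad)
  p <- bwmorph_op(p, "thin", Inf)
  p[pad + seq_len(h), pad + seq_len(w), drop = FALSE]
}

#' Euclidean distance map
#'
#' Exact Euclidean distance (in pixels, center-to-center) from each foreground
#' pixel to the nearest false pixel of the mask; 0 on false pixels. If the
#' mask has no false pixel the distance is infinite.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix.
#' @export
euclidean_distance_map <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  d <- EBImage::imageData(EBImage::distmap(
    matrix(as.numeric(mask), nrow(mask), ncol(mask)), metric = "euclidean"))
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# n passes of 3x3 dilation (used by the wire-dilation parameter)
dilate3 <- function(mask, n_iter = 1L) {
  for (i in seq_len(n_iter)) mask <- neighbor_filter(mask, "set_if", 1L)
  mask
}
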