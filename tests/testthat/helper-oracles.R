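# Brute-force oracles and small fixture builders. Every oracle here is a
# direct, slow transcription of the definition being tested, independent of
# the package's implementation path.

# mean of the k x k window with origin floor(k/2), replicate padding
bf_box_blur <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  o <- k %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
      ri <- min(max(i - o + di, 1), h)
      ci <- min(max(j - o + dj, 1), w)
      acc <- acc + img[ri, ci]
    }
    out[i, j] <- acc / (k * k)
  }
  out
}

bf_neighbor_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ri <- i + di; ci <- j + dj
      if (ri >= 1 && ri <= h && ci >= 1 && ci <= w && mask[ri, ci])
        acc <- acc + 1L
    }
    out[i, j] <- acc
  }
  out
}

# flood-fill component labelling
bf_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  offs <- if (connectivity == 8)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          r <- p[1] + o[1]; c <- p[2] + o[2]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- nxt
            queue <- c(queue, list(c(r, c)))
          }
        }
      }
    }
  }
  lab
}

bf_remove_small <- function(mask, min_area) {
  lab <- bf_label(mask, 8)
  if (max(lab) == 0) return(mask & FALSE)
  keep <- which(tabulate(lab[lab > 0]) >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

bf_fill_holes <- function(mask, max_area) {
  lab <- bf_label(!mask, 4)
  if (max(lab) == 0) return(mask)
  small <- which(tabulate(lab[lab > 0]) < max_area)
  mask | matrix(lab %in% small, nrow(mask), ncol(mask))
}

# exhaustive nearest-false scan
bf_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  fi <- which(!mask, arr.ind = TRUE)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j]) {
      out[i, j] <- if (nrow(fi) == 0) Inf else
        sqrt(min((fi[, 1] - i)^2 + (fi[, 2] - j)^2))
    }
  }
  out
}

n_components <- function(mask, connectivity = 8) {
  max(label_components(mask, connectivity))
}

# background 4-components of the mask embedded in an infinite background
# plane (pad with a one-pixel false border before complementing)
n_bg_components <- function(mask) {
  p <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  max(label_components(!p, 4L))
}

has_2x2_block <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < 2 || w < 2) return(FALSE)
  any(mask[-h, -w] & mask[-h, -1] & mask[-1, -w] & mask[-1, -1])
}

random_mask <- function(h, w, p = 0.5) matrix(runif(h * w) < p, h, w)

# full-span horizontal bar (no in-image end boundary)
full_bar <- function(h, w, center, width) {
  m <- matrix(FALSE, h, w)
  half <- (width - 1) / 2
  m[(center - half):(center + half), ] <- TRUE
  m
}

# a small phantom spec for fast tests
small_tree_spec <- function(seed, ...) {
  phantom_spec(image_shape = c(256L, 256L), n_branches = 3L,
               diameter_range_px = c(7, 11), seed = seed, ...)
}
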