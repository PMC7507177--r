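test_that("box_blur matches hand convolution and brute force", {
  # constants are fixed points for any k
  cst <- matrix(0.37, 9, 9)
  expect_equal(box_blur(cst, 4), cst)
  expect_equal(box_blur(cst, 1), cst)

  # single bright pixel, k = 3: a 3x3 block of 1/9
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  out <- box_blur(img, 3)
  expected <- matrix(0, 5, 5); expected[2:4, 2:4] <- 1 / 9
  expect_equal(out, expected)

  # random images against the brute-force definition, odd and even k
  set.seed(11)
  for (k in c(2, 3, 4, 5)) {
    img <- matrix(runif(10 * 12), 10, 12)
    expect_equal(box_blur(img, k), bf_box_blur(img, k), tolerance = 1e-12)
  }
  expect_error(box_blur(matrix(0, 4, 4), 5), "exceeds")
})

test_that("neighbor_filter obeys the keep_if/set_if contracts", {
  # isolated pixel has 0 neighbors
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_false(any(neighbor_filter(m, "keep_if", 4)))

  # 3x3 block: corners have 3 neighbors, edge-centers 5, center 8
  blk <- matrix(FALSE, 5, 5); blk[2:4, 2:4] <- TRUE
  out <- neighbor_filter(blk, "keep_if", 4)
  plus <- matrix(FALSE, 5, 5)
  plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  expect_identical(out, plus)

  # false pixel with all 8 neighbors true is set
  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  expect_true(neighbor_filter(ring, "set_if", 4)[3, 3])

  # keep_if anti-extensive, set_if extensive; counts match brute force
  set.seed(12)
  for (i in 1:30) {
    m <- random_mask(9, 9, runif(1, 0.2, 0.8))
    expect_identical(reaver:::neighbor_count(m), bf_neighbor_count(m))
    for (mn in c(1, 4, 7)) {
      kept <- neighbor_filter(m, "keep_if", mn)
      grown <- neighbor_filter(m, "set_if", mn)
      expect_true(all(kept <= m))
      expect_true(all(grown >= m))
      expect_identical(kept, m & (bf_neighbor_count(m) >= mn))
      expect_identical(grown, m | (bf_neighbor_count(m) >= mn))
    }
  }
})

test_that("component labelling matches flood fill for both connectivities", {
  # diagonal pair: one 8-connected component, two 4-connected
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(n_components(m, 8), 1L)
  expect_equal(n_components(m, 4), 2L)

  set.seed(13)
  for (i in 1:40) {
    m <- random_mask(12, 12, runif(1, 0.2, 0.8))
    for (conn in c(4L, 8L)) {
      lab <- label_components(m, conn)
      ref <- bf_label(m, conn)
      expect_equal(max(lab), max(ref))
      # same partition: labels are a relabelling of the reference
      if (max(ref) > 0) {
        expect_equal(length(unique(paste(lab[m], ref[m]))), max(ref))
      }
    }
  }
})

test_that("remove_small_components treats 'less than' strictly", {
  # component of exactly min_area survives
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE  # area 4
  expect_identical(remove_small_components(m, 4), m)
  expect_false(any(remove_small_components(m, 5)))

  # diagonal pair is one 8-connected component of area 2
  dp <- matrix(FALSE, 4, 4); dp[1, 1] <- TRUE; dp[2, 2] <- TRUE
  expect_identical(remove_small_components(dp, 2), dp)

  set.seed(14)
  for (i in 1:25) {
    m <- random_mask(12, 12, 0.45)
    a <- sample(1:6, 1)
    got <- remove_small_components(m, a)
    expect_identical(got, bf_remove_small(m, a))
    expect_identical(remove_small_components(got, a), got)  # idempotent
    expect_true(all(got <= m))
  }
})

test_that("fill_small_holes fills strictly-smaller 4-connected holes", {
  # single-pixel hole
  m <- matrix(TRUE, 5, 5); m[3, 3] <- FALSE
  expect_true(all(fill_small_holes(m, 2)))
  # hole of exactly max_area is not filled
  m2 <- matrix(TRUE, 6, 6); m2[3, 3:4] <- FALSE  # hole area 2
  expect_identical(fill_small_holes(m2, 2), m2)
  expect_true(all(fill_small_holes(m2, 3)))
  # one large border-touching complement region stays
  m3 <- matrix(FALSE, 8, 8); m3[4:5, 4:5] <- TRUE
  expect_identical(fill_small_holes(m3, 10), m3)

  set.seed(15)
  for (i in 1:25) {
    m <- random_mask(12, 12, 0.6)
    a <- sample(1:8, 1)
    got <- fill_small_holes(m, a)
    expect_identical(got, bf_fill_holes(m, a))
    expect_identical(fill_small_holes(got, a), got)
    expect_true(all(got >= m))
  }
})

test_that("local_majority_smooth keeps straight boundaries in place", {
  expect_true(all(local_majority_smooth(matrix(TRUE, 15, 15), 11)))
  expect_false(any(local_majority_smooth(matrix(FALSE, 15, 15), 11)))

  # left band: output stays a single left-anchored band, boundary moves
  # at most floor(k/2)
  m <- matrix(FALSE, 21, 21); m[, 1:10] <- TRUE
  out <- local_majority_smooth(m, 11, 0.5)
  expect_true(all(apply(out, 1, function(r) {
    b <- which(!r)[1]
    all(r[seq_len(b - 1)]) && !any(r[b:21])
  })))
  widths <- rowSums(out)
  expect_true(all(abs(widths - 10) <= 5))

  # definition check against box_blur of the complement
  set.seed(16)
  mm <- random_mask(13, 13, 0.5)
  expect_identical(local_majority_smooth(mm, 5, 0.5),
                   !(box_blur(matrix(as.numeric(!mm), 13, 13), 5) > 0.5))
})

test_that("euclidean_distance_map is exact against nearest-false search", {
  expect_equal(euclidean_distance_map(matrix(FALSE, 4, 4)),
               matrix(0, 4, 4))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(euclidean_distance_map(single)[3, 3], 1.0)

  # full-span bar of height 9: center row is 5 px from the nearest false
  bar <- full_bar(30, 40, 15, 9)
  expect_equal(unique(euclidean_distance_map(bar)[15, ]), 5.0)

  set.seed(17)
  for (i in 1:100) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    m <- random_mask(h, w, runif(1, 0.2, 0.9))
    expect_equal(euclidean_distance_map(m), bf_edt(m), tolerance = 1e-12)
  }
})

test_that("bridge, fill, majority, clean and spur follow their contracts", {
  # fill: ring with false center
  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  expect_true(bwmorph_op(ring, "fill")[3, 3])

  # bridge: two vertical runs separated by a 1-px gap get connected
  g <- matrix(FALSE, 5, 5)
  g[2:4, 2] <- TRUE; g[2:4, 4] <- TRUE
  br <- bwmorph_op(g, "bridge")
  expect_true(all(br[2:4, 3]))
  expect_true(all(br >= g))
  # but a false pixel whose true neighbors are all mutually connected stays
  l <- matrix(FALSE, 4, 4); l[2, 2] <- TRUE; l[2, 3] <- TRUE
  expect_identical(bwmorph_op(l, "bridge"), l)

  # clean removes isolated pixels only
  cl <- matrix(FALSE, 5, 7)
  cl[3, 2] <- TRUE               # isolated
  cl[2, 5] <- TRUE; cl[2, 6] <- TRUE  # pair
  out <- bwmorph_op(cl, "clean")
  expect_false(out[3, 2])
  expect_true(all(out[2, 5:6]))

  # spur removes endpoints once per iteration
  ln <- matrix(FALSE, 5, 9); ln[3, 2:8] <- TRUE
  sp1 <- bwmorph_op(ln, "spur", 1)
  expect_equal(sum(sp1), 5)
  sp2 <- bwmorph_op(ln, "spur", 2)
  expect_equal(sum(sp2), 3)

  # majority needs >= 5 of 9
  blk <- matrix(FALSE, 6, 6); blk[2:4, 2:4] <- TRUE
  mj <- bwmorph_op(blk, "majority")
  expect_true(mj[3, 3])
  expect_false(any(mj[1, ]))

  # extensivity/anti-extensivity across random masks
  set.seed(18)
  for (i in 1:20) {
    m <- random_mask(10, 10, 0.5)
    expect_true(all(bwmorph_op(m, "bridge") >= m))
    expect_true(all(bwmorph_op(m, "fill") >= m))
    expect_true(all(bwmorph_op(m, "clean") <= m))
    expect_true(all(bwmorph_op(m, "spur") <= m))
    expect_true(all(bwmorph_op(m, "thin") <= m))
    # n_iter = Inf reaches a fixed point for every kind
    for (kind in c("bridge", "fill", "majority", "clean", "spur")) {
      fp <- bwmorph_op(m, kind, Inf)
      expect_identical(bwmorph_op(fp, kind, 1), fp)
    }
  }
})
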