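test_that("presmoothing is benign on solid shapes and fills small holes", {
  expect_false(any(presmooth_for_skeleton(matrix(FALSE, 10, 10))))

  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  out <- presmooth_for_skeleton(sq)
  # contains the square's core (the majority filter may shave corner
  # pixels), grows by at most one pixel per side, and leaves no holes
  core <- matrix(FALSE, 30, 30); core[7:24, 7:24] <- TRUE
  expect_true(all(out >= core))
  grown <- matrix(FALSE, 30, 30); grown[5:26, 5:26] <- TRUE
  expect_true(all(out <= grown))
  expect_gte(sum(out), sum(sq) - 4)  # at most the four corners removed
  expect_equal(n_bg_components(out), 1L)

  holed <- sq; holed[14:15, 14:16] <- FALSE  # 6-px hole < 80
  expect_true(all(presmooth_for_skeleton(holed)[14:15, 14:16]))
})

test_that("initial_centerline reduces solid shapes to unit-width skeletons", {
  expect_false(any(initial_centerline(matrix(FALSE, 20, 20))))

  xy <- expand.grid(r = 1:41, c = 1:41)
  disk <- matrix((xy$r - 21)^2 + (xy$c - 21)^2 <= 100, 41, 41)
  dc <- initial_centerline(disk)
  expect_equal(n_components(dc, 8), 1L)
  expect_lte(sum(dc), 9)  # topological point: one tiny cluster

  bar <- full_bar(40, 80, 20, 9)
  bc <- initial_centerline(bar)
  expect_false(has_2x2_block(bc))
  expect_equal(n_components(bc, 8), 1L)
  # touches both vertical image borders (replicate padding at work)
  expect_gt(sum(bc[, 1]), 0)
  expect_gt(sum(bc[, 80]), 0)
})

test_that("sample_radii reads the distance transform at centerline pixels", {
  bar9 <- full_bar(40, 60, 20, 9)
  cl <- matrix(FALSE, 40, 60); cl[20, ] <- TRUE
  rm9 <- sample_radii(bar9, cl)
  expect_equal(unique(rm9$radius_px), 5.0)
  expect_equal(nrow(rm9), 60)

  bar5 <- full_bar(40, 60, 20, 5)
  rm5 <- sample_radii(bar5, cl)
  expect_equal(unique(rm5$radius_px), 3.0)

  expect_equal(nrow(sample_radii(bar9, matrix(FALSE, 40, 60))), 0L)

  # centerline pixel off the mask: warning and radius 0
  off <- matrix(FALSE, 40, 60); off[5, 5] <- TRUE
  expect_warning(rmo <- sample_radii(bar9, off), "outside")
  expect_equal(rmo$radius_px, 0)
})

test_that("splitting cuts at branchpoints into the expected segment counts", {
  # straight line: one segment
  ln <- matrix(FALSE, 20, 30); ln[10, 3:28] <- TRUE
  rmap <- sample_radii(reaver:::dilate3(ln, 2), ln)
  expect_length(split_into_segments(ln, rmap), 1L)

  # Y: three 20-px arms from a center
  y <- matrix(FALSE, 50, 50)
  y[25:45, 25] <- TRUE                      # south arm
  for (k in 1:20) { y[25 - k, 25 - k] <- TRUE; y[25 - k, 25 + k] <- TRUE }
  rmap <- sample_radii(reaver:::dilate3(y, 2), y)
  expect_length(split_into_segments(y, rmap), 3L)

  # +: four arms
  cr <- matrix(FALSE, 41, 41)
  cr[21, 2:40] <- TRUE; cr[2:40, 21] <- TRUE
  rmap <- sample_radii(reaver:::dilate3(cr, 2), cr)
  expect_length(split_into_segments(cr, rmap), 4L)
})

test_that("branchpoint and endpoint detection respects the border rule", {
  ln <- matrix(FALSE, 20, 30); ln[10, 3:28] <- TRUE
  expect_equal(nrow(find_branchpoints(ln)), 0L)
  ep <- find_endpoints(ln)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep[, "col"], c(3L, 28L))

  # line reaching the border: that terminus is not reported
  lb <- matrix(FALSE, 20, 30); lb[10, 1:15] <- TRUE
  expect_equal(nrow(find_endpoints(lb)), 1L)

  # closed loop: no endpoints
  loop <- matrix(FALSE, 12, 12)
  loop[4, 4:8] <- TRUE; loop[8, 4:8] <- TRUE
  loop[4:8, 4] <- TRUE; loop[4:8, 8] <- TRUE
  expect_equal(nrow(find_endpoints(loop)), 0L)

  # Y junction: one branchpoint (the cluster), three endpoints
  y <- matrix(FALSE, 50, 50)
  y[25:45, 25] <- TRUE
  for (k in 1:20) { y[25 - k, 25 - k] <- TRUE; y[25 - k, 25 + k] <- TRUE }
  expect_equal(nrow(find_branchpoints(y)), 1L)
  expect_equal(find_branchpoints(y)[1, ], c(row = 25L, col = 25L))

  # a junction on the outermost row: its border branch pixels are never
  # reported (under 8-connectivity the arm also creates an interior branch
  # pixel one row in, which legitimately is)
  yb <- matrix(FALSE, 50, 50)
  yb[1, 10:40] <- TRUE; yb[1:20, 25] <- TRUE
  bpb <- find_branchpoints(yb)
  expect_true(all(bpb[, "row"] > 1))
})

test_that("thin segments are pruned and thick networks survive intact", {
  # unit-width centerline: thick tube spine with a thin filament hanging off
  h <- 60; w <- 120
  spine <- matrix(FALSE, h, w); spine[30, 10:110] <- TRUE
  fil <- matrix(FALSE, h, w); fil[31:50, 60] <- TRUE
  cl <- spine | fil
  rmap <- data.frame(row = c(rep(30L, 101), 31:50),
                     col = c(10:110, rep(60L, 20)),
                     radius_px = c(rep(5, 101), rep(1, 20)))

  pruned <- prune_thin_segments(cl, rmap, 3)
  expect_false(any(pruned[35:50, 60]))        # filament gone
  expect_gt(sum(pruned[30, ]), 90)            # spine intact

  kept <- prune_thin_segments(cl, rmap, 0)
  expect_gt(sum(kept[31:50, 60]), 15)         # threshold 0 prunes nothing

  # all segments above threshold: output equals spur/clean/thin of input
  same <- prune_thin_segments(spine, rmap[1:101, ], 3)
  ref <- bwmorph_op(bwmorph_op(bwmorph_op(spine, "spur", 1),
                               "clean", 1), "thin", Inf)
  expect_identical(same, ref)
})

test_that("extract_centerline satisfies its structural invariants", {
  ph <- generate_phantom(small_tree_spec(seed = 31))
  seg <- segment_vessels(ph$image)
  cl <- extract_centerline(seg)

  expect_false(has_2x2_block(cl$centerline))
  # idempotent under a further thinning
  expect_identical(bwmorph_op(cl$centerline, "thin", Inf), cl$centerline)
  # radius map covers exactly the centerline pixels, radii positive
  expect_equal(nrow(cl$radius_map), sum(cl$centerline))
  expect_true(all(cl$radius_map$radius_px > 0))
  # reported points lie on the centerline, off the border
  for (pts in list(cl$branchpoints, cl$endpoints)) {
    if (nrow(pts) > 0) {
      expect_true(all(cl$centerline[pts]))
      expect_true(all(pts[, 1] > 1 & pts[, 1] < nrow(cl$centerline)))
      expect_true(all(pts[, 2] > 1 & pts[, 2] < ncol(cl$centerline)))
    }
  }
  expect_equal(nrow(cl$branchpoints), ph$network$junction_count)

  # empty input
  e <- extract_centerline(matrix(FALSE, 140, 140))
  expect_false(any(e$centerline))
  expect_equal(nrow(e$branchpoints), 0L)
})
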