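test_that("confusion counts match an exhaustive per-pixel tally", {
  a <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(unclass(confusion_counts(a, a))[c("fp", "fn")],
               list(fp = 0L, fn = 0L))

  pred <- matrix(TRUE, 4, 4)
  truth <- matrix(FALSE, 4, 4); truth[, 1:2] <- TRUE
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$tp, 8); expect_equal(cc$fp, 8)
  expect_equal(cc$tn, 0); expect_equal(cc$fn, 0)

  set.seed(51)
  for (i in 1:20) {
    p <- random_mask(8, 8); g <- random_mask(8, 8)
    cc <- confusion_counts(p, g)
    tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (r in 1:8) for (c in 1:8) {
      key <- if (p[r, c] && g[r, c]) "tp" else if (!p[r, c] && !g[r, c]) "tn"
        else if (p[r, c]) "fp" else "fn"
      tally[key] <- tally[key] + 1
    }
    expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]), tally)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 64)
    # swapping prediction and truth swaps fp and fn
    sw <- confusion_counts(g, p)
    expect_equal(sw$fp, cc$fn); expect_equal(sw$fn, cc$fp)
    expect_equal(sw$tp, cc$tp); expect_equal(sw$tn, cc$tn)
  }
  expect_error(confusion_counts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shapes")
})

test_that("segmentation scores implement the standard formulas", {
  perfect <- confusion_counts(matrix(TRUE, 3, 3), matrix(TRUE, 3, 3))
  sc <- segmentation_scores(perfect)
  expect_equal(sc[["accuracy"]], 1.0)
  expect_equal(sc[["sensitivity"]], 1.0)
  expect_true(is.na(sc[["specificity"]]))  # no negatives exist

  pred <- matrix(FALSE, 4, 4)
  truth <- matrix(FALSE, 4, 4); truth[1:2, ] <- TRUE
  sc2 <- segmentation_scores(confusion_counts(pred, truth))
  expect_equal(sc2[["accuracy"]], 0.5)
  expect_equal(sc2[["sensitivity"]], 0.0)
  expect_equal(sc2[["specificity"]], 1.0)

  cc <- structure(list(tp = 6L, tn = 2L, fp = 1L, fn = 1L),
                  class = "confusion_counts")
  sc3 <- segmentation_scores(cc)
  expect_equal(sc3[["accuracy"]], 0.8)
  expect_equal(sc3[["sensitivity"]], 6 / 7)
  expect_equal(sc3[["precision_ppv"]], 6 / 7)
  expect_equal(sc3[["specificity"]], 2 / 3)

  # complementing both masks swaps sensitivity and specificity
  set.seed(52)
  p <- random_mask(10, 10); g <- random_mask(10, 10)
  s1 <- segmentation_scores(confusion_counts(p, g))
  s2 <- segmentation_scores(confusion_counts(!p, !g))
  expect_equal(s1[["accuracy"]], s2[["accuracy"]])
  expect_equal(s1[["sensitivity"]], s2[["specificity"]])
  expect_equal(s1[["specificity"]], s2[["sensitivity"]])
})

test_that("error tables carry signed and absolute errors per metric", {
  mk <- function(id, len, af, d, bp) {
    data.frame(image_id = id, vessel_length_density_mm_per_mm2 = len,
               vessel_area_fraction = af, mean_vessel_diameter_um = d,
               branchpoint_count = bp, stringsAsFactors = FALSE)
  }
  measured <- rbind(mk("i1", 5, 0.2, 10, 4), mk("i2", 3, 0.1, 8, 7))
  truth <- rbind(mk("i1", 3, 0.25, 10, 4), mk("i2", 5, 0.1, 9, 2))

  et <- error_table(measured, truth)
  expect_equal(nrow(et), 8L)
  expect_equal(et$absolute_error, abs(et$error))
  expect_equal(et$error, et$measured - et$truth)
  len <- et[et$metric_name == "vessel_length_density_mm_per_mm2", ]
  expect_equal(len$error, c(2, -2))
  expect_equal(len$absolute_error, c(2, 2))

  same <- error_table(measured, measured)
  expect_true(all(same$absolute_error == 0))

  bad <- truth; bad$image_id <- c("i1", "iX")
  expect_error(error_table(measured, bad), "mismatch")

  set.seed(53)
  y <- runif(6); g <- runif(6)
  m2 <- mk(paste0("p", 1:6), y, 0.1, 1, 1)
  t2 <- mk(paste0("p", 1:6), g, 0.1, 1, 1)
  e2 <- error_table(m2, t2)
  expect_equal(e2$absolute_error[e2$metric_name ==
                                   "vessel_length_density_mm_per_mm2"],
               abs(y - g))
})

test_that("precision residuals are deviations from the median error", {
  expect_equal(precision_residuals(c(1, 2, 3)), c(1, 0, 1))
  expect_equal(precision_residuals(rep(4, 5)), rep(0, 5))
  # even n uses the midpoint of the central order statistics
  expect_equal(precision_residuals(c(0, 1, 2, 10)), c(1.5, 0.5, 0.5, 8.5))
  expect_error(precision_residuals(numeric(0)), "empty")
  # translation invariance
  set.seed(54)
  e <- rnorm(11)
  expect_equal(precision_residuals(e + 3.7), precision_residuals(e))
})
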