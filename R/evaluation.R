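#' Pixel confusion counts between a predicted and a ground-truth mask
#'
#' @param pred,truth Logical matrices of identical shape; `truth` is the
#'   reference classification.
#' @return An object of class `confusion_counts`: list with integer fields
#'   `tp`, `tn`, `fp`, `fn` summing to the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(is.matrix(pred), is.logical(pred),
            is.matrix(truth), is.logical(truth))
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), call. = FALSE)
  structure(list(tp = sum(pred & truth),
                 tn = sum(!pred & !truth),
                 fp = sum(pred & !truth),
                 fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Segmentation agreement scores
#'
#' Computes accuracy (TP+TN)/total, sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), and precision (positive predictive value) TP/(TP+FP). Scores
#' with a zero denominator are reported as `NA`.
#'
#' @param c A `confusion_counts` object.
#' @return Named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `precision_ppv`.
#' @export
segmentation_scores <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) stop("empty confusion counts", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (c$tp + c$tn) / total,
    sensitivity = safe_div(c$tp, c$tp + c$fn),
    specificity = safe_div(c$tn, c$tn + c$fp),
    precision_ppv = safe_div(c$tp, c$tp + c$fp))
}

#' Per-image, per-metric error against ground truth
#'
#' For matched measured and ground-truth metric tables, computes the signed
#' error E = Y - G and absolute error A = |E| for each of the four vessel
#' structure metrics.
#'
#' @param measured,truth Data frames as produced by [vessel_metrics_row()]
#'   (one row per image), with matching `image_id` in the same order.
#' @return A data frame with columns `image_id`, `metric_name`, `measured`,
#'   `truth`, `error`, `absolute_error`.
#' @export
error_table <- function(measured, truth) {
  stopifnot(is.data.frame(measured), is.data.frame(truth))
  if (nrow(measured) != nrow(truth))
    stop("measured and truth tables differ in length", call. = FALSE)
  if (!identical(as.character(measured$image_id),
                 as.character(truth$image_id)))
    stop("image_id mismatch between measured and truth tables",
         call. = FALSE)
  metrics <- c("vessel_length_density_mm_per_mm2", "vessel_area_fraction",
               "mean_vessel_diameter_um", "branchpoint_count")
  out <- do.call(rbind, lapply(metrics, function(mn) {
    e <- measured[[mn]] - truth[[mn]]
    data.frame(image_id = measured$image_id,
               metric_name = mn,
               measured = measured[[mn]],
               truth = truth[[mn]],
               error = e,
               absolute_error = abs(e),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Precision residuals (Brown-Forsythe transform)
#'
#' Absolute deviation of each signed error from the median error across
#' images; the per-image precision statistic. The median uses the midpoint of
#' the two central order statistics for even n.
#'
#' @param errors Numeric vector of signed errors (length >= 1).
#' @return Numeric vector of the same length.
#' @export
precision_residuals <- function(errors) {
  if (length(errors) < 1L) stop("empty error vector", call. = FALSE)
  abs(errors - stats::median(errors))
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience wrapper: confusion counts plus scores as a one-row data frame.
#'
#' @inheritParams confusion_counts
#' @param image_id Identifier for the row.
#' @return One-row data frame with the counts and the four scores.
#' @export
evaluate_masks <- function(pred, truth, image_id = "image") {
  cc <- confusion_counts(pred, truth)
  sc <- segmentation_scores(cc)
  data.frame(image_id = image_id, tp = cc$tp, tn = cc$tn, fp = cc$fp,
             fn = cc$fn, accuracy = sc[["accuracy"]],
             sensitivity = sc[["sensitivity"]],
             specificity = sc[["specificity"]],
             precision_ppv = sc[["precision_ppv"]],
             stringsAsFactors = FALSE)
}
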