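#' Evaluate one-box-per-image detections
#'
#' Scores detections against ground truth under the one-output-box
#' protocol: a predicted box is a true positive when its Jaccard index with
#' the truth is strictly greater than `tp_bound` (0.5), otherwise a false
#' positive (a prediction on a truth-free image is always a false
#' positive); a truth-bearing image left without a true positive counts
#' one false negative; the true-negative count is fixed at zero.  Reported
#' metrics follow `accuracy = TP / (TP + FP + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and the harmonic
#' F1; any ratio with a zero denominator is reported as 0 and flagged in
#' `undefined`.  Mean and SD of IoU are taken over images holding both a
#' truth and a prediction.
#'
#' @param preds Tibble with `image_id` and box columns; at most one row
#'   per image, omit an image to predict "no lesion".
#' @param truths Tibble with `image_id` and box columns for truth-bearing
#'   images; omit normal images.  Every predicted `image_id` must appear in
#'   the evaluated image set, i.e. `image_ids`.
#' @param image_ids Character vector of all evaluated images; defaults to
#'   the union of the ids in `preds` and `truths`.
#' @param tp_bound True-positive Jaccard bound (default 0.5).
#' @return An object of class `"us_eval"`: a list with `counts` (TP, FP,
#'   FN, TN), `metrics`, `undefined` (names of zero-denominator ratios) and
#'   `per_image` (id, IoU, outcome).
#' @export
evaluate_detections <- function(preds, truths,
                                image_ids = union(preds$image_id,
                                                  truths$image_id),
                                tp_bound = 0.5) {
  preds <- as_tibble(preds); truths <- as_tibble(truths)
  if (anyDuplicated(preds$image_id)) {
    abort("one predicted box per image: duplicated image_id in preds")
  }
  if (anyDuplicated(truths$image_id)) {
    abort("one truth box per image: duplicated image_id in truths")
  }
  stray <- setdiff(c(preds$image_id, truths$image_id), image_ids)
  if (length(stray) > 0) {
    abort(paste0("image_id not in the evaluated set: ",
                 paste(stray, collapse = ", ")))
  }
  rows <- lapply(image_ids, function(id) {
    p <- preds[preds$image_id == id, ]
    t <- truths[truths$image_id == id, ]
    iou <- if (nrow(p) == 1 && nrow(t) == 1) box_jaccard(p, t) else NA_real_
    outcome <- if (nrow(p) == 1 && nrow(t) == 1) {
      if (iou > tp_bound) "TP" else "FP+FN"
    } else if (nrow(p) == 1) {
      "FP"                                  # prediction on a normal image
    } else if (nrow(t) == 1) {
      "FN"                                  # missed lesion
    } else {
      "none"                                # normal image, no box: TN = 0
    }
    tibble(image_id = id, iou = iou, outcome = outcome)
  })
  per_image <- dplyr::bind_rows(rows)
  tp <- sum(per_image$outcome == "TP")
  fp <- sum(per_image$outcome %in% c("FP", "FP+FN"))
  fn <- sum(per_image$outcome %in% c("FN", "FP+FN"))
  safe_div <- function(num, den) if (den > 0) num / den else 0
  undefined <- character(0)
  if (tp + fp + fn == 0) undefined <- c(undefined, "accuracy")
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  if (tp + fn == 0) undefined <- c(undefined, "recall")
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  if (precision + recall == 0) undefined <- c(undefined, "f1")
  f1 <- safe_div(2 * recall * precision, recall + precision)
  ious <- per_image$iou[!is.na(per_image$iou)]
  structure(list(
    counts = c(TP = tp, FP = fp, FN = fn, TN = 0L),
    metrics = c(
      accuracy = safe_div(tp, tp + fp + fn),
      precision = precision, recall = recall, f1 = f1,
      mean_iou = if (length(ious) > 0) mean(ious) else NA_real_,
      std_iou = if (length(ious) > 1) sd(ious) else NA_real_
    ),
    undefined = undefined,
    per_image = per_image
  ), class = "us_eval")
}

#' @export
print.us_eval <- function(x, ...) {
  cat("<us_eval> ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = " "), "\n")
  m <- x$metrics
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              m["accuracy"], m["precision"], m["recall"], m["f1"]))
  if (!is.na(m["mean_iou"])) {
    cat(sprintf("  IoU %.3f +/- %.3f over %d matched images\n",
                m["mean_iou"], m["std_iou"], sum(!is.na(x$per_image$iou))))
  }
  if (length(x$undefined) > 0) {
    cat("  undefined (reported 0):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidiers for evaluation objects
#'
#' `tidy()` returns the per-image table (id, IoU, outcome); `glance()`
#' returns a one-row summary with counts and all metrics.
#'
#' @param x An `"us_eval"` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.us_eval <- function(x, ...) x$per_image

#' @rdname tidy.us_eval
#' @export
glance.us_eval <- function(x, ...) {
  tibble(
    TP = x$counts[["TP"]], FP = x$counts[["FP"]], FN = x$counts[["FN"]],
    TN = x$counts[["TN"]],
    accuracy = x$metrics[["accuracy"]], precision = x$metrics[["precision"]],
    recall = x$metrics[["recall"]], f1 = x$metrics[["f1"]],
    mean_iou = x$metrics[["mean_iou"]], std_iou = x$metrics[["std_iou"]],
    n_undefined = length(x$undefined)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
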