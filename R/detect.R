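#' Detect a lesion in one image
#'
#' Runs the full chain on one grayscale image: preprocessing (equalize,
#' normalize, denoise, clip), unsupervised region proposal on the clipped
#' frame, classifier scoring with the 0.9 confidence gate, iterative
#' bounding-box regression of every gated candidate, and aggregation into
#' a single detection.  The clip only discards bottom rows, so proposal
#' coordinates are already in original-image coordinates; scoring and
#' regression read the original (unclipped) image.  If no candidate
#' survives the gate the image is reported lesion-free — no box.
#'
#' @param img Grayscale intensity matrix.
#' @param classifier An `"roi_classifier"`.
#' @param regressor A `"box_regressor"`.
#' @param cfg A [pipeline_config()].
#' @return An object of class `"us_detection"`: list with `final` (one-row
#'   box tibble, 0 rows if nothing detected), `n_proposals`, `n_gated`,
#'   `trajectories` (list of regression trajectories for gated boxes),
#'   `image` and `config`.
#' @export
detect <- function(img, classifier, regressor, cfg = pipeline_config()) {
  if (!inherits(classifier, "roi_classifier")) abort("classifier missing")
  if (!inherits(regressor, "box_regressor")) abort("regressor missing")
  pp <- preprocess(img, cfg)
  props <- propose_rois(pp$image, cfg)
  scores <- score_rois(img, props, classifier)
  gated <- filter_rois(scores, cfg$classifier_gate)
  trajectories <- list()
  final <- gated[0, c("x", "y", "w", "h", "confidence")]
  if (nrow(gated) > 0) {
    regressed <- vector("list", nrow(gated))
    for (i in seq_len(nrow(gated))) {
      traj <- iterate_regression(gated[i, ], img, regressor,
                                 cfg$total_steps)
      trajectories[[i]] <- traj
      last <- traj[[length(traj)]]
      last$confidence <- gated$confidence[i]
      regressed[[i]] <- last
    }
    final <- aggregate_boxes(dplyr::bind_rows(regressed), dim(img), cfg)
  }
  structure(list(final = final, n_proposals = nrow(props),
                 n_gated = nrow(gated), trajectories = trajectories,
                 image = img, config = cfg),
            class = "us_detection")
}

#' @export
print.us_detection <- function(x, ...) {
  cat(sprintf("<us_detection> %d proposals -> %d gated -> %s\n",
              x$n_proposals, x$n_gated,
              if (nrow(x$final) > 0) sprintf(
                "box (%.1f, %.1f, %.1f, %.1f), confidence %.3f",
                x$final$x, x$final$y, x$final$w, x$final$h,
                x$final$confidence)
              else "no lesion box"))
  invisible(x)
}

#' Run a full train/detect/evaluate experiment on a phantom dataset
#'
#' Splits the dataset, trains the desk-scale classifier and regressor on
#' the training split (lesion phantoms only), runs [detect()] on every
#' held-out phantom, and evaluates the final boxes with
#' [evaluate_detections()].  All randomness flows from `cfg$rng_seed`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param cfg A [pipeline_config()].
#' @param train_fraction Fraction of samples used for training
#'   (default 0.8).
#' @param classifier,regressor Optional pre-trained models; trained here
#'   when `NULL`.
#' @return A list of class `"us_experiment"`: `report` (an `"us_eval"`),
#'   `log` (per-image tibble with stage counts and IoU), `classifier`,
#'   `regressor`, `test_ids`.
#' @export
run_experiment <- function(dataset, cfg = pipeline_config(),
                           train_fraction = 0.8,
                           classifier = NULL, regressor = NULL) {
  n <- length(dataset$samples)
  if (n == 0) abort("empty dataset")
  set.seed(cfg$rng_seed)
  n_train <- max(1, floor(train_fraction * n))
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0) abort("no held-out samples; lower train_fraction")
  train_samples <- dataset$samples[train_idx]
  if (is.null(classifier)) classifier <- train_classifier(train_samples, cfg)
  if (is.null(regressor)) regressor <- train_regressor(train_samples, cfg)

  ids <- dataset$manifest$image_id
  preds <- list(); truths <- list(); logs <- list()
  for (i in test_idx) {
    sm <- dataset$samples[[i]]
    det <- detect(sm$image, classifier, regressor, cfg)
    iou <- NA_real_
    if (nrow(det$final) > 0 && nrow(sm$truth_box) > 0) {
      iou <- box_jaccard(det$final, sm$truth_box)
    }
    logs[[length(logs) + 1]] <- tibble(
      image_id = ids[i], n_proposals = det$n_proposals,
      n_gated = det$n_gated, detected = nrow(det$final) > 0, iou = iou)
    if (nrow(det$final) > 0) {
      p <- det$final; p$image_id <- ids[i]
      preds[[length(preds) + 1]] <- p
    }
    if (nrow(sm$truth_box) > 0) {
      t <- sm$truth_box; t$image_id <- ids[i]
      truths[[length(truths) + 1]] <- t
    }
  }
  empty_det <- tibble(image_id = character(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), confidence = numeric())
  preds <- if (length(preds) > 0) dplyr::bind_rows(preds) else empty_det
  truths <- if (length(truths) > 0) dplyr::bind_rows(truths) else empty_det
  report <- evaluate_detections(preds, truths, image_ids = ids[test_idx],
                                tp_bound = cfg$tp_jaccard)
  structure(list(report = report, log = dplyr::bind_rows(logs),
                 classifier = classifier, regressor = regressor,
                 test_ids = ids[test_idx]),
            class = "us_experiment")
}

#' @export
print.us_experiment <- function(x, ...) {
  cat("<us_experiment>", length(x$test_ids), "held-out images\n")
  print(x$report)
  invisible(x)
}
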