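## A classifier is a list of class "roi_classifier" with a $score
## function(img, boxes) returning probabilities in [0, 1], one per box.

new_roi_classifier <- function(score, kind) {
  structure(list(score = score, kind = kind), class = "roi_classifier")
}

#' @export
print.roi_classifier <- function(x, ...) {
  cat("<roi_classifier:", x$kind, ">\n"); invisible(x)
}

## deterministic pseudo-noise in (-0.5, 0.5) from box geometry + seed
## (shader-style hash; no RNG state touched, so scoring is reproducible)
box_hash_noise <- function(boxes, seed) {
  v <- sin(boxes$x * 12.9898 + boxes$y * 78.233 +
             boxes$w * 37.719 + boxes$h * 9.151 + seed * 0.618) * 43758.5453
  v - floor(v) - 0.5
}

#' Stub and oracle RoI classifiers
#'
#' `classifier_constant(p)` scores every box `p` — the degenerate baseline.
#' `classifier_oracle(truth)` scores boxes from their Jaccard overlap with
#' a known truth box, mapped through a steep logistic
#' (`plogis(25 * (J - 0.25))`) so boxes on the lesion score near 1,
#' disjoint boxes near 0, plus a small deterministic perturbation of
#' amplitude `noise`; with `truth = NULL` (a normal image) every score is
#' near 0.  The oracle stands in for a trained network in pipeline tests.
#'
#' @param p Constant probability in `[0, 1]`.
#' @param truth One-row box tibble, or `NULL` for a lesion-free image.
#' @param noise Perturbation amplitude (default 0.02).
#' @param seed Integer folded into the deterministic perturbation.
#' @return An `"roi_classifier"`.
#' @export
classifier_constant <- function(p = 0.5) {
  if (p < 0 || p > 1) abort("constant probability must lie in [0, 1]")
  new_roi_classifier(function(img, boxes) rep(p, nrow(boxes)), "constant")
}

#' @rdname classifier_constant
#' @export
classifier_oracle <- function(truth, noise = 0.02, seed = 0L) {
  new_roi_classifier(function(img, boxes) {
    base <- if (is.null(truth) || nrow(truth) == 0) {
      rep(0.02, nrow(boxes))
    } else {
      stats::plogis(25 * (box_jaccard(boxes, truth) - 0.25))
    }
    pmin(pmax(base + noise * box_hash_noise(boxes, seed), 0), 1)
  }, "oracle")
}

#' Score RoI candidates
#'
#' Applies a classifier to each candidate box, preserving order.  Boxes
#' reaching outside the image are an error: the proposal stage never emits
#' them, so one arriving here indicates a coordinate-bookkeeping bug.
#'
#' @param img Intensity matrix.
#' @param rois Box tibble of candidates.
#' @param clf An `"roi_classifier"`.
#' @return `rois` with a `p_lesion` column appended.
#' @export
score_rois <- function(img, rois, clf) {
  rois <- as_box_tibble(rois)
  if (nrow(rois) > 0 && !all(boxes_within_image(rois, dim(img)))) {
    abort("RoI outside the image bounds")
  }
  p <- if (nrow(rois) == 0) numeric(0) else clf$score(img, rois)
  if (any(p < 0 | p > 1)) abort("classifier returned probability outside [0, 1]")
  rois$p_lesion <- as.numeric(p)
  rois
}

#' Confidence-gate RoI scores
#'
#' Keeps candidates whose lesion probability is strictly greater than the
#' gate (default 0.9).  The result may be empty — that is the designed
#' outcome on a normal image, where no detection is reported.  Kept boxes
#' get `confidence = p_lesion`.
#'
#' @param scores Output of [score_rois()].
#' @param gate Probability threshold (default 0.9); scores exactly equal
#'   to the gate are excluded.
#' @return Filtered score tibble (possibly 0 rows).
#' @export
filter_rois <- function(scores, gate = 0.9) {
  out <- scores[scores$p_lesion > gate, , drop = FALSE]
  out$confidence <- out$p_lesion
  out
}

## candidate boxes around a truth box for training: positives are jitters
## of the truth (IoU mostly >= 0.5), negatives random boxes elsewhere
training_candidates <- function(img, truth, n_pos = 6, n_neg = 6) {
  H <- nrow(img); W <- ncol(img)
  cand <- list()
  if (!is.null(truth) && nrow(truth) > 0) {
    for (k in seq_len(n_pos)) {
      jw <- truth$w * exp(runif(1, -0.2, 0.2))
      jh <- truth$h * exp(runif(1, -0.2, 0.2))
      jx <- truth$x + runif(1, -0.15, 0.15) * truth$w
      jy <- truth$y + runif(1, -0.15, 0.15) * truth$h
      cand[[length(cand) + 1]] <- bbox(jx, jy, jw, jh)
    }
  }
  for (k in seq_len(n_neg)) {
    w <- runif(1, 0.15, 0.5) * W
    h <- runif(1, 0.15, 0.5) * H
    x <- runif(1, 0, W - w)
    y <- runif(1, 0, H - h)
    cand[[length(cand) + 1]] <- bbox(x, y, w, h)
  }
  dplyr::bind_rows(cand)
}

#' Train the RoI lesion classifier
#'
#' Desk-scale trainable classifier: candidate boxes are generated around
#' each sample's truth box (jittered positives, random negatives), labelled
#' by overlap — positive at Jaccard `>= 0.5`, negative at `< 0.2`,
#' in-between candidates discarded (the same bounds the pipeline uses for
#' true positives and background boxes) — and a single-hidden-layer neural
#' network is fitted on downsampled `12 x 12` RoI crops.  Training is fully
#' seeded and reproducible.
#'
#' @param samples A list of phantom samples (see [generate_phantom()]) or
#'   of lists with elements `image` and `truth_box` (`NULL` truth for
#'   normal images).
#' @param cfg A [pipeline_config()]; `rng_seed` seeds candidate generation
#'   and weight initialization.
#' @param hidden Hidden units (default 8).
#' @param maxit Optimizer iterations (default 150).
#' @return An `"roi_classifier"` whose `score()` is deterministic.
#' @export
train_classifier <- function(samples, cfg = pipeline_config(), hidden = 8,
                             maxit = 150) {
  if (length(samples) == 0) abort("no training samples")
  set.seed(cfg$rng_seed)
  feats <- list(); labels <- list()
  for (sm in samples) {
    truth <- sm$truth_box
    cand <- training_candidates(sm$image, truth)
    jac <- if (is.null(truth) || nrow(truth) == 0) rep(0, nrow(cand)) else
      box_jaccard(cand, truth)
    lab <- ifelse(jac >= 0.5, 1L, ifelse(jac < 0.2, 0L, NA_integer_))
    keep <- !is.na(lab) & boxes_within_image(cand, dim(sm$image))
    if (!any(keep)) next
    feats[[length(feats) + 1]] <- roi_crop_features(sm$image, cand[keep, ])
    labels[[length(labels) + 1]] <- lab[keep]
  }
  X <- do.call(rbind, feats)
  y <- unlist(labels)
  if (length(unique(y)) < 2) {
    abort("training data must contain both lesion and background RoIs")
  }
  mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
  fit <- nnet::nnet(Xs, y, size = hidden, entropy = TRUE, maxit = maxit,
                    decay = 1e-3, MaxNWts = 10000, trace = FALSE)
  new_roi_classifier(function(img, boxes) {
    F <- roi_crop_features(img, boxes)
    Fs <- sweep(sweep(F, 2, mu, "-"), 2, sg, "/")
    as.numeric(predict(fit, Fs))
  }, "trained-nnet")
}
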