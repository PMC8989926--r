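#' Pipeline configuration
#'
#' Collects every scalar threshold the detection pipeline uses.  The
#' defaults are the method's operating point: a 0.9 confidence gate on RoI
#' classification, Jaccard 0.2 as the background-box bound for the
#' regression loss, Jaccard 0.5 / 0.7 as the aggregation clustering and
#' intersection bounds, Jaccard 0.5 as the true-positive bound, and removal
#' of the bottom 30% of rows before region proposal (breast tumours sit
#' predominantly in the upper part of the scan).  Edge-detection and
#' denoising scales are not dictated by the method and are exposed here as
#' ordinary tunables.
#'
#' @param clip_fraction Fraction of bottom rows removed before proposal
#'   (default 0.3); in `(0, 1)`.
#' @param classifier_gate RoI confidence gate; boxes with probability
#'   strictly greater than this survive (default 0.9).
#' @param background_jaccard Boxes with IoU below this against truth are
#'   background and excluded from the regression loss (default 0.2).
#' @param cluster_jaccard Aggregation clustering bound: a box joins a
#'   cluster when its IoU with a member is strictly greater (default 0.5).
#' @param intersect_jaccard Aggregation merge branch point: pairs at or
#'   above it merge to their intersection, pairs in
#'   `[cluster_jaccard, intersect_jaccard)` to the smallest enclosing box
#'   (default 0.7).
#' @param tp_jaccard Evaluation true-positive bound (default 0.5).
#' @param total_steps Number of regression iterations `S` (default 4).
#' @param canny_low,canny_high Hysteresis thresholds on gradient magnitude
#'   of the normalized image (defaults 0.08 and 0.2; `canny_low <
#'   canny_high`).
#' @param gaussian_sigma Gaussian smoothing scale in pixels before the
#'   gradient (default 1.8).
#' @param edge_dilate Rounds of 8-neighborhood dilation applied to the
#'   final edge map before the initial segmentation (default 1).  Thinned
#'   contours carry occasional one-pixel gaps under speckle; one round of
#'   barrier thickening closes them so closed structures stay separated
#'   from the background.  Set 0 to segment on the raw thin edges.
#' @param wavelet_name Wavelet for denoising: `"haar"`, `"db2"` or `"db4"`
#'   (default `"db4"`).
#' @param wavelet_levels Decomposition depth (default 3).
#' @param min_roi_px Minimum proposal side length in pixels (default 16).
#' @param max_roi_frac Proposals covering more than this fraction of the
#'   frame are dropped (default 0.95).
#' @param rng_seed Seed recorded with the run (default 1).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(clip_fraction = 0.3,
                            classifier_gate = 0.9,
                            background_jaccard = 0.2,
                            cluster_jaccard = 0.5,
                            intersect_jaccard = 0.7,
                            tp_jaccard = 0.5,
                            total_steps = 4,
                            canny_low = 0.08,
                            canny_high = 0.2,
                            gaussian_sigma = 1.8,
                            edge_dilate = 1,
                            wavelet_name = "db4",
                            wavelet_levels = 3,
                            min_roi_px = 16,
                            max_roi_frac = 0.95,
                            rng_seed = 1L) {
  cfg <- list(
    clip_fraction = clip_fraction,
    classifier_gate = classifier_gate,
    background_jaccard = background_jaccard,
    cluster_jaccard = cluster_jaccard,
    intersect_jaccard = intersect_jaccard,
    tp_jaccard = tp_jaccard,
    total_steps = as.integer(total_steps),
    canny_low = canny_low,
    canny_high = canny_high,
    gaussian_sigma = gaussian_sigma,
    edge_dilate = as.integer(edge_dilate),
    wavelet_name = wavelet_name,
    wavelet_levels = as.integer(wavelet_levels),
    min_roi_px = min_roi_px,
    max_roi_frac = max_roi_frac,
    rng_seed = as.integer(rng_seed)
  )
  if (!(cfg$clip_fraction > 0 && cfg$clip_fraction < 1)) {
    abort("clip_fraction must lie strictly between 0 and 1")
  }
  if (!(cfg$background_jaccard > 0 &&
        cfg$background_jaccard < cfg$cluster_jaccard &&
        cfg$cluster_jaccard <= cfg$intersect_jaccard &&
        cfg$intersect_jaccard <= 1)) {
    abort("need 0 < background_jaccard < cluster_jaccard <= intersect_jaccard <= 1")
  }
  if (cfg$total_steps < 1) abort("total_steps must be >= 1")
  if (cfg$canny_low >= cfg$canny_high) abort("canny_low must be < canny_high")
  if (cfg$gaussian_sigma <= 0) abort("gaussian_sigma must be positive")
  if (cfg$edge_dilate < 0) abort("edge_dilate must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
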