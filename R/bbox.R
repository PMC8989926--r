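#' Construct a bounding-box tibble
#'
#' Boxes are the unit of currency of the detection pipeline: one row per box
#' with the upper-left vertex `(x, y)`, width `w` and height `h` in pixels,
#' and an optional classification `confidence` in `[0, 1]`.  Coordinates are
#' 0-based with `x` along columns and `y` along rows; a box covers the
#' half-open region `[x, x + w) x [y, y + h)`, so integer boxes have area
#' exactly `w * h`.  Sub-pixel coordinates are allowed (regression produces
#' them).
#'
#' @param x,y Coordinates of the upper-left vertex (finite reals).
#' @param w,h Width and height in pixels; must be strictly positive.
#' @param confidence Optional probability in `[0, 1]` (`NA` when unscored).
#' @return A tibble with columns `x`, `y`, `w`, `h`, `confidence`.
#' @examples
#' bbox(3, 2, 5, 4)
#' @export
bbox <- function(x, y, w, h, confidence = NA_real_) {
  out <- tibble(
    x = as.numeric(x), y = as.numeric(y),
    w = as.numeric(w), h = as.numeric(h),
    confidence = as.numeric(confidence)
  )
  validate_boxes(out)
  out
}

#' Validate a box tibble
#'
#' Checks the box invariants: numeric finite `x`, `y`, strictly positive
#' finite `w`, `h`, and `confidence` (if present and non-`NA`) in `[0, 1]`.
#' Returns its input invisibly so it can sit in a pipe.
#'
#' @param boxes A data frame with columns `x`, `y`, `w`, `h` and optionally
#'   `confidence`.
#' @return `boxes`, invisibly.
#' @export
validate_boxes <- function(boxes) {
  need <- c("x", "y", "w", "h")
  missing_cols <- setdiff(need, names(boxes))
  if (length(missing_cols) > 0) {
    abort(paste0("box tibble is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (cl in need) {
    v <- boxes[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(paste0("box column '", cl, "' must be finite numeric"))
    }
  }
  if (any(boxes$w <= 0) || any(boxes$h <= 0)) {
    abort("box width and height must be strictly positive")
  }
  if ("confidence" %in% names(boxes)) {
    cf <- boxes$confidence
    bad <- !is.na(cf) & (cf < 0 | cf > 1)
    if (any(bad)) abort("box confidence must lie in [0, 1]")
  }
  invisible(boxes)
}

as_box_tibble <- function(boxes) {
  boxes <- as_tibble(boxes)
  if (!"confidence" %in% names(boxes)) boxes$confidence <- NA_real_
  validate_boxes(boxes)
  boxes[c("x", "y", "w", "h", "confidence")]
}

#' Jaccard index (intersection over union) of boxes
#'
#' Continuous-area IoU under the half-open pixel convention: no
#' rasterization, so fractional boxes produced by regression are measured
#' exactly.  `a` and `b` are recycled row-wise against each other
#' (either may be a single row).
#'
#' @param a,b Box tibbles (see [bbox()]).
#' @return Numeric vector of IoU values in `[0, 1]`; disjoint pairs give 0.
#' @examples
#' box_jaccard(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10))  # 1/3
#' @export
box_jaccard <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' Pairwise Jaccard matrix between two box sets
#'
#' @param a,b Box tibbles with `m` and `n` rows.
#' @return An `m x n` numeric matrix of IoU values.
#' @export
box_jaccard_matrix <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  out <- matrix(0, m, n)
  for (j in seq_len(n)) {
    out[, j] <- box_jaccard(a, b[j, , drop = FALSE])
  }
  out
}

## intersection box of two single-row boxes (must overlap)
box_intersect <- function(a, b) {
  x0 <- max(a$x, b$x); y0 <- max(a$y, b$y)
  x1 <- min(a$x + a$w, b$x + b$w); y1 <- min(a$y + a$h, b$y + b$h)
  if (x1 <= x0 || y1 <= y0) abort("boxes do not overlap; no intersection box")
  bbox(x0, y0, x1 - x0, y1 - y0)
}

## smallest axis-aligned box covering both
box_enclose <- function(a, b) {
  x0 <- min(a$x, b$x); y0 <- min(a$y, b$y)
  x1 <- max(a$x + a$w, b$x + b$w); y1 <- max(a$y + a$h, b$y + b$h)
  bbox(x0, y0, x1 - x0, y1 - y0)
}

box_center <- function(boxes) {
  cbind(boxes$x + boxes$w / 2, boxes$y + boxes$h / 2)
}

#' Tight bounding box of a binary mask
#'
#' Converts a segmentation ground-truth mask to the smallest axis-aligned
#' box containing every foreground pixel — the form in which lesion ground
#' truth enters detection and evaluation.
#'
#' @param mask A logical or numeric matrix; pixels with value > 0 are
#'   foreground.
#' @return A one-row box tibble with integer-valued `x`, `y`, `w`, `h`.
#' @examples
#' m <- matrix(0, 8, 10); m[3:6, 4:8] <- 1
#' mask_to_bbox(m)  # x = 3, y = 2, w = 5, h = 4
#' @export
mask_to_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("no lesion in mask: every pixel is background")
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  # pixel [r, c] covers x in [c-1, c), y in [r-1, r)
  bbox(x = c0 - 1, y = r0 - 1, w = c1 - c0 + 1, h = r1 - r0 + 1)
}

boxes_within_image <- function(boxes, dim_hw) {
  boxes$x >= 0 & boxes$y >= 0 &
    boxes$x + boxes$w <= dim_hw[2] & boxes$y + boxes$h <= dim_hw[1]
}
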