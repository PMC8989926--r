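## reflective (half-sample symmetric) index into 1..n
reflect_index <- function(i, n) {
  i <- (i - 1) %% (2 * n)
  ifelse(i >= n, 2 * n - 1 - i, i) + 1
}

## out[r, c] = m[reflect(r + dr), reflect(c + dc)]
shift_reflect <- function(m, dr, dc) {
  m[reflect_index(seq_len(nrow(m)) + dr, nrow(m)),
    reflect_index(seq_len(ncol(m)) + dc, ncol(m)),
    drop = FALSE]
}

## cross-correlation with a small kernel, reflective border
xcorr2 <- function(m, kern) {
  kr <- (nrow(kern) - 1) / 2
  kc <- (ncol(kern) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      if (kern[i, j] != 0) {
        out <- out + kern[i, j] * shift_reflect(m, i - 1 - kr, j - 1 - kc)
      }
    }
  }
  out
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized discrete Gaussian (radius
#' `ceiling(3 * sigma)`), reflective border, so a constant image is exactly
#' preserved and mass is conserved in the interior.
#'
#' @param img Intensity matrix.
#' @param sigma Gaussian scale in pixels; must be positive.
#' @return Smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(img, sigma = 1.4) {
  if (sigma <= 0) abort("sigma must be positive")
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(img), ncol(img))
  for (m in seq_along(k)) {  # rows
    out <- out + k[m] * shift_reflect(img, m - 1 - r, 0)
  }
  out2 <- matrix(0, nrow(img), ncol(img))
  for (m in seq_along(k)) {  # cols
    out2 <- out2 + k[m] * shift_reflect(out, 0, m - 1 - r)
  }
  out2
}

#' Sobel gradient field
#'
#' Cross-correlates the image with the two 3x3 Sobel kernels
#' `Sx = [[1,2,1],[0,0,0],[-1,-2,-1]]` and
#' `Sy = [[1,0,-1],[2,0,-2],[1,0,-1]]`.  Note the naming: under this kernel
#' pair `gx` responds to intensity change down the rows and `gy` to change
#' across the columns (the transpose of the labels some texts use);
#' magnitude and the suppression geometry are unaffected, and the
#' `direction` angle is computed accordingly as
#' `atan2(d/d_row, d/d_col) = atan2(gx, gy)`.
#'
#' @param img (Smoothed) intensity matrix.
#' @return A list of class `"gradient_field"` with matrices `gx`, `gy`,
#'   `magnitude` and `direction` (radians).
#' @export
sobel_gradients <- function(img) {
  sx <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)   # rows: 1 2 1 / 0 0 0 / -1 -2 -1
  sy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3)   # rows: 1 0 -1 / 2 0 -2 / 1 0 -1
  gx <- xcorr2(img, sx)
  gy <- xcorr2(img, sy)
  structure(
    list(gx = gx, gy = gy,
         magnitude = sqrt(gx^2 + gy^2),
         direction = atan2(gx, gy)),
    class = "gradient_field"
  )
}

#' Non-maximum suppression
#'
#' Thins the gradient magnitude to one-pixel ridges: each pixel's direction
#' is quantized to one of four sectors (nearest-neighbor, no interpolation)
#' and the pixel survives only if its magnitude strictly exceeds both
#' neighbors along the positive and negative gradient direction.  Plateaus
#' of equal magnitude are suppressed by the strict inequality.
#'
#' @param field A `"gradient_field"` from [sobel_gradients()].
#' @return Matrix of suppressed magnitudes (0 where suppressed).
#' @export
nonmax_suppress <- function(field) {
  mag <- field$magnitude
  ang <- field$direction %% pi  # orientation in [0, pi)
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  # sector 0: gradient along cols -> neighbors left/right
  # sector 1: 45 deg (drow = dcol)  sector 2: along rows  sector 3: 135 deg
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- shift_reflect(mag, o[1], o[2])
    n2 <- shift_reflect(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag > n1 & mag > n2)
  }
  mag * keep
}

## one 8-neighborhood binary dilation step (zero border)
dilate8 <- function(b) {
  out <- b
  H <- nrow(b); W <- ncol(b)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
      ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
      out[ok_r, ok_c] <- out[ok_r, ok_c] | b[rs[ok_r], cs[ok_c]]
    }
  }
  out
}

#' Hysteresis thresholding
#'
#' Two-threshold edge labelling: magnitudes above `high` are strong edges,
#' magnitudes in `[low, high]` are weak, anything below `low` is
#' suppressed.  Weak pixels enter the final edge map only if 8-connected —
#' possibly through other weak pixels — to a strong pixel.
#'
#' @param suppressed Matrix of suppressed magnitudes from
#'   [nonmax_suppress()].
#' @param low,high Thresholds with `low < high`.
#' @return A list of class `"edge_map"` with logical matrices `strong`,
#'   `weak` and `final` (`strong` is always a subset of `final`;
#'   `weak` and `strong` are disjoint).
#' @export
hysteresis_threshold <- function(suppressed, low, high) {
  if (low >= high) abort("hysteresis needs low < high")
  strong <- suppressed > high
  weak <- suppressed >= low & suppressed <= high
  cand <- strong | weak
  final <- strong
  repeat {
    grown <- dilate8(final) & cand
    if (identical(grown, final)) break
    final <- grown
  }
  structure(list(strong = strong, weak = weak, final = final),
            class = "edge_map")
}

#' Canny edge detection
#'
#' The four-step chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression, hysteresis thresholding.
#'
#' @param img Normalized intensity matrix.
#' @param cfg A [pipeline_config()]; uses `gaussian_sigma`, `canny_low`,
#'   `canny_high`.
#' @return An `"edge_map"` (see [hysteresis_threshold()]).
#' @export
canny <- function(img, cfg = pipeline_config()) {
  img |>
    gaussian_smooth(cfg$gaussian_sigma) |>
    sobel_gradients() |>
    nonmax_suppress() |>
    hysteresis_threshold(cfg$canny_low, cfg$canny_high)
}
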