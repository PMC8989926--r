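## Bilinear sampling of img at matrix coordinates (r, c); coordinates are
## clamped to the frame, so boxes straddling the border still crop cleanly.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)];     i01 <- img[cbind(r0, c0 + 1)]
  i10 <- img[cbind(r0 + 1, c0)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

#' Resample a box crop to a fixed grid
#'
#' Bilinear resize of the image content under a (possibly fractional) box
#' to an `out x out` matrix — the fixed-size input every learned model
#' consumes.  Sampling points are the centers of an `out x out` grid laid
#' over the box; points outside the frame clamp to the border.
#'
#' @param img Intensity matrix.
#' @param box One-row box tibble.
#' @param out Side length of the output grid (default 16).
#' @return An `out x out` numeric matrix.
#' @export
crop_resize <- function(img, box, out = 16) {
  u <- (seq_len(out) - 0.5) / out
  xs <- box$x + u * box$w       # 0-based x of sample centers
  ys <- box$y + u * box$h
  cs <- xs + 0.5                # matrix column coordinate
  rs <- ys + 0.5
  grid_r <- rep(rs, times = out)
  grid_c <- rep(cs, each = out)
  matrix(bilinear_sample(img, grid_r, grid_c), out, out)
}

## Feature vector for the RoI classifier: downsampled crop intensities.
roi_crop_features <- function(img, boxes, out = 12) {
  t(vapply(seq_len(nrow(boxes)), function(i) {
    as.vector(crop_resize(img, boxes[i, ], out))
  }, numeric(out * out)))
}

## Feature vector for the box regressor: a context window (the box expanded
## by `expand` about its center) resampled to `out x out`, plus darkness
## moments of that window — the normalized centroid and spread of
## (1 - intensity), which locate a hypoechoic lesion relative to the box —
## and the log box dimensions relative to the frame.
regressor_features <- function(img, boxes, out = 12, expand = 2) {
  H <- nrow(img); W <- ncol(img)
  t(vapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    cx <- b$x + b$w / 2; cy <- b$y + b$h / 2
    ctx <- bbox(cx - b$w * expand / 2, cy - b$h * expand / 2,
                b$w * expand, b$h * expand)
    crop <- crop_resize(img, ctx, out)
    dark <- 1 - crop
    wsum <- sum(dark)
    u <- (seq_len(out) - 0.5) / out - 0.5   # window-normalized coords
    if (wsum > 0) {
      # column-major layout: rep(u, each = out) varies with column (x),
      # rep(u, times = out) with row (y)
      mx <- sum(dark * rep(u, each = out)) / wsum
      my <- sum(dark * rep(u, times = out)) / wsum
      vx <- sqrt(max(sum(dark * rep(u, each = out)^2) / wsum - mx^2, 0))
      vy <- sqrt(max(sum(dark * rep(u, times = out)^2) / wsum - my^2, 0))
    } else {
      mx <- my <- vx <- vy <- 0
    }
    c(as.vector(crop), mx, my, vx, vy,
      log(b$w / W), log(b$h / H), mean(dark))
  }, numeric(out * out + 7)))
}
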