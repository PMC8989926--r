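#' Global histogram equalization
#'
#' Spreads the intensity CDF over the full scale.  Input may be raw 8-bit
#' (0..255) or normalized `[0, 1]`; it is quantized to 256 levels, remapped
#' by `(cdf(v) - cdf_min) / (1 - cdf_min)`, and returned on the input's
#' scale.  A constant image is returned unchanged (there is nothing to
#' spread); any image with at least two distinct levels comes out spanning
#' the full scale.
#'
#' @param img Numeric intensity matrix.
#' @return Matrix of the same shape and scale.
#' @export
equalize_histogram <- function(img) {
  rng_max <- if (max(img) > 1) 255 else 1
  lv <- pmin(pmax(round(img / rng_max * 255), 0), 255)
  counts <- tabulate(lv + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(lv)
  cdf_min <- min(cdf[counts > 0])
  if (cdf_min >= 1) return(img)  # single level
  eq <- (cdf - cdf_min) / (1 - cdf_min)
  matrix(eq[lv + 1L] * rng_max, nrow(img), ncol(img))
}

#' Min-max normalization to [0, 1]
#'
#' Per-image linear rescale; a constant image maps to all zeros.
#'
#' @param img Numeric intensity matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(matrix(0, nrow(img), ncol(img)))
  (img - lo) / (hi - lo)
}

## ---- separable periodized 2-D wavelet transform -------------------------
## Orthonormal Daubechies filters; analysis a_k = sum_m h_m x_{(2k+m) mod N},
## synthesis is the transpose, so reconstruction is exact.

wavelet_filter <- function(name) {
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983849,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    abort(paste0("unknown wavelet '", name, "' (use haar, db2 or db4)"))
  )
}

## analysis on each column of a matrix; returns list(a, d)
dwt_cols <- function(m, h) {
  n <- nrow(m)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  k2 <- 2 * (seq_len(n / 2) - 1)
  a <- matrix(0, n / 2, ncol(m)); d <- a
  for (mm in seq_len(L)) {
    idx <- (k2 + mm - 1) %% n + 1
    a <- a + h[mm] * m[idx, , drop = FALSE]
    d <- d + g[mm] * m[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

idwt_cols <- function(a, d, h) {
  n <- 2 * nrow(a)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  out <- matrix(0, n, ncol(a))
  k2 <- 2 * (seq_len(n / 2) - 1)
  for (mm in seq_len(L)) {
    idx <- (k2 + mm - 1) %% n + 1
    contrib <- h[mm] * a + g[mm] * d
    # scatter-add; idx has no duplicates within one tap shift
    out[idx, ] <- out[idx, ] + contrib
  }
  out
}

dwt2_level <- function(m, h) {
  cs <- dwt_cols(m, h)
  ll_lh <- dwt_cols(t(cs$a), h)  # rows of approx
  hl_hh <- dwt_cols(t(cs$d), h)  # rows of detail
  list(ll = t(ll_lh$a), lh = t(ll_lh$d), hl = t(hl_hh$a), hh = t(hl_hh$d))
}

idwt2_level <- function(bands, h) {
  a <- t(idwt_cols(t(bands$ll), t(bands$lh), h))
  d <- t(idwt_cols(t(bands$hl), t(bands$hh), h))
  idwt_cols(a, d, h)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Wavelet shrinkage denoising
#'
#' Multilevel separable wavelet decomposition (periodized orthonormal
#' Daubechies filters), soft thresholding of every detail subband, and exact
#' reconstruction.  The threshold is BayesShrink: the noise scale is
#' estimated once from the finest diagonal subband as
#' `median(|HH1|) / 0.6745`, and each subband is shrunk by
#' `sigma^2 / sigma_x` where `sigma_x^2` is the subband's signal variance
#' estimate (subbands indistinguishable from pure noise are zeroed).  The
#' image is symmetrically padded to a multiple of `2^levels` and cropped
#' back, so any shape is accepted.
#'
#' @param img Normalized intensity matrix.
#' @param wavelet_name `"haar"`, `"db2"` or `"db4"`.
#' @param levels Decomposition depth; must leave the coarsest level at
#'   least as long as the filter.
#' @return Denoised matrix, same shape.
#' @export
wavelet_denoise <- function(img, wavelet_name = "db4", levels = 3) {
  h <- wavelet_filter(wavelet_name)
  levels <- as.integer(levels)
  if (levels < 1) abort("levels must be >= 1")
  H <- nrow(img); W <- ncol(img)
  unit <- 2^levels
  # periodized orthonormal filters reconstruct exactly for any even length,
  # so the only hard limit is having at least one coefficient per subband
  if (unit > min(H, W)) {
    abort("wavelet levels too deep for image size")
  }
  Hp <- ceiling(H / unit) * unit
  Wp <- ceiling(W / unit) * unit
  # symmetric (mirror) extension on the bottom/right
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  m <- img[ri, ci, drop = FALSE]

  bands <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    b <- dwt2_level(cur, h)
    bands[[l]] <- b
    cur <- b$ll
  }
  sigma <- stats::median(abs(bands[[1]]$hh)) / 0.6745
  shrink <- function(d) {
    if (sigma == 0) return(d)
    vx <- mean(d^2) - sigma^2
    t <- if (vx <= 0) max(abs(d)) else sigma^2 / sqrt(vx)
    soft_threshold(d, t)
  }
  for (l in rev(seq_len(levels))) {
    b <- bands[[l]]
    b$lh <- shrink(b$lh); b$hl <- shrink(b$hl); b$hh <- shrink(b$hh)
    b$ll <- cur
    cur <- idwt2_level(b, h)
  }
  cur[seq_len(H), seq_len(W), drop = FALSE]
}

round_half_up <- function(x) floor(x + 0.5)

#' Clip the bottom of an image
#'
#' Removes the lowest `clip_fraction` of rows — the posterior part of the
#' scan where breast lesions rarely sit and redundant proposals accumulate.
#' Only bottom rows are discarded, so box coordinates in the clipped frame
#' equal those in the original frame; the returned offset map records this.
#' The retained count is `round((1 - clip_fraction) * H)`
#' (half away from zero).
#'
#' @param img Intensity matrix.
#' @param clip_fraction Fraction of bottom rows to remove, in `(0, 1)`.
#' @return A list with `image` (clipped matrix), `kept_rows`,
#'   `original_height`, and `row_offset_map = c(x = 0, y = 0)`.
#' @export
clip_bottom <- function(img, clip_fraction = 0.3) {
  if (!(clip_fraction > 0 && clip_fraction < 1)) {
    abort("clip_fraction must lie strictly between 0 and 1")
  }
  H <- nrow(img)
  kept <- round_half_up((1 - clip_fraction) * H)
  if (kept < 1) abort("clipping would remove every row")
  list(
    image = img[seq_len(kept), , drop = FALSE],
    kept_rows = as.integer(kept),
    original_height = H,
    row_offset_map = c(x = 0, y = 0)
  )
}

#' Full preprocessing chain
#'
#' Applies, in order: histogram equalization, min-max normalization,
#' wavelet shrinkage denoising, and bottom clipping.  The order matters:
#' equalization works on the raw intensity histogram, denoising assumes a
#' normalized image, and clipping is last so the denoiser never sees a
#' truncated frame.
#'
#' @param img Intensity matrix (raw 8-bit or `[0, 1]`).
#' @param cfg A [pipeline_config()].
#' @return As [clip_bottom()], with `image` fully processed; the additional
#'   element `stages` names the stages applied in order.
#' @export
preprocess <- function(img, cfg = pipeline_config()) {
  out <- img |>
    equalize_histogram() |>
    normalize_image() |>
    wavelet_denoise(cfg$wavelet_name, cfg$wavelet_levels) |>
    clip_bottom(cfg$clip_fraction)
  out$stages <- c("equalize", "normalize", "denoise", "clip")
  out
}
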