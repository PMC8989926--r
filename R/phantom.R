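#' Speckle-phantom configuration
#'
#' Parameters of the synthetic breast-ultrasound phantom: a brighter tissue
#' background carrying multiplicative speckle, a darker (hypoechoic)
#' elliptical lesion, an optional acoustic-shadow streak below the lesion,
#' and a dark posterior band over the bottom rows (the region the
#' preprocessing clip removes).  The lesion must sit entirely above the
#' posterior band — the anatomical prior the pipeline's bottom clip relies
#' on — and that is enforced here as an invariant.
#'
#' @param height,width Frame size in pixels (default 128 x 128).
#' @param lesion_center `c(x, y)` of the ellipse center, 0-based pixel
#'   coordinates; `NULL` for a lesion-free (normal) phantom.
#' @param lesion_axes `c(a, b)` semi-axes in pixels, each at least 4.
#' @param lesion_angle Ellipse rotation in radians.
#' @param background_level,lesion_level Mean echogenicity of tissue and
#'   lesion; `lesion_level < background_level`.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative
#'   speckle; larger is smoother (default 8).
#' @param shadow Add an acoustic-shadow streak below the lesion?
#' @param shadow_strength Multiplicative attenuation of the streak
#'   (default 0.55).
#' @param shadow_width Width of the streak as a fraction of the lesion
#'   width (default 0.7, centred on the lesion): shadowing emanates from
#'   the strongly attenuating core of the mass.
#' @param posterior_band_fraction Bottom fraction of rows darkened
#'   (default 0.3).
#' @param seed Integer seed; the phantom is a pure function of its config.
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(height = 128, width = 128,
                           lesion_center = c(64, 40),
                           lesion_axes = c(14, 10),
                           lesion_angle = 0,
                           background_level = 0.6,
                           lesion_level = 0.25,
                           speckle_shape = 8,
                           shadow = FALSE,
                           shadow_strength = 0.55,
                           shadow_width = 0.7,
                           posterior_band_fraction = 0.3,
                           seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              lesion_center = lesion_center, lesion_axes = lesion_axes,
              lesion_angle = lesion_angle,
              background_level = background_level,
              lesion_level = lesion_level, speckle_shape = speckle_shape,
              shadow = isTRUE(shadow), shadow_strength = shadow_strength,
              shadow_width = shadow_width,
              posterior_band_fraction = posterior_band_fraction,
              seed = as.integer(seed))
  if (cfg$height < 16 || cfg$width < 16) abort("phantom frame too small")
  if (cfg$shadow_width <= 0 || cfg$shadow_width > 1) {
    abort("shadow_width must lie in (0, 1]")
  }
  if (!is.null(cfg$lesion_center)) {
    if (any(cfg$lesion_axes < 4)) abort("lesion semi-axes must be >= 4 px")
    if (cfg$lesion_level >= cfg$background_level) {
      abort("lesion_level must be below background_level (hypoechoic)")
    }
    ext <- max(cfg$lesion_axes)
    top_rows <- (1 - cfg$posterior_band_fraction) * cfg$height
    if (cfg$lesion_center[1] - ext < 0 ||
        cfg$lesion_center[1] + ext > cfg$width ||
        cfg$lesion_center[2] - ext < 0 ||
        cfg$lesion_center[2] + ext > top_rows) {
      abort("lesion out of bounds: ellipse must fit above the posterior band")
    }
  }
  structure(cfg, class = "phantom_config")
}

#' Generate one speckle phantom
#'
#' Builds the clean echogenicity field (background tissue with smooth
#' spatial variation, the ellipse attenuated to `lesion_level`, the
#' optional shadow streak, the dark posterior band), then multiplies it by
#' unit-mean gamma speckle with a short correlation length.  Because the
#' speckle is applied last, `image / clean` has unit mean everywhere, and
#' the lesion stays darker than the surrounding tissue in expectation.
#' The returned mask is the exact rasterized ellipse (pixel centers inside)
#' and the truth box is its tight bounding box.  Deterministic given the
#' config seed.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `"us_phantom"`: list with `image` (matrix,
#'   nonnegative, nominal range `[0, ~1.5]` before any clamping), `mask`
#'   (logical matrix), `truth_box` (box tibble, 0 rows for a normal
#'   phantom), `clean` (noise-free field) and `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width
  # smooth tissue texture: +/- 8% large-scale variation
  tex <- gaussian_smooth(matrix(rnorm(H * W), H, W), 4)
  tex <- tex / max(sd(tex), 1e-12)
  clean <- cfg$background_level * (1 + 0.08 * tex)

  mask <- matrix(FALSE, H, W)
  if (!is.null(cfg$lesion_center)) {
    cx <- cfg$lesion_center[1]; cy <- cfg$lesion_center[2]
    a <- cfg$lesion_axes[1]; b <- cfg$lesion_axes[2]
    th <- cfg$lesion_angle
    px <- col(clean) - 0.5; py <- row(clean) - 0.5  # pixel centers, 0-based
    dx <- px - cx; dy <- py - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    mask <- u^2 + v^2 <= 1
    clean[mask] <- cfg$lesion_level
    if (cfg$shadow) {
      in_cols <- range(which(colSums(mask) > 0))
      mid <- mean(in_cols)
      half <- (in_cols[2] - in_cols[1]) * cfg$shadow_width / 2
      shadow_cols <- seq(max(1, ceiling(mid - half)),
                         min(W, floor(mid + half)))
      below <- max(which(rowSums(mask) > 0))
      if (below < H) {
        clean[(below + 1):H, shadow_cols] <-
          clean[(below + 1):H, shadow_cols] * cfg$shadow_strength
      }
    }
    # soften the lesion boundary by half a pixel so edges are not aliased
    clean <- gaussian_smooth(clean, 0.5)
  }
  band_start <- floor((1 - cfg$posterior_band_fraction) * H) + 1
  clean[band_start:H, ] <- clean[band_start:H, ] * 0.35

  k <- cfg$speckle_shape
  speckle <- matrix(rgamma(H * W, shape = k, rate = k), H, W)
  speckle <- gaussian_smooth(speckle, 0.6)
  img <- clean * speckle

  truth <- if (any(mask)) mask_to_bbox(mask) else
    bbox(0, 0, 1, 1)[0, ]
  structure(list(image = img, mask = mask, truth_box = truth,
                 clean = clean, config = cfg),
            class = "us_phantom")
}

#' @export
print.us_phantom <- function(x, ...) {
  cat(sprintf("<us_phantom %dx%d, %s>\n", nrow(x$image), ncol(x$image),
              if (nrow(x$truth_box) > 0) sprintf(
                "lesion box (%.0f, %.0f, %.0f, %.0f)",
                x$truth_box$x, x$truth_box$y, x$truth_box$w, x$truth_box$h)
              else "normal (no lesion)"))
  invisible(x)
}

#' Generate a seeded phantom dataset
#'
#' Draws `n` phantom configurations from the stated ranges with a single
#' seeded generator and renders each phantom from its own derived seed, so
#' the whole dataset is reproducible from one integer.  A fixed fraction of
#' the phantoms — exactly `round(n * normal_fraction)`, at seeded positions
#' — are lesion-free.
#'
#' @param n Number of phantoms.
#' @param seed Dataset seed.
#' @param normal_fraction Fraction of lesion-free phantoms (default 0).
#' @param height,width Frame size.
#' @param axes_range Range of ellipse semi-axes in pixels (default 8..16).
#' @param lesion_level_range Range of lesion echogenicity (0.2..0.35).
#' @param angle_range Range of ellipse rotation (0..pi).
#' @param shadow_prob Probability a lesion phantom carries a shadow
#'   streak (default 0.25).
#' @param margin Minimum clearance between the lesion extent and the frame
#'   / posterior band (default 3 px).
#' @return A list with `samples` (list of `"us_phantom"`) and `manifest`
#'   (tibble: `image_id`, `seed`, `is_normal`, geometry, truth box).
#' @export
generate_dataset <- function(n, seed = 1L, normal_fraction = 0,
                             height = 128, width = 128,
                             axes_range = c(8, 16),
                             lesion_level_range = c(0.2, 0.35),
                             angle_range = c(0, pi),
                             shadow_prob = 0.25,
                             margin = 3) {
  if (n < 1) abort("n must be >= 1")
  if (normal_fraction < 0 || normal_fraction > 1) {
    abort("normal_fraction must lie in [0, 1]")
  }
  bad_range <- function(r) length(r) != 2 || r[1] > r[2]
  if (bad_range(axes_range) || bad_range(lesion_level_range) ||
      bad_range(angle_range)) {
    abort("invalid parameter range (need c(min, max) with min <= max)")
  }
  if (axes_range[1] < 4) abort("invalid range: semi-axes must be >= 4 px")
  set.seed(seed)
  n_normal <- round_half_up(n * normal_fraction)
  normal_idx <- if (n_normal > 0) sort(sample.int(n, n_normal)) else integer(0)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  top_rows <- (1 - 0.3) * height

  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    is_normal <- i %in% normal_idx
    if (is_normal) {
      cfg <- phantom_config(height = height, width = width,
                            lesion_center = NULL, seed = sample_seeds[i])
    } else {
      a <- runif(1, axes_range[1], axes_range[2])
      b <- runif(1, axes_range[1], axes_range[2])
      ext <- max(a, b) + margin
      cx <- runif(1, ext, width - ext)
      cy <- runif(1, ext, top_rows - ext)
      cfg <- phantom_config(
        height = height, width = width,
        lesion_center = c(cx, cy), lesion_axes = c(a, b),
        lesion_angle = runif(1, angle_range[1], angle_range[2]),
        lesion_level = runif(1, lesion_level_range[1],
                             lesion_level_range[2]),
        shadow = runif(1) < shadow_prob,
        seed = sample_seeds[i])
    }
    samples[[i]] <- generate_phantom(cfg)
    tb <- samples[[i]]$truth_box
    rows[[i]] <- tibble(
      image_id = sprintf("phantom_%04d", i),
      seed = sample_seeds[i],
      is_normal = is_normal,
      center_x = if (is_normal) NA_real_ else cfg$lesion_center[1],
      center_y = if (is_normal) NA_real_ else cfg$lesion_center[2],
      semi_axis_a = if (is_normal) NA_real_ else cfg$lesion_axes[1],
      semi_axis_b = if (is_normal) NA_real_ else cfg$lesion_axes[2],
      angle = if (is_normal) NA_real_ else cfg$lesion_angle,
      shadow = if (is_normal) NA else cfg$shadow,
      truth_x = if (nrow(tb) > 0) tb$x else NA_real_,
      truth_y = if (nrow(tb) > 0) tb$y else NA_real_,
      truth_w = if (nrow(tb) > 0) tb$w else NA_real_,
      truth_h = if (nrow(tb) > 0) tb$h else NA_real_
    )
  }
  list(samples = samples, manifest = dplyr::bind_rows(rows))
}

#' Write a phantom dataset to disk
#'
#' Writes images and masks as PNG, truth boxes as JSON detection records,
#' and the manifest as CSV — the on-disk layout the CLI consumes.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truths <- list()
  for (i in seq_along(dataset$samples)) {
    sm <- dataset$samples[[i]]
    id <- dataset$manifest$image_id[i]
    write_gray_image(sm$image / max(sm$image), file.path(dir, paste0(id, ".png")))
    if (nrow(sm$truth_box) > 0) {
      write_gray_image(sm$mask * 1, file.path(dir, paste0(id, "_mask.png")))
      tb <- sm$truth_box
      tb$image_id <- id
      truths[[length(truths) + 1]] <- tb
    }
  }
  write_detections(dplyr::bind_rows(truths), file.path(dir, "truth.json"))
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}
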