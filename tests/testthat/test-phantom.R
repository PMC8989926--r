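test_that("phantoms are bit-identical given the same seed", {
  a <- generate_phantom(phantom_config(seed = 12))
  b <- generate_phantom(phantom_config(seed = 12))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c2 <- generate_phantom(phantom_config(seed = 13))
  expect_false(identical(a$image, c2$image))
})

test_that("the lesion is hypoechoic in every seeded phantom", {
  for (s in 1:20) {
    ph <- generate_phantom(phantom_config(seed = s))
    top <- 1:round(0.7 * nrow(ph$image))
    inside <- mean(ph$image[top, ][ph$mask[top, ]])
    outside <- mean(ph$image[top, ][!ph$mask[top, ]])
    expect_lt(inside, outside)
  }
})

test_that("truth boxes equal the mask bounding box over random configs", {
  set.seed(19)
  for (k in 1:50) {
    a <- runif(1, 5, 16); b <- runif(1, 5, 16)
    ext <- max(a, b) + 2
    cfg <- phantom_config(
      lesion_center = c(runif(1, ext, 128 - ext), runif(1, ext, 89 - ext)),
      lesion_axes = c(a, b), lesion_angle = runif(1, 0, pi),
      seed = k)
    ph <- generate_phantom(cfg)
    expect_equal(ph$truth_box[, 1:4], mask_to_bbox(ph$mask)[, 1:4])
  }
})

test_that("multiplicative speckle has unit mean outside the lesion", {
  for (s in 1:5) {
    ph <- generate_phantom(phantom_config(seed = 100 + s))
    ratio <- ph$image / ph$clean
    sel <- !ph$mask
    expect_lt(abs(mean(ratio[sel]) - 1), 0.02)
  }
})

test_that("the shadow streak darkens the region below the lesion", {
  ph_s <- generate_phantom(phantom_config(seed = 3, shadow = TRUE))
  ph_n <- generate_phantom(phantom_config(seed = 3, shadow = FALSE))
  tb <- ph_n$truth_box
  below_rows <- seq(round(tb$y + tb$h) + 2, round(0.7 * 128) - 1)
  mid_cols <- seq(round(tb$x + tb$w * 0.35), round(tb$x + tb$w * 0.65))
  expect_lt(mean(ph_s$image[below_rows, mid_cols]),
            0.8 * mean(ph_n$image[below_rows, mid_cols]))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(lesion_axes = c(2, 10)), ">= 4 px")
  expect_error(phantom_config(lesion_level = 0.7), "hypoechoic")
  expect_error(phantom_config(lesion_center = c(64, 80)), "out of bounds")
  expect_error(phantom_config(shadow_width = 0), "shadow_width")
})

test_that("dataset generation is reproducible with exact normal counts", {
  d1 <- generate_dataset(20, seed = 77, normal_fraction = 0.2)
  d2 <- generate_dataset(20, seed = 77, normal_fraction = 0.2)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$samples[[5]]$image, d2$samples[[5]]$image)
  expect_equal(sum(d1$manifest$is_normal), 4)

  d3 <- generate_dataset(50, seed = 7, normal_fraction = 0.2)
  expect_equal(sum(d3$manifest$is_normal), 10)

  # all lesion centers above the 70%-row line
  lesions <- d3$manifest[!d3$manifest$is_normal, ]
  expect_true(all(lesions$center_y < 0.7 * 128))

  expect_error(generate_dataset(0), "n must be")
  expect_error(generate_dataset(5, axes_range = c(2, 10)), "invalid range")
  expect_error(generate_dataset(5, axes_range = c(16, 8)), "invalid")
  expect_error(generate_dataset(5, normal_fraction = 1.5), "normal_fraction")
})

test_that("a dataset written to disk reads back consistently", {
  ds <- generate_dataset(3, seed = 15, normal_fraction = 1 / 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  truth <- read_detections(file.path(dir, "truth.json"))
  expect_equal(nrow(truth), sum(!ds$manifest$is_normal))
  img <- read_gray_image(file.path(dir, ds$manifest$image_id[1], fsep = "/") |>
                           paste0(".png"))
  expect_equal(dim(img), c(128, 128))
  mf <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), 3)
})
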