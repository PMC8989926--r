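test_that("gaussian smoothing preserves constants, mass, and the small-sigma limit", {
  expect_equal(gaussian_smooth(matrix(2.5, 20, 20), 1.5),
               matrix(2.5, 20, 20), tolerance = 1e-12)

  spike <- matrix(0, 33, 33); spike[17, 17] <- 1
  expect_equal(sum(gaussian_smooth(spike, 2)), 1, tolerance = 1e-6)

  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  expect_lt(max(abs(gaussian_smooth(img, 0.1) - img)), 1e-3)
  expect_error(gaussian_smooth(img, 0), "positive")
})

test_that("sobel gradients match hand cross-correlation of the kernels", {
  expect_equal(sobel_gradients(matrix(1, 10, 10))$magnitude,
               matrix(0, 10, 10))

  # horizontal ramp I(r, c) = c: change across columns -> |gy| = 8 interior
  ramp_c <- matrix(rep(1:12, each = 10), 10, 12)
  gf <- sobel_gradients(ramp_c)
  expect_equal(abs(gf$gy[5, 6]), 8)
  expect_equal(gf$gx[5, 6], 0)

  # vertical ramp I(r, c) = r: change down rows -> |gx| = 8 interior
  ramp_r <- matrix(rep(1:12, 10), 12, 10)
  gf <- sobel_gradients(ramp_r)
  expect_equal(abs(gf$gx[6, 5]), 8)
  expect_equal(gf$gy[6, 5], 0)
})

test_that("non-maximum suppression thins an ideal step edge to one pixel", {
  # ramp column at c = 10: 0 | 0.5 | 1 step
  img <- matrix(0, 20, 20)
  img[, 10] <- 0.5
  img[, 11:20] <- 1
  sup <- nonmax_suppress(sobel_gradients(img))
  for (r in 3:18) expect_equal(sum(sup[r, ] > 0), 1)

  expect_equal(nonmax_suppress(sobel_gradients(matrix(1, 8, 8))),
               matrix(0, 8, 8))

  # plateau of equal magnitudes is suppressed by strictness
  f <- sobel_gradients(matrix(0, 8, 8))
  f$magnitude <- matrix(1, 8, 8)
  f$direction <- matrix(0, 8, 8)
  expect_equal(nonmax_suppress(f), matrix(0, 8, 8))
})

test_that("hysteresis matches the printed rules and a flood-fill oracle", {
  m <- matrix(5, 6, 6)
  em <- hysteresis_threshold(m, 1, 2)
  expect_true(all(em$final))

  # weak-only blob, no strong support
  m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1.5
  em <- hysteresis_threshold(m, 1, 2)
  expect_false(any(em$final))

  # weak chain touching one strong pixel is fully recovered
  m <- matrix(0, 5, 12)
  m[3, 2:10] <- 1.5; m[3, 11] <- 3
  em <- hysteresis_threshold(m, 1, 2)
  expect_true(all(em$final[3, 2:11]))

  expect_error(hysteresis_threshold(m, 2, 1), "low < high")

  set.seed(21)
  for (k in 1:50) {
    mag <- matrix(runif(15 * 15, 0, 3), 15, 15) *
      (matrix(runif(15 * 15), 15, 15) < 0.4)
    em <- hysteresis_threshold(mag, 0.8, 1.8)
    expect_equal(em$final, bfs_hysteresis(mag, 0.8, 1.8))
    expect_true(all(em$final[em$strong]))       # strong subset of final
    expect_false(any(em$weak & em$strong))      # weak and strong disjoint
  }
})

test_that("canny finds a clean disc edge and survives speckle", {
  cfg <- pipeline_config()
  expect_false(any(canny(matrix(0.5, 32, 32), cfg)$final))

  disc <- disc_image(64, 20, 0.5)
  em <- canny(disc, cfg)
  idx <- which(em$final, arr.ind = TRUE)
  d <- sqrt((idx[, 2] - 0.5 - 32)^2 + (idx[, 1] - 0.5 - 32)^2)
  expect_gte(mean(abs(d - 20) <= 2), 0.95)

  # recall of the circle under multiplicative speckle, 10 seeds
  theta <- seq(0, 2 * pi, length.out = 180)
  cx <- 32 + 20 * cos(theta); cy <- 32 + 20 * sin(theta)
  recalls <- sapply(1:10, function(s) {
    set.seed(s)
    spk <- disc * matrix(rgamma(64 * 64, 8, 8), 64, 64)
    em <- canny(normalize_image(spk), cfg)
    idx <- which(em$final, arr.ind = TRUE)
    if (nrow(idx) == 0) return(0)
    mean(sapply(seq_along(theta), function(i) {
      min(sqrt((idx[, 2] - 0.5 - cx[i])^2 + (idx[, 1] - 0.5 - cy[i])^2)) <= 2
    }))
  })
  expect_gte(mean(recalls), 0.8)
})
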