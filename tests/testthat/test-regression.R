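test_that("delta encoding matches its closed form", {
  d <- encode_delta(bbox(10, 20, 40, 60), bbox(14, 26, 40, 60))
  expect_equal(unlist(d, use.names = FALSE), c(0.1, 0.1, 0, 0))

  b <- bbox(3, 4, 7, 9)
  expect_equal(unlist(encode_delta(b, b), use.names = FALSE), rep(0, 4))

  d <- encode_delta(bbox(0, 0, 10, 10), bbox(0, 0, 20, 10))
  expect_equal(unlist(d, use.names = FALSE), c(0, 0, log(2), 0))
})

test_that("delta decoding matches its closed form and identity", {
  b <- bbox(5, 6, 12, 8)
  expect_equal(apply_delta(b, tibble::tibble(t_x = 0, t_y = 0,
                                             t_w = 0, t_h = 0))[, 1:4],
               b[, 1:4])
  g <- apply_delta(bbox(0, 0, 10, 10),
                   tibble::tibble(t_x = 0.5, t_y = 0.2, t_w = log(2),
                                  t_h = 0))
  expect_equal(unlist(g[, 1:4], use.names = FALSE), c(5, 2, 20, 10))
  expect_error(apply_delta(b, tibble::tibble(t_x = Inf, t_y = 0, t_w = 0,
                                             t_h = 0)), "finite")
})

test_that("encode and apply are exact inverses on random pairs", {
  set.seed(101)
  for (k in 1:1000) {
    B <- random_real_box(); G <- random_real_box()
    back <- apply_delta(B, encode_delta(B, G))
    expect_equal(unlist(back[, 1:4]), unlist(G[, 1:4]), tolerance = 1e-9)
  }
})

test_that("the stepped target splits the correction as printed", {
  tgt <- step_target(bbox(0, 0, 10, 10), bbox(8, 0, 10, 10), s = 1, S = 4)
  expect_equal(unlist(tgt[, 1:4], use.names = FALSE), c(2, 0, 10, 10))

  B <- bbox(3, 1, 6, 9); G <- bbox(10, 12, 20, 15)
  expect_equal(step_target(B, G, s = 4, S = 4)[, 1:4], G[, 1:4])
  expect_equal(step_target(G, G, s = 2, S = 4)[, 1:4], G[, 1:4])
  expect_error(step_target(B, G, s = 5, S = 4), "1 <= s <= S")
  expect_error(step_target(B, G, s = 0, S = 4), "1 <= s <= S")
})

test_that("smooth L1 has the printed two-branch form", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(-2), 1.5)
  expect_equal(smooth_l1(c(-0.999, 1)), c(0.5 * 0.999^2, 0.5))
})

test_that("the regression loss masks background and scores the worked case", {
  B <- bbox(0, 0, 10, 10); G <- bbox(5, 0, 10, 10)
  # exact prediction: zero loss
  exact <- encode_delta(B, step_target(B, G, 1, 1))
  lt <- regression_loss(exact, B, G, s = 1, S = 1)
  expect_equal(lt$total, 0)

  # zero prediction, J = 1/3 >= 0.2: smooth_l1(0.5) = 0.125
  zero <- tibble::tibble(t_x = 0, t_y = 0, t_w = 0, t_h = 0)
  lt <- regression_loss(zero, B, G, s = 1, S = 1)
  expect_equal(lt$total, 0.125)
  expect_false(lt$per_box$background)

  # disjoint truth: background box contributes exactly zero
  far <- bbox(10, 0, 10, 10)
  lt <- regression_loss(zero, B, far, s = 1, S = 1)
  expect_equal(lt$total, 0)
  expect_true(lt$per_box$background)

  expect_error(regression_loss(zero, dplyr::bind_rows(B, B), G, 1, 1),
               "same number of rows")
})

test_that("iterating the oracle regressor telescopes onto the truth", {
  img <- matrix(0.5, 64, 64)
  set.seed(55)
  for (S in c(1, 2, 4, 8)) {
    for (k in 1:25) {
      B0 <- random_real_box(50); G <- random_real_box(50)
      traj <- iterate_regression(B0, img, regressor_oracle(G), S)
      expect_length(traj, S + 1)
      expect_equal(unlist(traj[[S + 1]][, 1:4]), unlist(G[, 1:4]),
                   tolerance = 1e-9)
    }
  }
})

test_that("the zero regressor leaves the box alone", {
  B0 <- bbox(4, 4, 10, 12)
  traj <- iterate_regression(B0, matrix(0, 32, 32), regressor_zero(), 3)
  for (t in traj) expect_equal(t[, 1:4], B0[, 1:4])
})

test_that("oracle-regressed IoU is nondecreasing along the trajectory", {
  img <- matrix(0.5, 64, 64)
  set.seed(77)
  for (k in 1:100) {
    B0 <- random_real_box(50); G <- random_real_box(50)
    traj <- iterate_regression(B0, img, regressor_oracle(G), 4)
    ious <- vapply(traj, function(b) box_jaccard(b, G), numeric(1))
    expect_true(all(diff(ious) >= -1e-12))
  }
})

test_that("regressor training is reproducible and needs usable samples", {
  ds <- generate_dataset(10, seed = 44, shadow_prob = 0)
  cfg <- pipeline_config(rng_seed = 9)
  r1 <- train_regressor(ds$samples[1:8], cfg)
  r2 <- train_regressor(ds$samples[1:8], cfg)
  probe <- ds$samples[[9]]
  B <- bbox(probe$truth_box$x + 3, probe$truth_box$y - 2,
            probe$truth_box$w, probe$truth_box$h)
  d1 <- r1$predict(probe$image, B, 1, 4)
  d2 <- r2$predict(probe$image, B, 1, 4)
  expect_identical(d1, d2)

  expect_error(train_regressor(list(), cfg), "no training samples")
  norm <- generate_dataset(3, seed = 2, normal_fraction = 1)
  expect_error(train_regressor(norm$samples, cfg), "truth box")
})
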