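make_eval_case <- function(n_good, n_bad) {
  ids <- sprintf("img%02d", seq_len(n_good + n_bad))
  truths <- dplyr::bind_rows(lapply(ids, function(id) {
    t <- bbox(10, 10, 20, 20); t$image_id <- id; t
  }))
  preds <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    p <- if (i <= n_good) bbox(11, 11, 20, 20) else bbox(40, 40, 10, 10)
    p$image_id <- ids[i]; p
  }))
  list(preds = preds, truths = truths, ids = ids)
}

test_that("the hand-counted 10-image case reproduces the printed formulas", {
  cs <- make_eval_case(6, 4)
  ev <- evaluate_detections(cs$preds, cs$truths, cs$ids)
  expect_equal(unname(ev$counts), c(6, 4, 4, 0))
  expect_equal(ev$metrics[["accuracy"]], 6 / 14)
  expect_equal(ev$metrics[["precision"]], 0.6)
  expect_equal(ev$metrics[["recall"]], 0.6)
  expect_equal(ev$metrics[["f1"]], 0.6)
})

test_that("perfect and degenerate predictions hit the boundary values", {
  cs <- make_eval_case(5, 0)
  ev <- evaluate_detections(cs$preds, cs$truths, cs$ids)
  expect_equal(ev$metrics[["accuracy"]], 1)
  expect_equal(ev$metrics[["f1"]], 1)

  # no predictions at all on truth-bearing images
  ev0 <- evaluate_detections(cs$preds[0, ], cs$truths, cs$ids)
  expect_equal(unname(ev0$counts), c(0, 0, 5, 0))
  expect_equal(ev0$metrics[["precision"]], 0)
  expect_equal(ev0$metrics[["recall"]], 0)
  expect_true("precision" %in% ev0$undefined)
})

test_that("a prediction on a normal image is a false positive; J = 0.5 is FP", {
  truths <- bbox(10, 10, 20, 20); truths$image_id <- "lesion"
  p1 <- bbox(10, 10, 20, 20); p1$image_id <- "lesion"
  p2 <- bbox(5, 5, 10, 10); p2$image_id <- "normal"
  ev <- evaluate_detections(dplyr::bind_rows(p1, p2), truths,
                            c("lesion", "normal", "normal2"))
  expect_equal(unname(ev$counts), c(1, 1, 0, 0))

  # exactly J = 0.5: "larger than 0.5" fails, so FP (and the image FN)
  half <- bbox(10, 20, 20, 20); half$image_id <- "lesion"  # J = 20x10/...
  jhalf <- box_jaccard(half, truths)
  expect_lt(abs(jhalf - 1 / 3), 1e-12)  # sanity: overlapping but low
  exact <- bbox(10, 10, 20, 10); exact$image_id <- "lesion"
  expect_equal(box_jaccard(exact, truths), 0.5)
  ev2 <- evaluate_detections(exact, truths, "lesion")
  expect_equal(unname(ev2$counts), c(0, 1, 1, 0))
})

test_that("one prediction per truth image forces FP = FN hence P = R", {
  set.seed(83)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    good <- sample(0:n, 1)
    cs <- make_eval_case(good, n - good)
    ev <- evaluate_detections(cs$preds, cs$truths, cs$ids)
    expect_equal(ev$counts[["FP"]], ev$counts[["FN"]])
    expect_equal(ev$metrics[["precision"]], ev$metrics[["recall"]])
    if (ev$metrics[["precision"]] + ev$metrics[["recall"]] > 0) {
      expect_equal(ev$metrics[["f1"]],
                   2 * ev$metrics[["precision"]] * ev$metrics[["recall"]] /
                     (ev$metrics[["precision"]] + ev$metrics[["recall"]]))
    }
    expect_true(all(ev$metrics[c("accuracy", "precision", "recall", "f1")] >= 0))
    expect_true(all(ev$metrics[c("accuracy", "precision", "recall", "f1")] <= 1))
  }
})

test_that("tidiers expose per-image and summary views", {
  cs <- make_eval_case(3, 1)
  ev <- evaluate_detections(cs$preds, cs$truths, cs$ids)
  td <- tidy(ev)
  expect_named(td, c("image_id", "iou", "outcome"))
  expect_equal(nrow(td), 4)
  gl <- glance(ev)
  expect_equal(gl$TP, 3)
  expect_equal(gl$accuracy, 3 / 5)

  expect_error(evaluate_detections(cs$preds, cs$truths, cs$ids[1:2]),
               "not in the evaluated set")
})
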