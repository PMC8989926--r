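make_map <- function(labels, img = NULL) {
  if (is.null(img)) img <- matrix(0.5, nrow(labels), ncol(labels))
  structure(list(labels = labels, n_regions = max(labels), image = img),
            class = "region_map")
}

test_that("similarity components match their closed forms", {
  # two half-frames with identical flat intensity: identical histograms
  labels <- matrix(1L, 10, 10); labels[, 6:10] <- 2L
  map <- make_map(labels)
  s <- region_similarity(1, 2, map)
  expect_equal(s$s_gray, 1)
  # jointly covering the whole image: s_size = 0
  expect_equal(s$s_size, 0)
  # two adjacent rectangles whose union is their joint bounding box
  expect_equal(s$s_fill, 1)
  expect_equal(s$total, s$s_gray + s$s_texture + s$s_size + s$s_fill)
  expect_error(region_similarity(1, 3, map), "unknown region")
  expect_error(region_similarity(2, 2, map), "distinct")
})

test_that("similarity lies in [0, 4] and is symmetric", {
  set.seed(13)
  labels <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)
  # make labels contiguous 1..4
  labels <- matrix(match(labels, sort(unique(as.vector(labels)))), 8, 8)
  map <- make_map(labels, matrix(runif(64), 8, 8))
  for (pair in list(c(1, 2), c(2, 3), c(1, 4))) {
    a <- region_similarity(pair[1], pair[2], map)
    b <- region_similarity(pair[2], pair[1], map)
    expect_equal(a$total, b$total)
    expect_gte(a$total, 0); expect_lte(a$total, 4)
  }
})

test_that("merging performs exactly n-1 merges with a full hierarchy", {
  # one region: no merges, one proposal
  res1 <- selective_search_merge(make_map(matrix(1L, 6, 6)))
  expect_equal(nrow(res1$hierarchy), 1)
  expect_equal(sum(!is.na(res1$hierarchy$parent1)), 0)
  expect_equal(nrow(res1$proposals), 1)

  # three regions: exactly 2 merges, 5 hierarchy records
  labels <- matrix(1L, 9, 9); labels[, 4:6] <- 2L; labels[, 7:9] <- 3L
  res3 <- selective_search_merge(make_map(labels,
                                          matrix(runif(81), 9, 9)))
  expect_equal(nrow(res3$hierarchy), 5)
  expect_equal(sum(!is.na(res3$hierarchy$parent1)), 2)
})

test_that("the highest-similarity pair merges first", {
  # four quadrants; two share an identical intensity, the others differ
  set.seed(17)
  labels <- matrix(1L, 10, 10)
  labels[1:5, 6:10] <- 2L; labels[6:10, 1:5] <- 3L; labels[6:10, 6:10] <- 4L
  img <- matrix(0, 10, 10)
  img[labels == 1] <- 0.2; img[labels == 2] <- 0.21  # nearly identical pair
  img[labels == 3] <- 0.6; img[labels == 4] <- 0.95
  map <- make_map(labels, img)
  # brute-force argmax over all pairwise totals
  pairs <- t(combn(4, 2))
  totals <- apply(pairs, 1, function(p)
    region_similarity(p[1], p[2], map)$total)
  best <- pairs[which.max(totals), ]
  res <- selective_search_merge(map)
  first <- res$hierarchy[5, ]  # first merged record
  expect_equal(sort(c(first$parent1, first$parent2)), sort(best))
})

test_that("the merge sequence equals a full re-scan oracle on small maps", {
  set.seed(23)
  for (k in 1:6) {
    # random contiguous-ish maps with 3..6 regions
    n <- sample(3:6, 1)
    labels <- matrix(0L, 12, 12)
    cuts <- sort(sample(2:11, n - 1))
    bounds <- c(0, cuts, 12)
    for (i in seq_len(n)) {
      labels[, (bounds[i] + 1):bounds[i + 1]] <- i
    }
    img <- matrix(runif(144), 12, 12)
    map <- make_map(labels, img)
    res <- selective_search_merge(map)
    oracle <- rescan_merge_oracle(map)
    got <- res$hierarchy[!is.na(res$hierarchy$parent1),
                         c("parent1", "parent2", "id")]
    want <- do.call(rbind, oracle$merges)
    expect_equal(unname(as.matrix(got)), unname(want))
    # boxes of every region ever existing agree too
    expect_setequal(
      paste(res$hierarchy$x, res$hierarchy$y, res$hierarchy$w,
            res$hierarchy$h),
      paste(oracle$boxes$x, oracle$boxes$y, oracle$boxes$w, oracle$boxes$h))
  }
})

test_that("propose_rois falls back to the whole frame and stays in bounds", {
  cfg <- pipeline_config()
  flat <- matrix(0.5, 40, 40)
  props <- propose_rois(flat, cfg)
  expect_equal(nrow(props), 1)
  expect_equal(unlist(props[1, 1:4], use.names = FALSE), c(0, 0, 40, 40))

  ph <- generate_phantom(phantom_config(seed = 8))
  pp <- preprocess(ph$image, cfg)
  props <- propose_rois(pp$image, cfg)
  expect_true(all(props$x >= 0 & props$y >= 0 &
                    props$x + props$w <= ncol(pp$image) &
                    props$y + props$h <= nrow(pp$image)))
  expect_true(all(props$w >= cfg$min_roi_px & props$h >= cfg$min_roi_px))
})
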