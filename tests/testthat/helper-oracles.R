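# Independent oracle implementations used to cross-check the package's
# algorithms.  These deliberately take the dumbest correct route
# (rasterization, BFS, full re-scan per round, literal loop transcription)
# and share no code with the implementations they test.

# IoU by rasterizing integer boxes onto a pixel grid
raster_jaccard <- function(a, b, grid = 64) {
  m1 <- matrix(FALSE, grid, grid); m2 <- m1
  fill <- function(m, bx) {
    rows <- seq(bx$y + 1, bx$y + bx$h); cols <- seq(bx$x + 1, bx$x + bx$w)
    m[rows, cols] <- TRUE
    m
  }
  m1 <- fill(m1, a); m2 <- fill(m2, b)
  inter <- sum(m1 & m2); uni <- sum(m1 | m2)
  inter / uni
}

random_int_box <- function(grid = 64) {
  w <- sample.int(grid - 1, 1); h <- sample.int(grid - 1, 1)
  x <- sample.int(grid - w, 1) - 1; y <- sample.int(grid - h, 1) - 1
  bbox(x, y, w, h)
}

random_real_box <- function(limit = 100) {
  bbox(runif(1, 0, limit), runif(1, 0, limit),
       runif(1, 1, limit / 2), runif(1, 1, limit / 2))
}

# BFS flood-fill hysteresis: weak pixels survive iff 8-connected to strong
bfs_hysteresis <- function(mag, low, high) {
  strong <- mag > high
  cand <- mag >= low            # strong or weak
  H <- nrow(mag); W <- ncol(mag)
  final <- strong
  queue <- which(strong)
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        q <- rr + (cc - 1) * H
        if (cand[q] && !final[q]) {
          final[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  final
}

# Full re-scan selective-search oracle: keeps the label image, merges the
# argmax pair by relabelling pixels, and recomputes every region statistic
# and every pairwise similarity from the pixels each round.
rescan_merge_oracle <- function(map) {
  labels <- map$labels
  img <- map$image
  area <- length(labels)
  seq_boxes <- list()
  merge_seq <- list()
  ids <- sort(unique(as.vector(labels)))
  next_id <- max(ids) + 1
  # record initial boxes
  for (id in ids) seq_boxes[[length(seq_boxes) + 1]] <- oracle_region_box(labels, id)
  while (length(ids) > 1) {
    best <- NULL; best_s <- -Inf
    for (ii in seq_along(ids)) {
      for (jj in seq_along(ids)) {
        if (ii < jj) {
          s <- oracle_similarity(labels, img, ids[ii], ids[jj], area)
          if (s > best_s + 1e-12) {
            best_s <- s; best <- c(ids[ii], ids[jj])
          }
        }
      }
    }
    labels[labels %in% best] <- next_id
    merge_seq[[length(merge_seq) + 1]] <- c(best, next_id)
    seq_boxes[[length(seq_boxes) + 1]] <- oracle_region_box(labels, next_id)
    ids <- c(setdiff(ids, best), next_id)
    next_id <- next_id + 1
  }
  list(merges = merge_seq, boxes = dplyr::bind_rows(seq_boxes))
}

oracle_region_box <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  bbox(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
       max(idx[, 2]) - min(idx[, 2]) + 1, max(idx[, 1]) - min(idx[, 1]) + 1)
}

# pairwise similarity recomputed from raw pixels (own binning code)
oracle_similarity <- function(labels, img, i, j, area) {
  pix_i <- img[labels == i]; pix_j <- img[labels == j]
  hist_of <- function(v) {
    b <- pmin(floor(v * 25), 24) + 1
    tabulate(b, 25) / length(v)
  }
  s_gray <- sum(pmin(hist_of(pix_i), hist_of(pix_j)))
  gf <- sobel_gradients(img)
  ori <- pmin(floor(((gf$direction %% (2 * pi)) / (2 * pi)) * 8), 7)
  mmax <- max(gf$magnitude)
  mb <- if (mmax > 0) pmin(floor(gf$magnitude / mmax * 10), 9) else
    0 * gf$magnitude
  tex <- ori * 10 + mb + 1
  tex_hist <- function(sel) tabulate(tex[sel], 80) / sum(sel)
  s_tex <- sum(pmin(tex_hist(labels == i), tex_hist(labels == j)))
  s_size <- 1 - (length(pix_i) + length(pix_j)) / area
  bi <- oracle_region_box(labels, i); bj <- oracle_region_box(labels, j)
  x0 <- min(bi$x, bj$x); y0 <- min(bi$y, bj$y)
  x1 <- max(bi$x + bi$w, bj$x + bj$w); y1 <- max(bi$y + bi$h, bj$y + bj$h)
  s_fill <- 1 - ((x1 - x0) * (y1 - y0) - length(pix_i) - length(pix_j)) / area
  s_fill <- min(max(s_fill, 0), 1)
  s_gray + s_tex + s_size + s_fill
}

# Literal transcription of the aggregation procedure: cluster around the
# image center, keep largest cluster(s), merge highest-IoU pairs
# (intersection at J >= 0.7, enclosing box at 0.5 <= J < 0.7) until one
# box remains, pick the most confident reduced box.
literal_aggregate <- function(boxes, image_shape) {
  if (nrow(boxes) == 0) return(boxes)
  jac <- function(a, b) {
    ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
    iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
    inter <- ix * iy
    inter / (a$w * a$h + b$w * b$h - inter)
  }
  ctr_x <- image_shape[2] / 2; ctr_y <- image_shape[1] / 2
  pool <- seq_len(nrow(boxes))
  dist2 <- sapply(pool, function(i) {
    (boxes$x[i] + boxes$w[i] / 2 - ctr_x)^2 +
      (boxes$y[i] + boxes$h[i] / 2 - ctr_y)^2
  })
  clusters <- list()
  while (length(pool) > 0) {
    seed <- pool[which.min(dist2[pool])]
    members <- seed; pool <- setdiff(pool, seed)
    repeat {
      grew <- FALSE
      for (b in pool) {
        hit <- FALSE
        for (m in members) if (jac(boxes[b, ], boxes[m, ]) > 0.5) hit <- TRUE
        if (hit) {
          members <- c(members, b); pool <- setdiff(pool, b); grew <- TRUE
        }
      }
      if (!grew) break
    }
    clusters[[length(clusters) + 1]] <- members
  }
  sizes <- lengths(clusters)
  finals <- list()
  for (members in clusters[sizes == max(sizes)]) {
    cl <- boxes[members, ]
    while (nrow(cl) > 1) {
      bi <- bj <- NA; bestj <- -Inf
      for (a in seq_len(nrow(cl) - 1)) for (b in (a + 1):nrow(cl)) {
        jv <- jac(cl[a, ], cl[b, ])
        if (jv > bestj + 1e-12) { bestj <- jv; bi <- a; bj <- b }
      }
      if (bestj < 0.5) {
        conf <- cl$confidence; conf[is.na(conf)] <- -Inf
        cl <- cl[-max(which(conf == min(conf))), ]
        next
      }
      a <- cl[bi, ]; b <- cl[bj, ]
      if (bestj >= 0.7) {
        nx <- max(a$x, b$x); ny <- max(a$y, b$y)
        nb <- bbox(nx, ny, min(a$x + a$w, b$x + b$w) - nx,
                   min(a$y + a$h, b$y + b$h) - ny)
      } else {
        nx <- min(a$x, b$x); ny <- min(a$y, b$y)
        nb <- bbox(nx, ny, max(a$x + a$w, b$x + b$w) - nx,
                   max(a$y + a$h, b$y + b$h) - ny)
      }
      nb$confidence <- max(a$confidence, b$confidence)
      cl <- dplyr::bind_rows(cl[-c(bi, bj), ], nb)
    }
    finals[[length(finals) + 1]] <- cl
  }
  finals <- dplyr::bind_rows(finals)
  conf <- finals$confidence; conf[is.na(conf)] <- -Inf
  top <- which(conf == max(conf))
  if (length(top) > 1) {
    d2 <- sapply(top, function(i) {
      (finals$x[i] + finals$w[i] / 2 - ctr_x)^2 +
        (finals$y[i] + finals$h[i] / 2 - ctr_y)^2
    })
    top <- top[which.min(d2)]
  }
  finals[top[1], ]
}

# random overlapping box sets for aggregation fuzzing
random_box_set <- function(n, frame = 64) {
  base <- random_int_box(frame)
  rows <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.6) {
      # perturbation of the base box: likely to overlap
      bbox(max(0, base$x + runif(1, -3, 3)),
           max(0, base$y + runif(1, -3, 3)),
           max(2, base$w * exp(runif(1, -0.2, 0.2))),
           max(2, base$h * exp(runif(1, -0.2, 0.2))),
           confidence = runif(1))
    } else {
      b <- random_int_box(frame); b$confidence <- runif(1); b
    }
  })
  dplyr::bind_rows(rows)
}

# small disc image for edge-detection checks
disc_image <- function(size = 64, radius = 20, contrast = 0.5) {
  cx <- size / 2; cy <- size / 2
  d <- sqrt((col(diag(0, size)) - 0.5 - cx)^2 +
              (row(diag(0, size)) - 0.5 - cy)^2)
  0.25 + contrast * (d <= radius)
}
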