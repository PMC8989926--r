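#' Cluster boxes by Jaccard overlap around the image center
#'
#' The first aggregation stage.  Repeatedly: seed a new cluster with the
#' unassigned box whose center is nearest the image center (Euclidean
#' distance; ties to the lowest input index), then sweep the remaining
#' boxes in input order, adding any whose Jaccard index with some current
#' member is strictly greater than `cluster_bound`; the sweep repeats until
#' a fixed point so membership is transitive and order-independent.
#' Assigned boxes leave the pool and the process continues until the pool
#' is empty.
#'
#' @param boxes Nonempty box tibble (with confidences).
#' @param image_shape `c(height, width)` of the frame.
#' @param cluster_bound Membership bound (default 0.5, strict).
#' @return A list of clusters; each cluster is a box tibble whose first
#'   row is the seed.
#' @export
cluster_boxes <- function(boxes, image_shape, cluster_bound = 0.5) {
  boxes <- as_box_tibble(boxes)
  if (nrow(boxes) == 0) abort("cannot cluster an empty box set")
  ctr <- c(image_shape[2] / 2, image_shape[1] / 2)  # (x, y)
  centers <- box_center(boxes)
  d2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2
  pool <- seq_len(nrow(boxes))
  clusters <- list()
  while (length(pool) > 0) {
    seed <- pool[which.min(d2[pool])]
    members <- seed
    pool <- setdiff(pool, seed)
    repeat {
      added <- FALSE
      for (b in pool) {
        if (any(box_jaccard(boxes[rep(b, length(members)), ],
                            boxes[members, ]) > cluster_bound)) {
          members <- c(members, b)
          pool <- setdiff(pool, b)
          added <- TRUE
        }
      }
      if (!added) break
    }
    clusters[[length(clusters) + 1]] <- boxes[members, ]
  }
  clusters
}

#' Merge one pair of overlapping boxes
#'
#' The aggregation merge rule: if `J(B1, B2) >= intersect_bound` (default
#' 0.7) the merged box is their intersection; if
#' `cluster_bound <= J < intersect_bound` it is the smallest box covering
#' both.  A pair below `cluster_bound` is not mergeable and raises an
#' error (the cluster reducer handles that case by dropping a member).
#' The merged box carries the larger of the two confidences.
#'
#' @param B1,B2 One-row box tibbles.
#' @param intersect_bound,cluster_bound Jaccard branch points (0.7 / 0.5).
#' @return One-row box tibble.
#' @examples
#' merge_pair(bbox(0, 0, 10, 10), bbox(1, 0, 10, 10))  # intersection branch
#' @export
merge_pair <- function(B1, B2, intersect_bound = 0.7, cluster_bound = 0.5) {
  j <- box_jaccard(B1, B2)
  if (j < cluster_bound) {
    abort("non-mergeable pair: Jaccard index below the cluster bound")
  }
  out <- if (j >= intersect_bound) box_intersect(B1, B2) else
    box_enclose(B1, B2)
  out$confidence <- max(B1$confidence, B2$confidence, na.rm = FALSE)
  out
}

#' Reduce a cluster to a single box
#'
#' Repeatedly merges the member pair with the largest Jaccard index (via
#' [merge_pair()]) until one box remains.  Intersection merges can shrink
#' boxes enough that no remaining pair reaches the cluster bound; in that
#' unspecified regime the member with the lowest confidence is dropped
#' (ties to the latest-entered member) and reduction continues, which
#' guarantees termination.
#'
#' @param cluster Nonempty box tibble.
#' @param intersect_bound,cluster_bound Jaccard branch points (0.7 / 0.5).
#' @return One-row box tibble.
#' @export
reduce_cluster <- function(cluster, intersect_bound = 0.7,
                           cluster_bound = 0.5) {
  cl <- as_box_tibble(cluster)
  if (nrow(cl) == 0) abort("cannot reduce an empty cluster")
  while (nrow(cl) > 1) {
    J <- box_jaccard_matrix(cl, cl)
    diag(J) <- -Inf
    J[lower.tri(J)] <- -Inf
    if (max(J) < cluster_bound) {
      conf <- cl$confidence
      conf[is.na(conf)] <- -Inf
      drop <- max(which(conf == min(conf)))
      cl <- cl[-drop, , drop = FALSE]
      next
    }
    best <- which(J == max(J), arr.ind = TRUE)[1, ]  # first pair column-major

    merged <- merge_pair(cl[best[1], ], cl[best[2], ],
                         intersect_bound, cluster_bound)
    cl <- dplyr::bind_rows(cl[-c(best[1], best[2]), , drop = FALSE], merged)
  }
  cl
}

#' Aggregate regressed boxes into one detection
#'
#' The full post-processing stage: cluster the boxes around the image
#' center ([cluster_boxes()]), keep the cluster(s) of maximal size, reduce
#' each to a single box ([reduce_cluster()]), and return the reduced box
#' with the highest confidence (ties to the box nearest the image center).
#' An empty input returns an empty box tibble — the designed output for a
#' normal image.
#'
#' @param boxes Box tibble (possibly 0 rows) with confidences.
#' @param image_shape `c(height, width)`.
#' @param cfg A [pipeline_config()] supplying the Jaccard bounds.
#' @return A one-row box tibble, or a 0-row tibble when `boxes` is empty.
#' @export
aggregate_boxes <- function(boxes, image_shape, cfg = pipeline_config()) {
  boxes <- as_box_tibble(boxes)
  if (nrow(boxes) == 0) return(boxes)
  clusters <- cluster_boxes(boxes, image_shape, cfg$cluster_jaccard)
  sizes <- vapply(clusters, nrow, integer(1))
  top <- clusters[sizes == max(sizes)]
  reduced <- dplyr::bind_rows(lapply(top, reduce_cluster,
                                     intersect_bound = cfg$intersect_jaccard,
                                     cluster_bound = cfg$cluster_jaccard))
  conf <- reduced$confidence
  conf[is.na(conf)] <- -Inf
  cand <- which(conf == max(conf))
  if (length(cand) > 1) {
    ctr <- c(image_shape[2] / 2, image_shape[1] / 2)
    centers <- box_center(reduced[cand, ])
    d2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2
    cand <- cand[which.min(d2)]
  }
  reduced[cand[1], ]
}
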