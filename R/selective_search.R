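## Per-region statistics backing the selective-search similarities:
## size (pixel count), L1-normalized 25-bin intensity histogram,
## L1-normalized 8-orientation x 10-magnitude gradient (texture) histogram,
## and the region bounding box.  Histograms of a merged region are the
## size-weighted averages of its parents, as in canonical selective search.
region_statistics <- function(map) {
  img <- map$image
  labels <- map$labels
  n <- map$n_regions
  lab_vec <- as.vector(labels)
  sizes <- tabulate(lab_vec, nbins = n)

  # 25-bin intensity histogram over [0, 1]
  gray_bin <- pmin(floor(as.vector(img) * 25), 24) + 1L
  hg <- matrix(0, 25, n)
  idx <- (lab_vec - 1L) * 25L + gray_bin
  tab <- tabulate(idx, nbins = 25L * n)
  hg[] <- tab
  hg <- sweep(hg, 2, sizes, "/")

  # texture: Sobel gradient orientation (8 sectors, full circle) x
  # magnitude (10 bins over the image's magnitude range)
  gf <- sobel_gradients(img)
  ori <- floor(((gf$direction %% (2 * pi)) / (2 * pi)) * 8)
  ori <- pmin(ori, 7)
  mmax <- max(gf$magnitude)
  mag_bin <- if (mmax > 0) pmin(floor(gf$magnitude / mmax * 10), 9) else
    matrix(0, nrow(img), ncol(img))
  tex_bin <- as.vector(ori * 10 + mag_bin) + 1L  # 1..80
  ht <- matrix(0, 80, n)
  idx <- (lab_vec - 1L) * 80L + tex_bin
  tab <- tabulate(idx, nbins = 80L * n)
  ht[] <- tab
  ht <- sweep(ht, 2, sizes, "/")

  # bounding boxes (0-based, half-open)
  rows <- row(labels); cols <- col(labels)
  r0 <- tapply(as.vector(rows), lab_vec, min)
  r1 <- tapply(as.vector(rows), lab_vec, max)
  c0 <- tapply(as.vector(cols), lab_vec, min)
  c1 <- tapply(as.vector(cols), lab_vec, max)
  boxes <- cbind(x = c0 - 1, y = r0 - 1, w = c1 - c0 + 1, h = r1 - r0 + 1)

  list(sizes = sizes, hist_gray = hg, hist_texture = ht, boxes = boxes)
}

## similarity of region j (columns of stats) against a single region's
## stats; fully vectorized.  Returns a 4 x m matrix (gray, texture, size,
## fill).
similarity_components <- function(size_i, hg_i, ht_i, box_i,
                                  sizes, hg, ht, boxes, image_area) {
  s_gray <- colSums(pmin(hg, hg_i))  # matrix first so dims survive recycling
  s_tex <- colSums(pmin(ht, ht_i))
  s_size <- 1 - (size_i + sizes) / image_area
  bx0 <- pmin(box_i[1], boxes[, 1])
  by0 <- pmin(box_i[2], boxes[, 2])
  bx1 <- pmax(box_i[1] + box_i[3], boxes[, 1] + boxes[, 3])
  by1 <- pmax(box_i[2] + box_i[4], boxes[, 2] + boxes[, 4])
  bb_area <- (bx1 - bx0) * (by1 - by0)
  s_fill <- 1 - (bb_area - size_i - sizes) / image_area
  s_fill <- pmin(pmax(s_fill, 0), 1)
  rbind(gray = s_gray, texture = s_tex, size = s_size, fill = s_fill)
}

#' Selective-search similarity between two regions
#'
#' The four-component similarity driving region agglomeration:
#' `s_gray` and `s_texture` are histogram intersections of the regions'
#' normalized 25-bin intensity and 8x10 gradient-texture histograms;
#' `s_size = 1 - (|i| + |j|) / image_area` favours merging small regions
#' first; `s_fill = 1 - (area(BB_ij) - |i| - |j|) / image_area` (clamped to
#' `[0, 1]`) favours pairs whose union fills its joint bounding box.
#' `total` is their plain sum, in `[0, 4]`.
#'
#' @param i,j Distinct region labels present in `map`.
#' @param map A `"region_map"` from [initial_segmentation()].
#' @param image_area Denominator for the size/fill terms; defaults to the
#'   map's own pixel count.
#' @return A one-row tibble with `s_gray`, `s_texture`, `s_size`, `s_fill`,
#'   `total`.
#' @export
region_similarity <- function(i, j, map, image_area = length(map$labels)) {
  if (i == j) abort("region similarity needs two distinct regions")
  st <- region_statistics(map)
  n <- length(st$sizes)
  if (i < 1 || j < 1 || i > n || j > n) abort("unknown region id")
  s <- similarity_components(st$sizes[i], st$hist_gray[, i],
                             st$hist_texture[, i], st$boxes[i, ],
                             st$sizes[j], st$hist_gray[, j, drop = FALSE],
                             st$hist_texture[, j, drop = FALSE],
                             st$boxes[j, , drop = FALSE], image_area)
  tibble(s_gray = s[1, 1], s_texture = s[2, 1], s_size = s[3, 1],
         s_fill = s[4, 1], total = sum(s[, 1]))
}

#' Greedy selective-search agglomeration
#'
#' Merges the initial regions down to a single region: similarities are
#' computed for every region pair (not only adjacent ones), the
#' highest-similarity pair is merged into a new region, similarities
#' involving the merged pair are discarded, similarities of the new region
#' against all survivors are added, and the loop repeats until the
#' similarity set is empty — exactly `n - 1` merges for `n` initial
#' regions.  Argmax ties break to the lexicographically lowest id pair and
#' a merged region gets id `max(existing) + 1`, so the hierarchy is fully
#' deterministic.
#'
#' @param map A `"region_map"`.
#' @param image_area Area denominator for size/fill similarities.
#' @return A list: `hierarchy`, a tibble with one row per region that ever
#'   existed (`id`, `parent1`, `parent2` (`NA` for initial regions),
#'   `size`, `x`, `y`, `w`, `h`), and `proposals`, the deduplicated
#'   bounding boxes of all those regions.
#' @export
selective_search_merge <- function(map, image_area = length(map$labels)) {
  st <- region_statistics(map)
  n <- length(st$sizes)
  n_tot <- 2 * n - 1
  sizes <- numeric(n_tot); sizes[1:n] <- st$sizes
  hg <- matrix(0, 25, n_tot); hg[, 1:n] <- st$hist_gray
  ht <- matrix(0, 80, n_tot); ht[, 1:n] <- st$hist_texture
  boxes <- matrix(0, n_tot, 4); boxes[1:n, ] <- st$boxes
  parents <- matrix(NA_integer_, n_tot, 2)
  active <- c(rep(TRUE, n), rep(FALSE, max(n_tot - n, 0)))

  # S[j, i] = total similarity of pair (i, j), i < j; column-major scan of
  # this layout visits pairs in (i, j) lexicographic order, so which.max's
  # first-hit rule is the documented tie-break.
  S <- matrix(-Inf, n_tot, n_tot)
  fill_sims <- function(i, against) {
    if (length(against) == 0) return(NULL)
    s <- similarity_components(sizes[i], hg[, i], ht[, i], boxes[i, ],
                               sizes[against], hg[, against, drop = FALSE],
                               ht[, against, drop = FALSE],
                               boxes[against, , drop = FALSE], image_area)
    colSums(s)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ag <- (i + 1):n
      S[ag, i] <- fill_sims(i, ag)
    }
  }

  for (t in seq_len(n - 1) + n - 1) {
    k <- which.max(S)
    j <- (k - 1) %% n_tot + 1
    i <- (k - 1) %/% n_tot + 1
    new_id <- t + 1  # ids n+1 .. 2n-1, i.e. max existing + 1
    tot <- sizes[i] + sizes[j]
    hg[, new_id] <- (sizes[i] * hg[, i] + sizes[j] * hg[, j]) / tot
    ht[, new_id] <- (sizes[i] * ht[, i] + sizes[j] * ht[, j]) / tot
    sizes[new_id] <- tot
    boxes[new_id, ] <- c(
      min(boxes[i, 1], boxes[j, 1]),
      min(boxes[i, 2], boxes[j, 2]),
      max(boxes[i, 1] + boxes[i, 3], boxes[j, 1] + boxes[j, 3]) -
        min(boxes[i, 1], boxes[j, 1]),
      max(boxes[i, 2] + boxes[i, 4], boxes[j, 2] + boxes[j, 4]) -
        min(boxes[i, 2], boxes[j, 2])
    )
    parents[new_id, ] <- c(i, j)
    active[c(i, j)] <- FALSE
    S[, c(i, j)] <- -Inf
    S[c(i, j), ] <- -Inf
    active[new_id] <- TRUE
    ag <- which(active[seq_len(new_id - 1)])
    if (length(ag) > 0) S[new_id, ag] <- fill_sims(new_id, ag)
  }

  ids <- seq_len(n_tot)
  hierarchy <- tibble(
    id = ids,
    parent1 = parents[, 1], parent2 = parents[, 2],
    size = sizes[ids],
    x = boxes[ids, 1], y = boxes[ids, 2],
    w = boxes[ids, 3], h = boxes[ids, 4]
  )
  props <- dplyr::distinct(hierarchy[, c("x", "y", "w", "h")])
  props$confidence <- NA_real_
  list(hierarchy = hierarchy, proposals = props)
}

#' Region-of-interest proposal
#'
#' The unsupervised proposal chain: Canny edge detection, initial
#' oversegmentation of the non-edge components, greedy selective-search
#' agglomeration, then the deduplicated bounding boxes of every region the
#' hierarchy ever contained.  The edge map is thickened by
#' `cfg$edge_dilate` rounds of dilation first so that speckle-induced
#' one-pixel contour gaps do not fuse a closed structure with the
#' background.  Boxes smaller than `cfg$min_roi_px` on either
#' side or covering more than `cfg$max_roi_frac` of the frame are dropped
#' as redundant; if that filter removes everything (a featureless image
#' yields only the whole frame), the whole-frame box is returned so every
#' image has at least one candidate.
#'
#' @param img Preprocessed (normalized, clipped) intensity matrix.
#' @param cfg A [pipeline_config()].
#' @return A box tibble of proposals, all within the image bounds.
#' @export
propose_rois <- function(img, cfg = pipeline_config()) {
  edges <- canny(img, cfg)$final
  for (k in seq_len(cfg$edge_dilate)) edges <- dilate8(edges)
  map <- initial_segmentation(img, edges)
  res <- selective_search_merge(map)
  props <- res$proposals
  keep <- props$w >= cfg$min_roi_px & props$h >= cfg$min_roi_px &
    props$w * props$h <= cfg$max_roi_frac * length(img)
  out <- props[keep, ]
  if (nrow(out) == 0) {
    out <- bbox(0, 0, ncol(img), nrow(img))
  }
  as_box_tibble(out)
}
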