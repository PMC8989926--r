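## Connected-component labelling of a logical mask by iterative
## minimum-label propagation; returns an integer matrix, 0 outside the
## mask, labels renumbered 1..n in row-major order of first occurrence.
label_components <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(Inf, H, W)
  lab[mask] <- which(mask)  # unique seed per pixel (column-major index)
  pad_shift <- function(m, dr, dc) {
    out <- matrix(Inf, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    nl <- lab
    for (o in offs) nl <- pmin(nl, pad_shift(lab, o[1], o[2]))
    nl[!mask] <- Inf
    if (identical(nl, lab)) break
    lab <- nl
  }
  out <- matrix(0L, H, W)
  if (any(mask)) {
    # renumber deterministically by row-major first occurrence
    rm_order <- as.vector(t(lab))
    seen <- unique(rm_order[is.finite(rm_order)])
    out[mask] <- match(lab[mask], seen)
  }
  out
}

#' Initial oversegmentation from an edge map
#'
#' Deterministic starting partition for selective search: the connected
#' components of the non-edge pixels become regions, and each edge pixel is
#' then assigned to its nearest component (layered 8-neighborhood growth,
#' i.e. chessboard distance; ties resolved to the lowest label), so every
#' pixel ends up labelled.  Components use 4-connectivity deliberately:
#' thinned edge contours are 8-connected curves, and by the standard
#' connectivity duality an 8-connected closed curve separates the plane
#' only for 4-connected regions — with 8-connected regions the inside of a
#' thin contour would leak through its diagonal steps into the outside.
#' An empty edge map yields a single region covering the image.
#'
#' @param img Intensity matrix (retained alongside the labels for the
#'   similarity statistics).
#' @param edges An `"edge_map"` from [canny()], or a logical matrix of edge
#'   pixels.
#' @return A list of class `"region_map"`: `labels` (integer matrix,
#'   partitioning the image), `n_regions`, and `image`.
#' @export
initial_segmentation <- function(img, edges) {
  edge <- if (inherits(edges, "edge_map")) edges$final else edges > 0
  if (!all(dim(edge) == dim(img))) abort("edge map and image shapes differ")
  H <- nrow(img); W <- ncol(img)
  if (all(edge)) {
    # degenerate: everything is edge; one region
    labels <- matrix(1L, H, W)
    return(structure(list(labels = labels, n_regions = 1L, image = img),
                     class = "region_map"))
  }
  labels <- label_components(!edge, connectivity = 4)
  # grow labels into edge pixels, one chessboard layer at a time,
  # minimum label wins within a layer
  while (any(labels == 0L)) {
    lf <- matrix(Inf, H, W)
    lf[labels > 0L] <- labels[labels > 0L]
    best <- matrix(Inf, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- matrix(Inf, H, W)
      rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
      ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
      out[ok_r, ok_c] <- lf[rs[ok_r], cs[ok_c]]
      best <- pmin(best, out)
    }
    newly <- labels == 0L & is.finite(best)
    labels[newly] <- as.integer(best[newly])
  }
  structure(
    list(labels = labels, n_regions = max(labels), image = img),
    class = "region_map"
  )
}
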