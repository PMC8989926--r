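#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF into a numeric matrix of intensities in
#' `[0, 1]` (rows are image rows, top first).  Multi-channel input is
#' collapsed to its channel mean; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format '.", ext, "' (use PNG or TIFF)"))
  )
  if (length(dim(px)) == 3) {
    nch <- dim(px)[3]
    if (nch == 2 || nch == 4) nch <- nch - 1  # drop alpha
    px <- apply(px[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  px
}

#' Read a binary lesion mask
#'
#' Masks follow the published ground-truth convention: 8-bit PNG with
#' foreground strictly greater than zero.
#'
#' @param path Path to a PNG (or TIFF) mask.
#' @return A logical matrix, `TRUE` on lesion pixels.
#' @export
read_mask <- function(path) {
  read_gray_image(path) > 0
}

#' Write a grayscale image
#'
#' @param img Numeric matrix; values are clamped to `[0, 1]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}

#' Write and read detection records
#'
#' Detections are serialized as a JSON array of records
#' `{image_id, x, y, w, h, confidence}`, one record per box, so a detection
#' table round-trips exactly: `read_detections(write_detections(d, p))`
#' equals `d`.  An empty table writes a valid empty file.  On read, records
#' violating the box invariants (`w <= 0`, `h <= 0`, non-finite coordinates,
#' confidence outside `[0, 1]`) are rejected with an error.
#'
#' @param detections A tibble with columns `image_id`, `x`, `y`, `w`, `h`
#'   and optionally `confidence`.
#' @param path File path for the JSON records (for [write_detections_csv()],
#'   a CSV with header `image_id,x,y,w,h,confidence`).
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns the detection tibble.
#' @export
write_detections <- function(detections, path) {
  detections <- as_tibble(detections)
  if (!"image_id" %in% names(detections)) {
    abort("detections need an 'image_id' column")
  }
  if (!"confidence" %in% names(detections)) {
    detections$confidence <- NA_real_
  }
  if (nrow(detections) > 0) validate_boxes(detections)
  cols <- c("image_id", "x", "y", "w", "h", "confidence")
  jsonlite::write_json(detections[cols], path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) abort(paste0("detection file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) {
    return(tibble(image_id = character(), x = numeric(), y = numeric(),
                  w = numeric(), h = numeric(), confidence = numeric()))
  }
  raw <- as_tibble(raw)
  need <- c("image_id", "x", "y", "w", "h")
  if (!all(need %in% names(raw))) {
    abort("malformed detection file: records need image_id, x, y, w, h")
  }
  if (!"confidence" %in% names(raw)) raw$confidence <- NA_real_
  raw$image_id <- as.character(raw$image_id)
  for (cl in c("x", "y", "w", "h", "confidence")) {
    raw[[cl]] <- as.numeric(raw[[cl]])
  }
  validate_boxes(raw)
  raw[c("image_id", "x", "y", "w", "h", "confidence")]
}

#' @rdname write_detections
#' @export
write_detections_csv <- function(detections, path) {
  detections <- as_tibble(detections)
  if (!"confidence" %in% names(detections)) detections$confidence <- NA_real_
  cols <- c("image_id", "x", "y", "w", "h", "confidence")
  write.csv(detections[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
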