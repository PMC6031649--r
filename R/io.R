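#' Read a TIFF or PNG image
#'
#' @param path image path (`.tif`, `.tiff` or `.png`; 8/16-bit, 1-3
#'   channels).
#' @return A numeric matrix (single channel) or an H x W x 3 array, values
#'   in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else if (dim(img)[3] == 2L) img <- img[, , 1L]  # grey + extra channel
    else if (dim(img)[3] > 3L) img <- img[, , 1:3]
  }
  img
}

#' Write / read a label image as single-channel 16-bit TIFF
#'
#' Labels are stored as 16-bit grey values (so at most 65535 objects per
#' image).
#'
#' @param labels a [label_image()].
#' @param path output path.
#' @return `write_label_image()` returns `path` invisibly;
#'   `read_label_image()` returns a [label_image()].
#' @export
write_label_image <- function(labels, path) {
  stopifnot(inherits(labels, "label_image"))
  if (max(labels$labels) > 65535L)
    stop("more than 65535 objects; cannot store as 16-bit", call. = FALSE)
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_image
#' @param image_id identifier for the read label image.
#' @param pixel_scale micrometres per pixel for the read label image.
#' @export
read_label_image <- function(path, image_id = "image", pixel_scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  label_image(matrix(as.integer(round(m * 65535)), nrow(m)),
              image_id, pixel_scale)
}
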