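#' Label image container
#'
#' A label image is an integer matrix aligned with its source image in which
#' 0 marks background and each positive integer marks the pixels of one
#' segmented object (a nucleus, a cell, or a superpixel). Labels are kept as
#' a contiguous set 1..N; use [relabel_sequential()] to restore this after
#' filtering.
#'
#' @param labels integer matrix, non-negative; 0 is background.
#' @param image_id character scalar identifying the source image.
#' @param pixel_scale physical pixel size in micrometres per pixel.
#' @return An object of class `label_image` with fields `labels`, `image_id`
#'   and `pixel_scale`.
#' @export
label_image <- function(labels, image_id = "image", pixel_scale = 1) {
  if (!is.matrix(labels)) stop("`labels` must be a 2-D matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0)
    stop("`pixel_scale` must be a positive scalar (um/px)", call. = FALSE)
  structure(
    list(labels = labels, image_id = as.character(image_id)[1L],
         pixel_scale = as.numeric(pixel_scale)),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  n <- n_objects(x)
  cat(sprintf("<label_image> '%s': %d x %d px, %d object%s, %.4g um/px\n",
              x$image_id, nrow(x$labels), ncol(x$labels), n,
              if (n == 1L) "" else "s", x$pixel_scale))
  invisible(x)
}

#' Number of objects in a label image
#' @param x a `label_image`.
#' @return Integer count of distinct positive labels.
#' @export
n_objects <- function(x) {
  stopifnot(inherits(x, "label_image"))
  length(setdiff(unique(as.vector(x$labels)), 0L))
}

#' Relabel objects to the contiguous set 1..N
#'
#' Keeps object identity but renames labels so the positive IDs are exactly
#' 1..N in increasing order of the original IDs. The old-to-new mapping is
#' returned so object-level metadata can be carried across.
#'
#' @param x a `label_image` (or a bare integer matrix).
#' @return A list with `labels` (the relabelled `label_image`) and `map`, a
#'   named integer vector mapping old label -> new label (empty for an empty
#'   label image).
#' @export
relabel_sequential <- function(x) {
  bare <- !inherits(x, "label_image")
  m <- if (bare) x else x$labels
  old <- sort(setdiff(unique(as.vector(m)), 0L))
  map <- seq_along(old)
  names(map) <- old
  if (length(old)) {
    lut <- integer(max(old) + 1L)          # lut[old + 1] -> new
    lut[old + 1L] <- map
    m <- matrix(lut[m + 1L], nrow = nrow(m))
  }
  out <- if (bare) label_image(m) else label_image(m, x$image_id, x$pixel_scale)
  list(labels = out, map = map)
}

# areas of each label as a named integer vector (names = label IDs)
label_areas <- function(m) {
  v <- as.vector(m)
  tab <- tabulate(v[v > 0L])
  keep <- which(tab > 0L)
  stats::setNames(tab[keep], keep)
}

#' Convert a pixel distance to micrometres
#'
#' @param d distance(s) in pixels, non-negative.
#' @param pixel_scale micrometres per pixel, positive.
#' @return `d * pixel_scale`, in micrometres.
#' @examples
#' pixels_to_microns(800, 0.390250)  # 312.2
#' pixels_to_microns(50, 0.27)       # 13.5
#' @export
pixels_to_microns <- function(d, pixel_scale) {
  if (any(d < 0)) stop("pixel distances must be non-negative", call. = FALSE)
  if (pixel_scale <= 0) stop("`pixel_scale` must be positive", call. = FALSE)
  d * pixel_scale
}
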