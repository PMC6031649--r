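#' Object centroids from a label image
#'
#' The centre of mass of each segmented area (unweighted mean of member
#' pixel coordinates; intensity plays no role). Coordinates are pixel-based,
#' origin top-left, 0-based, row-major; centroids may be fractional.
#'
#' @param labels a [label_image()] with at least one object.
#' @return data.frame with `object_id`, `centroid_row`, `centroid_col`,
#'   ordered by object ID.
#' @export
compute_centroids <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  m <- labels$labels
  idx <- which(m > 0L)
  if (!length(idx)) stop("label image has no objects", call. = FALSE)
  lab <- m[idx]
  r <- (idx - 1L) %% nrow(m)        # 0-based row
  cc <- (idx - 1L) %/% nrow(m)      # 0-based col
  cr <- rowsum(r, lab); ccol <- rowsum(cc, lab); n <- rowsum(rep(1L, length(idx)), lab)
  data.frame(object_id = as.integer(rownames(cr)),
             centroid_row = cr[, 1] / n[, 1],
             centroid_col = ccol[, 1] / n[, 1],
             row.names = NULL)
}

# lattice points of the bounding box lying inside the convex hull of the
# object's pixel centres (boundary inclusive); pts is a 2-col matrix (r, c)
.hull_pixel_count <- function(pts) {
  if (nrow(pts) <= 2L) return(nrow(pts))
  hull <- grDevices::chull(pts)
  v <- pts[hull, , drop = FALSE]
  k <- nrow(v)
  if (k <= 2L) return(nrow(unique(pts))) # collinear object
  grid <- as.matrix(expand.grid(r = min(pts[, 1]):max(pts[, 1]),
                                c = min(pts[, 2]):max(pts[, 2])))
  nxt <- c(2:k, 1L)
  inside <- rep(TRUE, nrow(grid))
  for (e in seq_len(k)) {
    p1 <- v[e, ]; p2 <- v[nxt[e], ]
    cr <- (p2[1] - p1[1]) * (grid[, 2] - p1[2]) -
          (p2[2] - p1[2]) * (grid[, 1] - p1[1])
    inside <- inside & (cr <= 1e-9)   # chull vertices are clockwise
  }
  sum(inside)
}

.haralick_names <- c("asm", "con", "cor", "var", "idm", "sav", "sva",
                     "sen", "ent", "dva", "den", "f12", "f13")

#' Regular (per-object) features from images and a label image
#'
#' Computes the package's canonical regular feature set for every object:
#' a shape block (pixel and physical area, perimeter, eccentricity,
#' solidity, extent, major/minor axis length, circularity = 4*pi*A/P^2) and,
#' per channel, an intensity block (mean, standard deviation, median, min,
#' max, integrated) and a texture block (13 grey-level co-occurrence
#' statistics at distance 1, averaged over 4 directions, on intensities
#' requantized to `bins` grey levels within the object).
#'
#' Degenerate cases are mapped to finite conventions: a 1-pixel object has
#' perimeter 0 and circularity 1; undefined statistics (e.g. correlation of
#' a constant patch, eccentricity of a point) are set to 0. No NaN/Inf
#' leaves this function.
#'
#' @param channels a numeric matrix or a named list of numeric matrices,
#'   one per channel, each the same shape as `labels`.
#' @param labels a [label_image()] with labels 1..N.
#' @param bins number of grey levels for the co-occurrence quantization.
#' @return A [feature_table()] with provenance `regular` for every feature.
#' @export
extract_regular_features <- function(channels, labels, bins = 32) {
  stopifnot(inherits(labels, "label_image"))
  if (is.matrix(channels)) channels <- list(ch1 = channels)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels))
  for (ch in channels)
    if (!is.matrix(ch) || !all(dim(ch) == dim(labels$labels)))
      stop("every channel must match the label image shape", call. = FALSE)
  m <- labels$labels
  ids <- sort(setdiff(unique(as.vector(m)), 0L))
  if (!length(ids)) stop("label image has no objects", call. = FALSE)
  if (!identical(ids, seq_along(ids)))
    stop("labels must be sequential 1..N; run relabel_sequential()", call. = FALSE)
  n <- length(ids)
  scale <- labels$pixel_scale

  cen <- compute_centroids(labels)
  sh <- EBImage::computeFeatures.shape(m)
  mo <- EBImage::computeFeatures.moment(m)
  area <- sh[, "s.area"]
  perim <- sh[, "s.perimeter"]
  ecc <- mo[, "m.eccentricity"]; ecc[!is.finite(ecc)] <- 0
  major <- mo[, "m.majoraxis"]; major[!is.finite(major)] <- 0
  minor <- major * sqrt(pmax(0, 1 - ecc^2))

  idx_by_obj <- split(which(m > 0L), m[m > 0L])
  solidity <- extent <- numeric(n)
  for (i in seq_len(n)) {
    px <- idx_by_obj[[as.character(i)]]
    pts <- cbind((px - 1L) %% nrow(m), (px - 1L) %/% nrow(m))
    hull_n <- .hull_pixel_count(pts)
    solidity[i] <- if (hull_n > 0) min(1, area[i] / hull_n) else 1
    bbox <- (diff(range(pts[, 1])) + 1L) * (diff(range(pts[, 2])) + 1L)
    extent[i] <- area[i] / bbox
  }
  # 1-px objects (and zero perimeters) take circularity 1 by convention
  circ <- ifelse(perim > 0 & area > 1, 4 * pi * area / perim^2, 1)

  out <- data.frame(
    image_id = labels$image_id, object_id = cen$object_id,
    centroid_row = cen$centroid_row, centroid_col = cen$centroid_col,
    area_px = as.numeric(area), area_um2 = area * scale^2,
    perimeter = as.numeric(perim), eccentricity = ecc,
    solidity = solidity, extent = extent,
    major_axis = as.numeric(major), minor_axis = as.numeric(minor),
    circularity = circ, row.names = NULL)

  for (chn in names(channels)) {
    ch <- channels[[chn]]
    vals <- split(ch[m > 0L], m[m > 0L])
    vals <- vals[as.character(seq_len(n))]
    int_block <- t(vapply(vals, function(v) c(
      mean(v), if (length(v) > 1L) stats::sd(v) else 0,
      stats::median(v), min(v), max(v), sum(v)), numeric(6)))
    colnames(int_block) <- paste0(chn, "_int_",
                                  c("mean", "std", "median", "min", "max",
                                    "integrated"))
    rng <- range(ch)
    ref <- (ch - rng[1]) / max(diff(rng), .Machine$double.eps)
    har <- EBImage::computeFeatures.haralick(m, ref, haralick.nbins = bins,
                                             haralick.scales = 1)
    har <- har[, seq_len(13L), drop = FALSE]
    har[!is.finite(har)] <- 0
    colnames(har) <- paste0(chn, "_tex_", .haralick_names)
    out <- cbind(out, int_block, har)
  }
  rownames(out) <- NULL
  feature_table(out, pixel_scale = scale)
}
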