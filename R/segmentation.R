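#' Nuclei segmentation configuration
#'
#' @param min_object_size minimum equivalent-circle diameter in micrometres;
#'   smaller objects are discarded (default 5 um).
#' @param drop_border drop objects touching the image border (default TRUE).
#' @param threshold_method only `"adaptive_otsu"` is implemented: an Otsu
#'   threshold per local block, bilinearly interpolated between block
#'   centres.
#' @param pixel_scale micrometres per pixel.
#' @param block_size side of the local thresholding block in pixels.
#' @return A `nuclei_config` list.
#' @export
nuclei_config <- function(min_object_size = 5, drop_border = TRUE,
                          threshold_method = c("adaptive_otsu"),
                          pixel_scale = 1, block_size = 50) {
  threshold_method <- match.arg(threshold_method)
  if (min_object_size <= 0) stop("`min_object_size` must be > 0", call. = FALSE)
  if (pixel_scale <= 0) stop("`pixel_scale` must be > 0", call. = FALSE)
  if (block_size < 2) stop("`block_size` must be >= 2", call. = FALSE)
  structure(list(min_object_size = min_object_size, drop_border = drop_border,
                 threshold_method = threshold_method,
                 pixel_scale = pixel_scale, block_size = block_size),
            class = "nuclei_config")
}

#' SLIC superpixel configuration
#'
#' `size` is the nominal linear spacing of the superpixel grid in pixels
#' (e.g. 35 px corresponds to 9.45 um at 0.27 um/px). `min_region` is a
#' pixel-area threshold: after clustering, any connected region smaller than
#' it is merged into an adjacent region ("connectivity enforcement"). For
#' the canonical sizes 25/35/50/75/100 the default minimum regions are
#' 20/25/40/60/75 px; otherwise 75% of `size`, rounded.
#'
#' @param size nominal superpixel spacing in pixels, >= 2.
#' @param compactness trade-off between colour similarity and spatial
#'   proximity (larger = more regular shapes); default 10.
#' @param min_region minimum region size in pixels (area), >= 1 and
#'   < `size^2`.
#' @param pixel_scale micrometres per pixel.
#' @param iterations number of assignment/update sweeps (default 10).
#' @return A `slic_config` list.
#' @export
slic_config <- function(size, compactness = 10, min_region = NULL,
                        pixel_scale = 1, iterations = 10) {
  if (size < 2) stop("`size` must be >= 2", call. = FALSE)
  if (is.null(min_region)) {
    canonical <- c("25" = 20, "35" = 25, "50" = 40, "75" = 60, "100" = 75)
    min_region <- if (as.character(size) %in% names(canonical))
      unname(canonical[as.character(size)]) else max(1, round(0.75 * size))
  }
  if (min_region < 1) stop("`min_region` must be >= 1", call. = FALSE)
  if (min_region >= size^2) stop("`min_region` must be < size^2", call. = FALSE)
  if (compactness <= 0) stop("`compactness` must be > 0", call. = FALSE)
  if (pixel_scale <= 0) stop("`pixel_scale` must be > 0", call. = FALSE)
  structure(list(size = size, compactness = compactness,
                 min_region = min_region, pixel_scale = pixel_scale,
                 iterations = iterations),
            class = "slic_config")
}

# Otsu threshold of a numeric vector via 256-bin between-class variance,
# on the vector's own range. Returns NA for (near-)constant input.
.otsu_threshold <- function(v, eps = 1e-8) {
  rng <- range(v)
  if (diff(rng) < eps) return(NA_real_)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - rng[1]) / diff(rng) * nb)), nbins = nb)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w1 <- cumsum(w)
  mu1 <- cumsum(w * mids)
  mu_t <- mu1[nb]
  bc <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

# Block-wise Otsu threshold map, bilinearly interpolated between block
# centres; low-contrast blocks fall back to the global threshold.
.adaptive_otsu_map <- function(img, block_size) {
  h <- nrow(img); w <- ncol(img)
  nbr <- max(1L, floor(h / block_size))
  nbc <- max(1L, floor(w / block_size))
  blocks <- function(n, k) split(seq_len(n), if (k == 1L) rep(1L, n)
                                 else cut(seq_len(n), k, labels = FALSE))
  rb <- blocks(h, nbr)
  cb <- blocks(w, nbc)
  thr <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc))
    thr[i, j] <- .otsu_threshold(as.vector(img[rb[[i]], cb[[j]]]))
  global <- .otsu_threshold(as.vector(img))
  if (is.na(global)) global <- mean(img) # fully flat image: nothing segments
  thr[is.na(thr)] <- global
  if (nbr == 1L && nbc == 1L) return(matrix(thr[1, 1], h, w))
  rc <- vapply(rb, function(ix) mean(ix), 0)
  cc <- vapply(cb, function(ix) mean(ix), 0)
  interp1 <- function(centres, vals, out) {
    if (length(centres) == 1L) return(rep(vals, length(out)))
    stats::approx(centres, vals, xout = out, rule = 2)$y
  }
  # interpolate along columns for each block-row, then along rows
  rows_interp <- t(apply(thr, 1L, interp1, centres = cc, out = seq_len(w)))
  if (nbr == 1L) rows_interp <- matrix(rows_interp, nrow = 1L)
  apply(rows_interp, 2L, interp1, centres = rc, out = seq_len(h))
}

# drop labels touching the border of an integer label matrix
.drop_border_labels <- function(m) {
  edge <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  edge <- setdiff(edge, 0L)
  if (length(edge)) m[m %in% edge] <- 0L
  m
}

#' Segment nuclei from a DNA-channel image
#'
#' Thresholds the image with a block-wise adaptive Otsu map, labels
#' connected foreground components, removes border-touching objects (when
#' `drop_border`) and objects with equivalent-circle diameter below
#' `min_object_size` micrometres, then relabels sequentially.
#'
#' @param image a single-channel numeric matrix (any intensity range).
#' @param cfg a [nuclei_config()].
#' @param image_id identifier recorded in the output.
#' @return A [label_image()]; empty (0 objects) when nothing is found.
#' @export
segment_nuclei <- function(image, cfg = nuclei_config(), image_id = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a single-channel numeric matrix", call. = FALSE)
  stopifnot(inherits(cfg, "nuclei_config"))
  thr <- .adaptive_otsu_map(image, cfg$block_size)
  bw <- image > thr
  if (!any(bw))
    return(label_image(matrix(0L, nrow(image), ncol(image)), image_id,
                       cfg$pixel_scale))
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(image))
  if (cfg$drop_border) lab <- .drop_border_labels(lab)
  areas <- label_areas(lab)
  if (length(areas)) {
    eq_diam_um <- 2 * sqrt(areas / pi) * cfg$pixel_scale
    small <- as.integer(names(areas))[eq_diam_um < cfg$min_object_size]
    if (length(small)) lab[lab %in% small] <- 0L
  }
  res <- relabel_sequential(label_image(lab, image_id, cfg$pixel_scale))
  res$labels
}

#' Segment cytoplasm around nuclei seeds
#'
#' Adaptive thresholding of the cytoplasm channel followed by seeded region
#' growing from the nuclei (CellProfiler-style watershed on intensity with
#' nuclei as seed points): every cytoplasm region carries the label of its
#' seed nucleus, contains that nucleus, and contested foreground between two
#' seeds is split between them.
#'
#' @param image cytoplasm-channel numeric matrix, same shape as the nuclei
#'   label image.
#' @param nuclei a [label_image()] of seed nuclei with at least one object.
#' @param cfg a [nuclei_config()] (the thresholding parameters are reused).
#' @return A [label_image()] with the same label IDs as `nuclei`.
#' @export
segment_cytoplasm <- function(image, nuclei, cfg = nuclei_config()) {
  stopifnot(inherits(nuclei, "label_image"))
  if (!is.matrix(image) || !all(dim(image) == dim(nuclei$labels)))
    stop("`image` must match the nuclei label image shape", call. = FALSE)
  if (n_objects(nuclei) == 0L)
    stop("`nuclei` must contain at least one seed object", call. = FALSE)
  thr <- .adaptive_otsu_map(image, cfg$block_size)
  mask <- (image > thr) | (nuclei$labels > 0L)  # seed containment guaranteed
  lab <- EBImage::propagate(image, seeds = nuclei$labels, mask = mask,
                            lambda = 1e-4)
  label_image(matrix(as.integer(lab), nrow(image)), nuclei$image_id,
              nuclei$pixel_scale)
}

# connected components (4-connectivity) of an integer assignment map,
# treating each distinct value separately; returns an integer matrix 1..M
.components_of_assignment <- function(assign) {
  comp <- matrix(0L, nrow(assign), ncol(assign))
  offset <- 0L
  for (k in sort(unique(as.vector(assign)))) {
    lab <- EBImage::bwlabel(assign == k)
    lab <- matrix(as.integer(lab), nrow(assign))
    sel <- lab > 0L
    comp[sel] <- lab[sel] + offset
    offset <- offset + max(lab)
  }
  comp
}

# boundary-pair contact counts between adjacent components (4-connectivity)
.component_contacts <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  a <- c(comp[-h, ], comp[, -w])
  b <- c(comp[-1, ], comp[, -1])
  sel <- a != b
  if (!any(sel)) return(NULL)
  pair <- cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  key <- paste(pair[, 1], pair[, 2])
  cnt <- table(key)
  ids <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  data.frame(a = as.integer(ids[, 1]), b = as.integer(ids[, 2]),
             n = as.integer(cnt))
}

#' SLIC superpixel segmentation
#'
#' Grid-seeded k-means in joint colour-position space: pixels are clustered
#' by intensity (CIELAB for 3-channel images, scaled intensity for
#' grayscale) and spatial proximity, with the compactness parameter
#' weighting the spatial term. Seeding is a deterministic regular grid (no
#' randomness). After clustering, connectivity is enforced: each connected
#' fragment smaller than `cfg$min_region` pixels is merged into the adjacent
#' region it shares the longest boundary with, so the output is a partition
#' of the image into regions of at least `min_region` pixels.
#'
#' @param image a numeric matrix (grayscale) or an H x W x 3 array (RGB,
#'   values in \[0, 1\]).
#' @param cfg a [slic_config()].
#' @param image_id identifier recorded in the output.
#' @return A [label_image()] whose positive labels 1..N partition the image.
#' @export
slic_superpixels <- function(image, cfg, image_id = "image") {
  stopifnot(inherits(cfg, "slic_config"))
  if (is.matrix(image)) {
    h <- nrow(image); w <- ncol(image)
    col <- list(100 * (image - min(image)) /
                  max(diff(range(image)), .Machine$double.eps))
  } else if (length(dim(image)) == 3L && dim(image)[3] == 3L) {
    h <- dim(image)[1]; w <- dim(image)[2]
    lab3 <- grDevices::convertColor(cbind(as.vector(image[, , 1]),
                                          as.vector(image[, , 2]),
                                          as.vector(image[, , 3])),
                                    from = "sRGB", to = "Lab")
    col <- lapply(1:3, function(i) matrix(lab3[, i], h, w))
  } else stop("`image` must be a matrix or an H x W x 3 array", call. = FALSE)
  S <- cfg$size
  if (S^2 > h * w) stop("superpixel size too large for this image", call. = FALSE)

  nr <- max(1L, round(h / S)); nc <- max(1L, round(w / S))
  cen_r <- (seq_len(nr) - 0.5) * h / nr
  cen_c <- (seq_len(nc) - 0.5) * w / nc
  centres <- cbind(r = rep(cen_r, times = nc), c = rep(cen_c, each = nr))
  K <- nrow(centres)
  cen_col <- do.call(cbind, lapply(col, function(ch)
    ch[cbind(pmax(1L, pmin(h, round(centres[, 1]))),
             pmax(1L, pmin(w, round(centres[, 2]))))]))

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m2s2 <- (cfg$compactness / S)^2
  assign <- matrix(0L, h, w)

  for (it in seq_len(cfg$iterations)) {
    best <- matrix(Inf, h, w)
    for (k in seq_len(K)) {
      r0 <- max(1L, floor(centres[k, 1] - S)); r1 <- min(h, ceiling(centres[k, 1] + S))
      c0 <- max(1L, floor(centres[k, 2] - S)); c1 <- min(w, ceiling(centres[k, 2] + S))
      d2 <- m2s2 * ((rows[r0:r1, c0:c1] - centres[k, 1])^2 +
                    (cols[r0:r1, c0:c1] - centres[k, 2])^2)
      for (i in seq_along(col))
        d2 <- d2 + (col[[i]][r0:r1, c0:c1] - cen_col[k, i])^2
      sel <- d2 < best[r0:r1, c0:c1]
      if (any(sel)) {
        sub <- assign[r0:r1, c0:c1]; sub[sel] <- k
        assign[r0:r1, c0:c1] <- sub
        subb <- best[r0:r1, c0:c1]; subb[sel] <- d2[sel]
        best[r0:r1, c0:c1] <- subb
      }
    }
    # pixels out of every window (possible on ragged grids): nearest centre
    if (any(assign == 0L)) {
      miss <- which(assign == 0L, arr.ind = TRUE)
      for (ii in seq_len(nrow(miss))) {
        d <- (centres[, 1] - miss[ii, 1])^2 + (centres[, 2] - miss[ii, 2])^2
        assign[miss[ii, 1], miss[ii, 2]] <- which.min(d)
      }
    }
    if (it < cfg$iterations) {
      idx <- as.vector(assign)
      cnt <- tabulate(idx, nbins = K)
      nzk <- cnt > 0L
      centres[nzk, 1] <- rowsum(as.vector(rows), idx)[, 1] / cnt[nzk]
      centres[nzk, 2] <- rowsum(as.vector(cols), idx)[, 1] / cnt[nzk]
      for (i in seq_along(col))
        cen_col[nzk, i] <- rowsum(as.vector(col[[i]]), idx)[, 1] / cnt[nzk]
    }
  }

  comp <- .components_of_assignment(assign)
  comp <- .merge_small_regions(comp, cfg$min_region)
  res <- relabel_sequential(label_image(comp, image_id, cfg$pixel_scale))
  res$labels
}

# merge connected regions smaller than min_region into the adjacent region
# sharing the longest boundary (ties: smallest label), until none remain.
# Works in passes: contacts are computed once per pass and merges within a
# pass are chained through union-find, so heavily fragmented assignments
# (thousands of tiny regions) stay tractable.
.merge_small_regions <- function(comp, min_region) {
  repeat {
    areas_v <- label_areas(comp)
    if (length(areas_v) <= 1L) break
    ids <- as.integer(names(areas_v))
    if (!any(areas_v < min_region)) break
    contacts <- .component_contacts(comp)
    if (is.null(contacts)) break
    n_id <- max(ids)
    parent <- seq_len(n_id)
    area <- integer(n_id); area[ids] <- as.integer(areas_v)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    small <- ids[order(areas_v, ids)]
    small <- small[area[small] < min_region]
    for (target in small) {
      rt <- find(target)
      if (rt != target || area[rt] >= min_region) next
      tc <- contacts[contacts$a == target | contacts$b == target, ,
                     drop = FALSE]
      if (!nrow(tc)) next # isolated region: nothing adjacent to merge into
      nbrs <- ifelse(tc$a == target, tc$b, tc$a)
      roots <- vapply(nbrs, find, 0L)
      keep <- roots != rt
      if (!any(keep)) next
      wt <- rowsum(tc$n[keep], roots[keep])
      cand <- as.integer(rownames(wt))
      into <- cand[order(-wt[, 1], cand)][1L]
      parent[rt] <- into
      area[into] <- area[into] + area[rt]
    }
    lut <- vapply(seq_len(n_id), find, 0L)
    new <- matrix(lut[comp], nrow(comp))
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}
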