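#' Parameters for the culture-like generator
#'
#' Emulates a drug-screen cell-culture regime: scattered cells placed by a
#' parent-offspring (Neyman-Scott) clustered point process, class labels
#' spatially autocorrelated within clusters, class-conditional Gaussian
#' feature distributions, nine phenotype classes plus a debris class, and a
#' deliberately confusable class pair whose feature means are pulled
#' together by `overlap`. Each cluster's minority cells are drawn
#' preferentially from a class-specific companion class, so the composition
#' of a cell's neighbourhood carries information its own features do not.
#'
#' @param n_images number of images.
#' @param image_size c(H, W) in pixels.
#' @param pixel_scale micrometres per pixel (default 0.390250, the culture
#'   scale at which 800 px = 312.2 um).
#' @param n_classes number of classes including debris.
#' @param cells_per_image Poisson mean cell count per image.
#' @param clusters_per_image Poisson mean parent (cluster) count per image.
#' @param sigma_cluster parent-offspring dispersion in pixels.
#' @param p_same probability a cell takes its cluster's dominant class.
#' @param treatment_strength probability a cluster's dominant class equals
#'   the image-level dominant phenotype. Each image emulates one field of a
#'   treated well, whose perturbation shifts the phenotype composition of
#'   the whole field; this is what keeps very large neighbourhoods
#'   informative in cultures.
#' @param context_strength weight of the dominant class's companion among
#'   the cluster's minority cells.
#' @param n_features number of regular features (>= n_classes).
#' @param effect_size distance scale between class feature means.
#' @param confusable_pair indices of the two confusable classes.
#' @param overlap fraction in \[0, 1\] of the confusable pair's mean
#'   separation that is removed (1 = identical means).
#' @param annotate_n number of cells to annotate (sampled over all images).
#' @param seed integer seed; the single source of randomness.
#' @return A `culture_sim_params` list.
#' @export
culture_sim_params <- function(n_images = 20, image_size = c(520, 520),
                               pixel_scale = 0.390250, n_classes = 10,
                               cells_per_image = 150, clusters_per_image = 6,
                               sigma_cluster = 120, p_same = 0.75,
                               treatment_strength = 0.85,
                               context_strength = 0.7, n_features = 10,
                               effect_size = 2.2, confusable_pair = c(1, 2),
                               overlap = 0.85, annotate_n = 1500, seed = 1) {
  if (overlap < 0 || overlap > 1) stop("`overlap` must be in [0, 1]",
                                       call. = FALSE)
  if (cells_per_image <= 0 || n_images < 1)
    stop("densities/counts must be positive", call. = FALSE)
  if (n_features < n_classes)
    stop("`n_features` must be >= `n_classes`", call. = FALSE)
  if (p_same < 0 || p_same > 1) stop("`p_same` must be in [0, 1]",
                                     call. = FALSE)
  class_names <- c("abundant", "rounded", "elongated", "multinucleated",
                   "bundled_microtubule", "peripheral_cytoskeleton",
                   "punctate_actin_foci", "decreased_cell_size",
                   "fragmented_nucleus", "debris")
  class_names <- if (n_classes <= length(class_names))
    class_names[seq_len(n_classes)] else
    c(class_names, paste0("class_", seq_len(n_classes - length(class_names))))
  structure(as.list(environment()), class = "culture_sim_params")
}

# class-mean matrix: one coordinate per class at `effect_size`, with the
# confusable pair's means pulled together by `overlap`
.class_means <- function(n_classes, n_features, effect_size, pair, overlap) {
  mu <- matrix(0, n_classes, n_features)
  mu[cbind(seq_len(n_classes), seq_len(n_classes))] <- effect_size
  a <- pair[1]; b <- pair[2]
  mu[b, ] <- mu[a, ] + (1 - overlap) * (mu[b, ] - mu[a, ])
  mu
}

#' Simulate a culture-like dataset
#'
#' Places cells with a Neyman-Scott clustered point process and draws their
#' regular features from class-conditional Gaussians (see
#' [culture_sim_params()]). The feature table is generated directly from
#' the statistical model (the fast path used by the classification
#' machinery); with `render = TRUE`, per-image DNA/actin channel images and
#' matching label images of class-dependent discs are rendered as well, for
#' exercising the segmentation and feature-extraction stages.
#'
#' @param params a [culture_sim_params()].
#' @param render also render intensity images and label images.
#' @return A list with `table` (ground-truth [feature_table()]), `truth`
#'   (all cells: `image_id`, `object_id`, `class`, `cluster`),
#'   `annotations` (the annotated subset), `params`, and when rendering
#'   `images` (list of per-image channel lists) and `labels` (list of
#'   [label_image()]).
#' @export
simulate_culture <- function(params, render = FALSE) {
  stopifnot(inherits(params, "culture_sim_params"))
  p <- params
  h <- p$image_size[1]; w <- p$image_size[2]
  max_r <- 12
  if (p$cells_per_image * (2 * max_r)^2 > 0.85 * h * w)
    stop("infeasible cell density: expected footprint exceeds packing limit",
         call. = FALSE)
  mu <- .class_means(p$n_classes, p$n_features, p$effect_size,
                     p$confusable_pair, p$overlap)
  companion <- ((seq_len(p$n_classes) + 1L) %% p$n_classes) + 1L

  out <- .with_seed(p$seed, {
    rows <- vector("list", p$n_images)
    for (im in seq_len(p$n_images)) {
      n_par <- max(1L, stats::rpois(1, p$clusters_per_image))
      par_pos <- cbind(stats::runif(n_par, 0, h - 1),
                       stats::runif(n_par, 0, w - 1))
      img_dom <- sample.int(p$n_classes, 1L)
      par_cls <- ifelse(stats::runif(n_par) < p$treatment_strength, img_dom,
                        sample.int(p$n_classes, n_par, replace = TRUE))
      n_cell <- stats::rpois(1, p$cells_per_image)
      if (n_cell == 0L) next
      pa <- sample.int(n_par, n_cell, replace = TRUE)
      pos <- par_pos[pa, , drop = FALSE] +
        matrix(stats::rnorm(2 * n_cell, 0, p$sigma_cluster), ncol = 2)
      pos[, 1] <- pmin(pmax(pos[, 1], 0), h - 1)
      pos[, 2] <- pmin(pmax(pos[, 2], 0), w - 1)
      dom <- par_cls[pa]
      take_dom <- stats::runif(n_cell) < p$p_same
      cls <- dom
      for (i in which(!take_dom)) {
        wgt <- rep((1 - p$context_strength) / (p$n_classes - 2L), p$n_classes)
        wgt[dom[i]] <- 0
        wgt[companion[dom[i]]] <- p$context_strength
        cls[i] <- sample.int(p$n_classes, 1L, prob = wgt)
      }
      feats <- mu[cls, , drop = FALSE] +
        matrix(stats::rnorm(n_cell * p$n_features), n_cell)
      colnames(feats) <- sprintf("feat_%02d", seq_len(p$n_features))
      rows[[im]] <- data.frame(image_id = sprintf("culture_%02d", im),
                               object_id = seq_len(n_cell),
                               centroid_row = pos[, 1], centroid_col = pos[, 2],
                               cluster = pa, class = p$class_names[cls],
                               feats, row.names = NULL)
    }
    df <- do.call(rbind, rows)
    ann_ix <- sample.int(nrow(df), min(p$annotate_n, nrow(df)))
    list(df = df, ann_ix = sort(ann_ix))
  })
  df <- out$df
  tab <- feature_table(df[setdiff(names(df), c("cluster", "class"))],
                       pixel_scale = p$pixel_scale)
  truth <- df[c("image_id", "object_id", "class", "cluster")]
  res <- list(table = tab, truth = truth,
              annotations = truth[out$ann_ix, c("image_id", "object_id",
                                                "class")],
              params = p, mode = "culture")
  if (render) {
    rend <- .render_culture(df, p)
    res$images <- rend$images
    res$labels <- rend$labels
  }
  res
}

# render class-dependent discs into DNA/actin channels + label image
.render_culture <- function(df, p) {
  h <- p$image_size[1]; w <- p$image_size[2]
  cls_ix <- match(df$class, p$class_names)
  radius <- 9 + (cls_ix %% 3L) * 2
  radius[df$class == "debris"] <- 3
  dna_lvl <- 0.45 + 0.04 * cls_ix
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  images <- labels <- list()
  for (im in unique(df$image_id)) {
    sel <- which(df$image_id == im)
    dna <- matrix(0.05, h, w); act <- matrix(0.05, h, w)
    lab <- matrix(0L, h, w)
    for (i in sel) {
      d2 <- (rows - (df$centroid_row[i] + 1))^2 +
            (cols - (df$centroid_col[i] + 1))^2
      disc <- d2 <= radius[i]^2
      lab[disc] <- df$object_id[i]
      dna[disc] <- dna_lvl[i]
      act[d2 <= (radius[i] + 3)^2] <- 0.35 + 0.02 * (cls_ix[i] %% 5L)
    }
    images[[im]] <- list(dna = dna, actin = act)
    labels[[im]] <- label_image(lab, im, p$pixel_scale)
  }
  list(images = images, labels = labels)
}

#' Parameters for the tissue-like generator
#'
#' Emulates an HE-stained tissue section: each image is partitioned into a
#' few macro-domains (tumour-like or connective-like), each domain into
#' Voronoi regions of one tissue component each, drawn from the domain's
#' composition profile. Superpixel-level objects are laid out on a regular
#' grid of the requested SLIC size; their features are the footprint's
#' type-fraction mixture of class feature means plus Gaussian within-type
#' noise. Below `cell_scale` a superpixel covers only a fragment of a cell,
#' whose appearance can resemble a different component: its expected
#' features are pulled a random amount (growing as the size shrinks) toward
#' a random other class mean. Above `cell_scale` several components fall
#' into one footprint, so the type mixture itself blurs the features. The
#' two mechanisms make feature quality best at `cell_scale`, mirroring how
#' segmentation granularity behaves on real sections. The confusable pair
#' (cancer cell and
#' fibroblast) has *identical* feature means — only the surrounding
#' composition separates them, because cancer superpixels sit among lumen
#' and endothelium while fibroblasts sit among stroma and smooth muscle.
#'
#' @param n_images number of images.
#' @param image_size c(H, W) in pixels.
#' @param pixel_scale micrometres per pixel (default 0.27, the tissue scale
#'   at which 35 px = 9.45 um).
#' @param n_domains macro-domains (Voronoi seeds) per image.
#' @param n_regions tissue regions (Voronoi seeds) per image; must be >=
#'   the number of region types.
#' @param cell_scale the superpixel size (px) at which features are
#'   cleanest (the generator's "cell size"); default 35.
#' @param n_features number of regular features.
#' @param effect_size distance scale between class feature means.
#' @param sigma_feat within-type feature noise standard deviation.
#' @param annotate_n number of superpixels to annotate per SLIC size.
#' @param seed integer seed.
#' @return A `tissue_sim_params` list.
#' @export
tissue_sim_params <- function(n_images = 20, image_size = c(480, 480),
                              pixel_scale = 0.27, n_domains = 4,
                              n_regions = 16, cell_scale = 35,
                              n_features = 10, effect_size = 2.5,
                              sigma_feat = 1, annotate_n = 1200, seed = 1) {
  class_names <- c("cancer_cell", "lumen", "endothelial_cell",
                   "lymphocyte_plasma_cell", "fibroblast_fibrocyte",
                   "stroma", "smooth_muscle", "lipocyte", "debris")
  if (n_regions < length(class_names) / 2)
    stop("`n_regions` too small for the type vocabulary", call. = FALSE)
  if (n_domains < 2) stop("need at least 2 domains", call. = FALSE)
  profiles <- list(
    tumour = c(cancer_cell = 0.45, lumen = 0.25, endothelial_cell = 0.15,
               lymphocyte_plasma_cell = 0.10, debris = 0.05),
    connective = c(fibroblast_fibrocyte = 0.45, stroma = 0.25,
                   smooth_muscle = 0.15, lipocyte = 0.10, debris = 0.05))
  structure(as.list(environment()), class = "tissue_sim_params")
}

# per-image spatial model: domain seeds with contexts, region seeds with types
.tissue_image_model <- function(p) {
  h <- p$image_size[1]; w <- p$image_size[2]
  dom_pos <- cbind(stats::runif(p$n_domains, 0, h - 1),
                   stats::runif(p$n_domains, 0, w - 1))
  ctx <- rep_len(c("tumour", "connective"), p$n_domains)[
    sample.int(p$n_domains)]
  reg_pos <- cbind(stats::runif(p$n_regions, 0, h - 1),
                   stats::runif(p$n_regions, 0, w - 1))
  dd <- outer(reg_pos[, 1], dom_pos[, 1], "-")^2 +
        outer(reg_pos[, 2], dom_pos[, 2], "-")^2
  reg_dom <- max.col(-dd)
  reg_type <- vapply(seq_len(p$n_regions), function(r) {
    prof <- p$profiles[[ctx[reg_dom[r]]]]
    sample(names(prof), 1L, prob = prof)
  }, "")
  list(reg_pos = reg_pos, reg_type = reg_type)
}

# type index of the nearest region seed for a set of points (n x 2)
.tissue_type_at <- function(model, pts, class_names) {
  dd <- outer(pts[, 1], model$reg_pos[, 1], "-")^2 +
        outer(pts[, 2], model$reg_pos[, 2], "-")^2
  match(model$reg_type[max.col(-dd)], class_names)
}

#' Simulate a tissue-like dataset
#'
#' Generates superpixel-level feature tables and annotations at one or more
#' SLIC sizes from a shared spatial model per image (see
#' [tissue_sim_params()]); the spatial model, not the size, is what the
#' seed fixes, so tables at different sizes describe the same virtual
#' tissue. With `render = TRUE`, HE-like RGB images and pixel-wise
#' ground-truth type maps are rendered for the segmentation path.
#'
#' @param params a [tissue_sim_params()].
#' @param sizes SLIC sizes (px) at which to emit tables; default the
#'   params' `cell_scale`.
#' @param render also render RGB images and ground-truth type maps.
#' @return A list with `tables`, `truth` and `annotations` (named lists,
#'   one entry per size; truth has `image_id`, `object_id`, `class`,
#'   `purity`), `params`, and when rendering `images` (H x W x 3 arrays)
#'   and `type_maps` (integer matrices indexing `params$class_names`).
#' @export
simulate_tissue <- function(params, sizes = NULL, render = FALSE) {
  stopifnot(inherits(params, "tissue_sim_params"))
  p <- params
  if (is.null(sizes)) sizes <- p$cell_scale
  h <- p$image_size[1]; w <- p$image_size[2]
  nc <- length(p$class_names)
  mu <- .class_means(nc, p$n_features, p$effect_size,
                     match(c("cancer_cell", "fibroblast_fibrocyte"),
                           p$class_names), overlap = 1)

  .with_seed(p$seed, {
    models <- replicate(p$n_images, .tissue_image_model(p), simplify = FALSE)
    sub <- as.matrix(expand.grid(u = seq(-0.4, 0.4, length.out = 5),
                                 v = seq(-0.4, 0.4, length.out = 5)))
    tables <- truth <- annotations <- list()
    for (s in sizes) {
      nr <- floor(h / s); ncg <- floor(w / s)
      off_r <- (h - nr * s) / 2; off_c <- (w - ncg * s) / 2
      cen <- as.matrix(expand.grid(
        r = off_r + (seq_len(nr) - 0.5) * s - 0.5,
        c = off_c + (seq_len(ncg) - 0.5) * s - 0.5))
      # below the cell scale a superpixel sees a cell fragment whose
      # appearance can resemble another type: its expected features are
      # pulled toward a random other class mean, increasingly so the
      # further below the cell scale the superpixel is
      frag_max <- max(0, 1 - (s / p$cell_scale)^2)
      rows <- vector("list", p$n_images)
      for (im in seq_len(p$n_images)) {
        n_obj <- nrow(cen)
        frac <- matrix(0, n_obj, nc)
        for (k in seq_len(nrow(sub))) {
          pts <- cbind(cen[, 1] + sub[k, 1] * s, cen[, 2] + sub[k, 2] * s)
          t_ix <- .tissue_type_at(models[[im]], pts, p$class_names)
          frac[cbind(seq_len(n_obj), t_ix)] <-
            frac[cbind(seq_len(n_obj), t_ix)] + 1
        }
        frac <- frac / nrow(sub)
        maj <- max.col(frac, ties.method = "first")
        mean_mat <- frac %*% mu
        if (frag_max > 0) {
          # a fragment either sits in a homogeneous part of its cell
          # (features intact) or straddles a compartment that mimics
          # another component (features substantially replaced)
          hit <- stats::runif(n_obj) < frag_max
          gam <- ifelse(hit, stats::runif(n_obj, 0.5, 1), 0)
          rnd <- sample.int(nc, n_obj, replace = TRUE)
          mean_mat <- (1 - gam) * mean_mat + gam * mu[rnd, , drop = FALSE]
        }
        feats <- mean_mat +
          matrix(stats::rnorm(n_obj * p$n_features, 0, p$sigma_feat), n_obj)
        colnames(feats) <- sprintf("feat_%02d", seq_len(p$n_features))
        rows[[im]] <- data.frame(
          image_id = sprintf("tissue_%02d", im), object_id = seq_len(n_obj),
          centroid_row = cen[, 1], centroid_col = cen[, 2],
          class = p$class_names[maj],
          purity = frac[cbind(seq_len(n_obj), maj)], feats,
          row.names = NULL)
      }
      df <- do.call(rbind, rows)
      key <- as.character(s)
      tables[[key]] <- feature_table(
        df[setdiff(names(df), c("class", "purity"))],
        pixel_scale = p$pixel_scale)
      truth[[key]] <- df[c("image_id", "object_id", "class", "purity")]
      ann_ix <- sort(sample.int(nrow(df), min(p$annotate_n, nrow(df))))
      annotations[[key]] <- df[ann_ix, c("image_id", "object_id", "class")]
    }
    res <- list(tables = tables, truth = truth, annotations = annotations,
                params = p, mode = "tissue")
    if (render) {
      palette <- cbind(
        r = c(0.85, 0.95, 0.75, 0.45, 0.80, 0.90, 0.70, 0.95, 0.30),
        g = c(0.45, 0.90, 0.55, 0.40, 0.60, 0.75, 0.45, 0.85, 0.30),
        b = c(0.75, 0.95, 0.70, 0.70, 0.80, 0.85, 0.60, 0.70, 0.30))
      res$images <- res$type_maps <- vector("list", p$n_images)
      pix <- as.matrix(expand.grid(r = seq_len(h) - 1, c = seq_len(w) - 1))
      for (im in seq_len(p$n_images)) {
        t_ix <- .tissue_type_at(models[[im]], pix, p$class_names)
        tm <- matrix(t_ix, h, w)
        img <- array(0, c(h, w, 3))
        for (ch in 1:3) {
          noisy <- matrix(palette[t_ix, ch], h, w) +
            stats::rnorm(h * w, 0, 0.04)
          # optics: PSF smoothing makes noise spatially correlated
          noisy <- as.matrix(EBImage::gblur(noisy, sigma = 1.5))
          img[, , ch] <- pmin(1, pmax(0, noisy))
        }
        res$type_maps[[im]] <- tm
        res$images[[im]] <- img
      }
      names(res$images) <- names(res$type_maps) <-
        sprintf("tissue_%02d", seq_len(p$n_images))
    }
    res
  })
}

#' Annotate superpixels by majority ground-truth type
#'
#' @param labels a [label_image()] of superpixels.
#' @param type_map integer matrix of ground-truth types (same shape).
#' @param class_names character vector the type indices refer to.
#' @return data.frame `image_id`, `object_id`, `class`.
#' @export
annotate_superpixels <- function(labels, type_map, class_names) {
  stopifnot(inherits(labels, "label_image"),
            all(dim(type_map) == dim(labels$labels)))
  m <- labels$labels
  sel <- m > 0L
  tab <- table(label = m[sel], type = type_map[sel])
  maj <- apply(tab, 1L, which.max)
  data.frame(image_id = labels$image_id,
             object_id = as.integer(rownames(tab)),
             class = class_names[as.integer(colnames(tab))[maj]],
             row.names = NULL)
}

#' Write a simulated dataset to disk
#'
#' Writes the ground-truth and annotation CSVs, the feature table(s), any
#' rendered images (TIFF) and label images (16-bit TIFF), and a
#' `manifest.json` recording the generating parameters and seed, so the
#' fixture can be regenerated byte-identically.
#'
#' @param dataset a list from [simulate_culture()] or [simulate_tissue()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
emit_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character()
  wr <- function(x, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(x), f, row.names = FALSE)
    paths <<- c(paths, f)
  }
  if (!is.null(dataset$table)) wr(dataset$table, "feature_table.csv")
  if (!is.null(dataset$tables))
    for (s in names(dataset$tables))
      wr(dataset$tables[[s]], sprintf("feature_table_size%s.csv", s))
  if (is.data.frame(dataset$annotations)) wr(dataset$annotations,
                                             "annotations.csv")
  if (is.list(dataset$annotations) && !is.data.frame(dataset$annotations))
    for (s in names(dataset$annotations))
      wr(dataset$annotations[[s]], sprintf("annotations_size%s.csv", s))
  if (!is.null(dataset$truth)) {
    if (is.data.frame(dataset$truth)) wr(dataset$truth, "ground_truth.csv")
    else for (s in names(dataset$truth))
      wr(dataset$truth[[s]], sprintf("ground_truth_size%s.csv", s))
  }
  for (im in names(dataset$images)) {
    img <- dataset$images[[im]]
    f <- file.path(out_dir, paste0(im, ".tif"))
    if (is.list(img)) img <- simplify2array(img)
    tiff::writeTIFF(img, f, bits.per.sample = 16L)
    paths <- c(paths, f)
  }
  for (im in names(dataset$labels)) {
    f <- file.path(out_dir, paste0(im, "_labels.tif"))
    tiff::writeTIFF(dataset$labels[[im]]$labels / 65535, f,
                    bits.per.sample = 16L)
    paths <- c(paths, f)
  }
  mf <- file.path(out_dir, "manifest.json")
  par <- dataset$params
  jsonlite::write_json(list(mode = dataset$mode,
                            params = par[setdiff(names(par), "class_names")],
                            class_names = par$class_names),
                       mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, mf)
  invisible(paths)
}
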