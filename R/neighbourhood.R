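#' Neighbourhood selection configuration
#'
#' Two selection rules are supported, both on Euclidean distances between
#' object centroids and both confined to objects of the same image:
#' `knn` takes the K nearest objects (distance ties broken by ascending
#' object ID); `radius` takes every object whose centroid lies within a
#' fixed pixel radius `n` (boundary inclusive). The focal object is excluded
#' from its own neighbourhood unless `include_self = TRUE`.
#'
#' @param method `"knn"` or `"radius"`.
#' @param K number of nearest neighbours (knn only), >= 1.
#' @param n radius in pixels (radius only), > 0.
#' @param pixel_scale micrometres per pixel (used only for reporting
#'   physical distances, e.g. via [pixels_to_microns()]).
#' @param include_self whether the focal object joins its own
#'   neighbourhood (default FALSE).
#' @return A `neighbourhood_config` list.
#' @export
neighbourhood_config <- function(method = c("knn", "radius"), K = NULL,
                                 n = NULL, pixel_scale = 1,
                                 include_self = FALSE) {
  method <- match.arg(method)
  if (method == "knn") {
    if (is.null(K) || K < 1 || K != round(K))
      stop("knn requires integer `K` >= 1", call. = FALSE)
    if (!is.null(n)) stop("`n` is not used by the knn method", call. = FALSE)
  } else {
    if (is.null(n) || n <= 0) stop("radius requires `n` > 0", call. = FALSE)
    if (!is.null(K)) stop("`K` is not used by the radius method", call. = FALSE)
  }
  structure(list(method = method, K = if (method == "knn") as.integer(K),
                 n = if (method == "radius") as.numeric(n),
                 pixel_scale = pixel_scale, include_self = include_self),
            class = "neighbourhood_config")
}

.check_centroid_table <- function(tab) {
  req <- c("image_id", "object_id", "centroid_row", "centroid_col")
  if (!all(req %in% names(tab)))
    stop("need columns ", paste(req, collapse = ", "), call. = FALSE)
  as.data.frame(tab)[req]
}

# shared kernel: per-image distance matrix -> long neighbour records
.select_neighbours <- function(tab, selector) {
  tab <- .check_centroid_table(tab)
  parts <- split(seq_len(nrow(tab)), tab$image_id)
  recs <- vector("list", length(parts))
  for (p in seq_along(parts)) {
    ix <- parts[[p]]
    ids <- tab$object_id[ix]
    d <- as.matrix(stats::dist(cbind(tab$centroid_row[ix],
                                     tab$centroid_col[ix])))
    img_rec <- vector("list", length(ix))
    for (i in seq_along(ix)) {
      sel <- selector(d[i, ], i, ids)
      img_rec[[i]] <- if (length(sel)) data.frame(
        image_id = tab$image_id[ix[i]], object_id = ids[i],
        neighbour_id = ids[sel], distance = d[i, sel], rank = seq_along(sel),
        row.names = NULL) else NULL
    }
    recs[[p]] <- do.call(rbind, img_rec)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(image_id = character(), object_id = integer(),
                      neighbour_id = integer(), distance = numeric(),
                      rank = integer())
  rownames(out) <- NULL
  out
}

.neighbour_sets <- function(records, tab, cfg) {
  tab <- .check_centroid_table(tab)
  structure(list(records = records,
                 objects = tab[c("image_id", "object_id")],
                 config = cfg),
            class = "neighbour_sets")
}

#' @export
print.neighbour_sets <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<neighbour_sets> %s (%s): %d objects, %d neighbour links\n",
              cfg$method,
              if (cfg$method == "knn") paste0("K=", cfg$K)
              else paste0("n=", cfg$n, " px"),
              nrow(x$objects), nrow(x$records)))
  invisible(x)
}

#' K-nearest-neighbour selection
#'
#' For every object, the K same-image objects with the smallest Euclidean
#' centroid distance (ties broken by ascending object ID). An image with a
#' single object yields an empty neighbour set; images with fewer than K+1
#' objects yield all available neighbours.
#'
#' @param tab a table with `image_id`, `object_id`, `centroid_row`,
#'   `centroid_col` (e.g. a [feature_table()]).
#' @param K number of neighbours, >= 1.
#' @param include_self include the focal object itself (default FALSE).
#' @return A `neighbour_sets` object; `$records` is a long data.frame
#'   (`image_id`, `object_id`, `neighbour_id`, `distance`, `rank`) with
#'   distances sorted ascending within each focal object.
#' @export
knn_neighbours <- function(tab, K, include_self = FALSE) {
  cfg <- neighbourhood_config("knn", K = K, include_self = include_self)
  sel <- function(drow, i, ids) {
    cand <- if (include_self) seq_along(drow) else setdiff(seq_along(drow), i)
    if (!length(cand)) return(integer())
    cand[order(drow[cand], ids[cand])][seq_len(min(K, length(cand)))]
  }
  .neighbour_sets(.select_neighbours(tab, sel), tab, cfg)
}

#' Fixed-radius (N-distance) neighbour selection
#'
#' For every object, all same-image objects whose centroid lies within `n`
#' pixels (boundary inclusive). Empty neighbour sets are recorded, not
#' errors.
#'
#' @inheritParams knn_neighbours
#' @param n radius in pixels, > 0.
#' @return A `neighbour_sets` object (see [knn_neighbours()]).
#' @export
radius_neighbours <- function(tab, n, include_self = FALSE) {
  cfg <- neighbourhood_config("radius", n = n, include_self = include_self)
  sel <- function(drow, i, ids) {
    cand <- if (include_self) seq_along(drow) else setdiff(seq_along(drow), i)
    cand <- cand[drow[cand] <= n]
    cand[order(drow[cand], ids[cand])]
  }
  .neighbour_sets(.select_neighbours(tab, sel), tab, cfg)
}

.nbr_stats <- c("mean", "median", "std", "min", "max")

.stat_block <- function(x) {
  # x: numeric matrix (neighbours x features); returns 5 x F matrix
  if (!nrow(x)) return(matrix(0, 5L, ncol(x)))
  s <- if (nrow(x) > 1L) apply(x, 2L, stats::sd) else rep(0, ncol(x))
  rbind(colMeans(x), apply(x, 2L, stats::median), s,
        apply(x, 2L, min), apply(x, 2L, max))
}

#' Aggregate neighbour features into neighbourhood columns
#'
#' For F regular features this emits 5F aggregate columns
#' (`<stat>__<feature>` for mean/median/std/min/max over the neighbours'
#' regular features), 5 distance-statistic columns (`nbr_dist_<stat>` over
#' the centroid distances to the neighbours), and — for the radius method —
#' one `nbr_count` column giving the extent of the neighbourhood (for KNN
#' the count is the known K, so no column is added). Standard deviations use
#' the sample convention (ddof = 1); a single neighbour has std 0. Objects
#' with an empty neighbour set get all-zero neighbourhood columns (and count
#' 0), keeping the table rectangular so classifiers see "no context" as a
#' signal.
#'
#' @param tab a [feature_table()] whose `regular` columns are aggregated;
#'   every neighbour ID in `sets` must resolve to a row of `tab`.
#' @param sets a `neighbour_sets` from [knn_neighbours()] or
#'   [radius_neighbours()].
#' @return A [feature_table()] with the same objects (same order as `tab`)
#'   and only neighbourhood-derived columns: width 5F+5 (knn) or 5F+6
#'   (radius).
#' @export
aggregate_neighbourhood <- function(tab, sets) {
  stopifnot(inherits(sets, "neighbour_sets"))
  feats <- feature_names(tab, "regular")
  if (!length(feats)) stop("`tab` has no regular features", call. = FALSE)
  df <- as.data.frame(tab)
  key <- paste(df$image_id, df$object_id)
  rec <- sets$records
  if (nrow(rec)) {
    nbr_row <- match(paste(rec$image_id, rec$neighbour_id), key)
    if (anyNA(nbr_row))
      stop("neighbour IDs not resolvable in the feature table", call. = FALSE)
  } else nbr_row <- integer()

  fmat <- as.matrix(df[feats])
  n_obj <- nrow(df)
  agg <- matrix(0, n_obj, 5L * length(feats))
  dstat <- matrix(0, n_obj, 5L)
  count <- integer(n_obj)
  if (nrow(rec)) {
    grp <- split(seq_len(nrow(rec)), match(paste(rec$image_id, rec$object_id),
                                           key))
    for (g in names(grp)) {
      i <- as.integer(g); rows <- grp[[g]]
      count[i] <- length(rows)
      # column-major flatten of the 5 x F block = per-feature stat runs,
      # matching the <stat>__<feature> name order below
      agg[i, ] <- as.vector(.stat_block(fmat[nbr_row[rows], , drop = FALSE]))
      dstat[i, ] <- as.vector(.stat_block(matrix(rec$distance[rows], ncol = 1)))
    }
  }
  cn <- as.vector(vapply(feats, function(f) paste0(.nbr_stats, "__", f),
                         character(5L)))
  colnames(agg) <- cn
  colnames(dstat) <- paste0("nbr_dist_", .nbr_stats)
  out <- cbind(df[c("image_id", "object_id", "centroid_row", "centroid_col")],
               agg, dstat)
  prov <- c(stats::setNames(rep("neighbourhood", ncol(agg)), cn),
            stats::setNames(rep("distance_stat", 5L), colnames(dstat)))
  if (sets$config$method == "radius") {
    out$nbr_count <- as.numeric(count)
    prov <- c(prov, nbr_count = "neighbour_count")
  }
  feature_table(out, provenance = prov,
                pixel_scale = attr(tab, "pixel_scale"))
}

#' Column-wise combination of regular and neighbourhood tables
#'
#' @param regular a [feature_table()] of regular features.
#' @param neighbourhood the matching table from [aggregate_neighbourhood()];
#'   must have identical objects in identical order.
#' @return A [feature_table()] with both column blocks, provenance tags
#'   preserved; project back with [feature_view()].
#' @export
combine_features <- function(regular, neighbourhood) {
  kr <- paste(regular$image_id, regular$object_id)
  kn <- paste(neighbourhood$image_id, neighbourhood$object_id)
  if (!identical(kr, kn))
    stop("object keys/order differ between the two tables", call. = FALSE)
  nf <- feature_names(neighbourhood)
  out <- cbind(as.data.frame(regular),
               as.data.frame(neighbourhood)[, nf, drop = FALSE])
  feature_table(out,
                provenance = c(attr(regular, "provenance"),
                               attr(neighbourhood, "provenance")[nf]),
                pixel_scale = attr(regular, "pixel_scale"))
}

#' One-call neighbourhood augmentation
#'
#' Convenience wrapper: selects neighbours under `cfg` and returns the
#' combined (regular + neighbourhood) table.
#'
#' @param tab a [feature_table()] of regular features.
#' @param cfg a [neighbourhood_config()].
#' @return A combined [feature_table()].
#' @export
augment_features <- function(tab, cfg) {
  sets <- if (cfg$method == "knn")
    knn_neighbours(tab, cfg$K, cfg$include_self)
  else radius_neighbours(tab, cfg$n, cfg$include_self)
  combine_features(tab, aggregate_neighbourhood(tab, sets))
}
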