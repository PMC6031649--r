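#' Feature table construction
#'
#' The canonical object table: one row per segmented object with its image
#' ID, object ID, centroid (pixel coordinates, 0-based, origin top-left),
#' and named numeric feature columns. Each feature column carries a
#' provenance tag (`regular`, `neighbourhood`, `distance_stat`, or
#' `neighbour_count`) so views can be projected later.
#'
#' @param df a data.frame with columns `image_id`, `object_id`,
#'   `centroid_row`, `centroid_col` and numeric feature columns.
#' @param provenance named character vector tagging every feature column; if
#'   NULL all feature columns are tagged `regular`.
#' @param pixel_scale micrometres per pixel.
#' @return A `feature_table` (a data.frame with `provenance` and
#'   `pixel_scale` attributes).
#' @export
feature_table <- function(df, provenance = NULL, pixel_scale = 1) {
  req <- c("image_id", "object_id", "centroid_row", "centroid_col")
  if (!all(req %in% names(df)))
    stop("feature table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- paste(df$image_id, df$object_id)
  if (anyDuplicated(key))
    stop("duplicate (image_id, object_id) pairs", call. = FALSE)
  feats <- setdiff(names(df), req)
  if (length(feats)) {
    if (!all(vapply(df[feats], is.numeric, TRUE)))
      stop("feature columns must be numeric", call. = FALSE)
    if (any(!vapply(df[feats], function(x) all(is.finite(x)), TRUE)))
      stop("feature columns must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (is.null(provenance))
    provenance <- stats::setNames(rep("regular", length(feats)), feats)
  if (!setequal(names(provenance), feats))
    stop("`provenance` must tag exactly the feature columns", call. = FALSE)
  ok <- c("regular", "neighbourhood", "distance_stat", "neighbour_count")
  if (!all(provenance %in% ok))
    stop("unknown provenance tag", call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, provenance = provenance[feats], pixel_scale = pixel_scale,
            class = c("feature_table", "data.frame"))
}

#' Feature column names of a table, optionally filtered by provenance
#' @param x a `feature_table`.
#' @param provenance optional character vector of tags to keep.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(x, provenance = NULL) {
  p <- attr(x, "provenance")
  if (is.null(p)) stop("not a feature_table", call. = FALSE)
  if (is.null(provenance)) names(p) else names(p)[p %in% provenance]
}

#' Project a feature table onto a feature view
#'
#' @param x a `feature_table` containing regular and (optionally)
#'   neighbourhood-derived columns.
#' @param view one of `"regular"` (regular columns only),
#'   `"neighbourhood"` (neighbourhood aggregates, distance statistics and
#'   neighbour count), or `"combined"` (everything).
#' @return A `feature_table` restricted to the view's columns.
#' @export
feature_view <- function(x, view = c("combined", "regular", "neighbourhood")) {
  view <- match.arg(view)
  keep <- switch(view,
    combined = feature_names(x),
    regular = feature_names(x, "regular"),
    neighbourhood = feature_names(x, c("neighbourhood", "distance_stat",
                                       "neighbour_count")))
  id_cols <- c("image_id", "object_id", "centroid_row", "centroid_col")
  feature_table(as.data.frame(x)[, c(id_cols, keep), drop = FALSE],
                provenance = attr(x, "provenance")[keep],
                pixel_scale = attr(x, "pixel_scale"))
}

#' @export
print.feature_table <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("<feature_table> %d objects x %d features (%s)\n",
              nrow(x), length(p),
              paste(sprintf("%s: %d", names(table(p)), table(p)),
                    collapse = ", ")))
  NextMethod()
}

#' Read / write feature tables as CSV
#'
#' The on-disk dialect is UTF-8 CSV with a header row and `.` decimal,
#' columns `image_id, object_id, centroid_row, centroid_col` plus arbitrary
#' numeric feature columns. Provenance tags are not stored in the file;
#' `read_feature_table()` tags columns named `<stat>__<feature>`,
#' `nbr_dist_<stat>` and `nbr_count` by their naming convention and
#' everything else `regular`.
#'
#' @param path file path.
#' @param pixel_scale micrometres per pixel recorded on the read table.
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, pixel_scale = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  feats <- setdiff(names(df), c("image_id", "object_id", "centroid_row",
                                "centroid_col"))
  prov <- stats::setNames(rep("regular", length(feats)), feats)
  prov[grepl("^(mean|median|std|min|max)__", feats)] <- "neighbourhood"
  prov[grepl("^nbr_dist_", feats)] <- "distance_stat"
  prov[feats == "nbr_count"] <- "neighbour_count"
  feature_table(df, provenance = prov, pixel_scale = pixel_scale)
}

#' @rdname read_feature_table
#' @param x a `feature_table` to write.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
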