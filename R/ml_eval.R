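`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classifier specification
#'
#' Five classifier families are hosted: `naive_bayes` (e1071), raw
#' `random_forest` (randomForest, 100 trees), `svm_smo` (linear-kernel SVM,
#' C = 1), `simple_logistic` (multinomial logistic regression via nnet), and
#' `mlp` (single-hidden-layer perceptron, hidden size
#' (n_features + n_classes)/2). By default a PCA retaining 99% of variance
#' is fitted on each training fold and applied to its test fold for
#' `naive_bayes` and `mlp` (to curb their cost in high dimension); set
#' `pca_coverage = NA` to disable, or a fraction to force it for any family.
#' Features are z-scored per training fold before `svm_smo`,
#' `simple_logistic` and `mlp`.
#'
#' @param family one of `"naive_bayes"`, `"random_forest"`, `"svm_smo"`,
#'   `"simple_logistic"`, `"mlp"`.
#' @param hyperparams named list overriding defaults (`ntree`, `cost`,
#'   `maxit`, `decay`, `size`).
#' @param pca_coverage fraction in (0, 1], NA to disable, or NULL for the
#'   family default (0.99 for naive_bayes and mlp, none otherwise).
#' @param seed integer seed; every stochastic fit derives its RNG state
#'   from this.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("random_forest", "naive_bayes",
                                       "svm_smo", "simple_logistic", "mlp"),
                            hyperparams = list(), pca_coverage = NULL,
                            seed = 1L) {
  family <- match.arg(family)
  if (is.null(pca_coverage))
    pca_coverage <- if (family %in% c("naive_bayes", "mlp")) 0.99 else NA
  if (!is.na(pca_coverage) && (pca_coverage <= 0 || pca_coverage > 1))
    stop("`pca_coverage` must be in (0, 1]", call. = FALSE)
  structure(list(family = family, hyperparams = hyperparams,
                 pca_coverage = pca_coverage, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Image-level cross-validation folds
#'
#' Partitions whole images (never single objects) into `k` folds so that
#' all annotated objects of one image share a fold and spatially proximal
#' objects can never straddle the train/test split. Fold sizes differ by at
#' most one image; the partition is deterministic given `seed`.
#'
#' @param annotations data.frame with at least `image_id` (an
#'   `AnnotationSet`: `image_id`, `object_id`, `class`).
#' @param k number of folds; must not exceed the number of distinct
#'   annotated images.
#' @param seed integer seed for the image shuffle.
#' @return data.frame with `image_id` and `fold` (1..k).
#' @export
make_image_folds <- function(annotations, k, seed = 1L) {
  imgs <- sort(unique(as.character(annotations$image_id)))
  if (length(imgs) < k)
    stop("fewer distinct images (", length(imgs), ") than folds (", k, ")",
         call. = FALSE)
  ord <- imgs[.with_seed(seed, sample.int(length(imgs)))]
  data.frame(image_id = ord,
             fold = rep_len(seq_len(k), length(ord)),
             row.names = NULL)
}

#' PCA projection at a variance-coverage target
#'
#' Fits a principal component analysis on the training matrix only and
#' retains the minimal number of leading components whose cumulative
#' explained variance reaches `coverage`. A zero-variance matrix maps to a
#' single all-zero component.
#'
#' @param train numeric matrix (rows = objects).
#' @param coverage fraction in (0, 1].
#' @return A list with `ncomp`, `center`, `rotation` and
#'   `transform(newdata)` applying the training projection.
#' @export
pca_reduce <- function(train, coverage) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]",
                                          call. = FALSE)
  p <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  var <- p$sdev^2
  if (sum(var) < .Machine$double.eps) {
    ctr <- colMeans(train)
    return(list(ncomp = 1L, center = ctr,
                rotation = matrix(0, ncol(train), 1L),
                transform = function(x) matrix(0, nrow(x), 1L,
                                               dimnames = list(NULL, "PC1"))))
  }
  keep <- which(var > .Machine$double.eps)
  cum <- cumsum(var[keep]) / sum(var)
  ncomp <- if (coverage == 1) length(keep) else
    min(which(cum >= coverage), length(keep))
  rot <- p$rotation[, seq_len(ncomp), drop = FALSE]
  ctr <- p$center
  list(ncomp = ncomp, center = ctr, rotation = rot,
       transform = function(x) scale(x, center = ctr, scale = FALSE) %*% rot)
}

# z-score scaler fitted on train; zero-variance columns pass through
fit_scaler <- function(train) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < .Machine$double.eps] <- 1
  list(center = mu, scale = sdv,
       transform = function(x) scale(x, center = mu, scale = sdv))
}

# fold-local preprocessing pipeline for a classifier family
.fit_preprocess <- function(train, spec) {
  steps <- list()
  if (spec$family %in% c("svm_smo", "simple_logistic", "mlp"))
    steps$scaler <- fit_scaler(train)
  x <- if (!is.null(steps$scaler)) steps$scaler$transform(train) else train
  if (!is.na(spec$pca_coverage))
    steps$pca <- pca_reduce(x, spec$pca_coverage)
  steps
}

.apply_preprocess <- function(steps, x) {
  if (!is.null(steps$scaler)) x <- steps$scaler$transform(x)
  if (!is.null(steps$pca)) x <- steps$pca$transform(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

.fit_classifier <- function(x, y, spec) {
  hp <- spec$hyperparams
  switch(spec$family,
    naive_bayes = e1071::naiveBayes(as.data.frame(x), y),
    random_forest = randomForest::randomForest(x, y,
                                               ntree = hp$ntree %||% 100L),
    svm_smo = e1071::svm(x, y, kernel = "linear", cost = hp$cost %||% 1,
                         scale = FALSE),
    simple_logistic = nnet::multinom(y ~ ., data = data.frame(y = y, x),
                                     trace = FALSE, MaxNWts = 1e6,
                                     maxit = hp$maxit %||% 100L),
    mlp = {
      size <- hp$size %||% max(1L, round((ncol(x) + nlevels(y)) / 2))
      nnet::nnet(y ~ ., data = data.frame(y = y, x), size = size,
                 trace = FALSE, MaxNWts = 1e6, maxit = hp$maxit %||% 150L,
                 decay = hp$decay %||% 1e-4)
    })
}

.predict_classifier <- function(fit, x, spec) {
  xd <- as.data.frame(x)
  cls <- switch(spec$family,
    naive_bayes = stats::predict(fit, xd),
    random_forest = stats::predict(fit, x),
    svm_smo = stats::predict(fit, x),
    simple_logistic = stats::predict(fit, xd),
    mlp = factor(stats::predict(fit, xd, type = "class"),
                 levels = fit$lev))
  as.character(cls)
}

#' Image-level cross-validated classification
#'
#' Evaluates a classifier over the annotated objects of a feature table
#' under a chosen feature view, with every preprocessing step (z-scoring,
#' PCA) and the classifier itself fitted on each training fold only — no
#' information from a test fold ever reaches its model. Accuracy is pooled
#' over folds (total correct / total evaluated), matching the aggregated
#' confusion matrix.
#'
#' @param tab a [feature_table()] (typically the combined table from
#'   [augment_features()]).
#' @param annotations data.frame `image_id`, `object_id`, `class`; every
#'   annotated object must exist in `tab`.
#' @param folds either an integer number of folds (image folds are then
#'   generated with the spec's seed) or a data.frame from
#'   [make_image_folds()].
#' @param spec a [classifier_spec()].
#' @param view `"regular"`, `"neighbourhood"` or `"combined"`.
#' @return An `eval_result` with `accuracy`, `fold_accuracy`, `confusion`
#'   (rows = true class), `folds`, `view`, `n`.
#' @export
cross_validate <- function(tab, annotations, folds, spec,
                           view = c("combined", "regular", "neighbourhood")) {
  view <- match.arg(view)
  stopifnot(inherits(spec, "classifier_spec"))
  ann <- as.data.frame(annotations)
  if (anyDuplicated(paste(ann$image_id, ann$object_id)))
    stop("an object is annotated more than once", call. = FALSE)
  vt <- feature_view(tab, view)
  key <- paste(vt$image_id, vt$object_id)
  row_ix <- match(paste(ann$image_id, ann$object_id), key)
  if (anyNA(row_ix))
    stop("annotated objects missing from the feature table", call. = FALSE)
  if (is.numeric(folds) && length(folds) == 1L)
    folds <- make_image_folds(ann, folds, seed = spec$seed)
  fold_of <- folds$fold[match(as.character(ann$image_id), folds$image_id)]
  if (anyNA(fold_of)) stop("annotated image missing from fold table",
                           call. = FALSE)
  classes <- sort(unique(as.character(ann$class)))
  y <- factor(as.character(ann$class), levels = classes)
  x_all <- as.matrix(as.data.frame(vt)[feature_names(vt)])[row_ix, ,
                                                           drop = FALSE]
  k <- max(folds$fold)
  pred <- character(length(y))
  fold_acc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- fold_of == f
    if (!any(te)) next
    tr <- !te
    if (length(setdiff(classes, as.character(y[tr]))))
      warning("fold ", f, ": class(es) absent from training data: ",
              paste(setdiff(classes, as.character(y[tr])), collapse = ", "),
              call. = FALSE)
    steps <- .fit_preprocess(x_all[tr, , drop = FALSE], spec)
    xtr <- .apply_preprocess(steps, x_all[tr, , drop = FALSE])
    xte <- .apply_preprocess(steps, x_all[te, , drop = FALSE])
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L) {
      # degenerate training fold: only the constant prediction is defined
      pf <- rep(as.character(ytr[1L]), sum(te))
    } else {
      fit <- .with_seed(spec$seed * 1000L + f,
                        .fit_classifier(xtr, ytr, spec))
      pf <- .predict_classifier(fit, xte, spec)
    }
    pred[te] <- pf
    fold_acc[f] <- mean(pf == as.character(y[te]))
  }
  conf <- table(true = y, predicted = factor(pred, levels = classes))
  structure(list(accuracy = mean(pred == as.character(y)),
                 fold_accuracy = fold_acc,
                 confusion = conf, folds = folds, view = view, spec = spec,
                 n = length(y)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s / %s view: accuracy %.4f (%d objects, %d folds)\n",
    x$spec$family, x$view, x$accuracy, x$n, max(x$folds$fold)))
  invisible(x)
}

#' @export
summary.eval_result <- function(object, ...) {
  print(object)
  cat("per-fold accuracy:",
      paste(sprintf("%.3f", object$fold_accuracy), collapse = " "), "\n")
  cat("confusion matrix (rows = true):\n")
  print(object$confusion)
  invisible(object)
}

#' Accuracy versus neighbourhood extent
#'
#' Runs image-level cross-validation on the combined (regular +
#' neighbourhood) view for each neighbourhood size, plus the size-0
#' baseline (regular features only), on a single fold assignment shared by
#' all sizes. For `method = "knn"` sizes are K values; for `"radius"` they
#' are pixel radii.
#'
#' @param tab a [feature_table()] of regular features.
#' @param annotations `image_id`, `object_id`, `class`.
#' @param sizes increasing vector of neighbourhood sizes (K or n).
#' @param method `"knn"` or `"radius"`.
#' @param spec a [classifier_spec()].
#' @param folds number of image folds (default 10).
#' @return A `sweep_result`: `curve` (size, accuracy; size 0 = baseline),
#'   `best` (argmax row of the curve), `results` (the `eval_result`s).
#' @export
sweep_neighbourhood <- function(tab, annotations, sizes,
                                method = c("knn", "radius"), spec,
                                folds = 10L) {
  method <- match.arg(method)
  if (!length(sizes) || is.unsorted(sizes))
    stop("`sizes` must be non-empty and sorted increasing", call. = FALSE)
  fold_tab <- make_image_folds(annotations, folds, seed = spec$seed)
  res <- vector("list", length(sizes) + 1L)
  res[[1L]] <- cross_validate(tab, annotations, fold_tab, spec,
                              view = "regular")
  for (i in seq_along(sizes)) {
    cfg <- if (method == "knn")
      neighbourhood_config("knn", K = sizes[i])
    else neighbourhood_config("radius", n = sizes[i])
    comb <- augment_features(tab, cfg)
    res[[i + 1L]] <- cross_validate(comb, annotations, fold_tab, spec,
                                    view = "combined")
  }
  curve <- data.frame(size = c(0, sizes),
                      accuracy = vapply(res, `[[`, 0, "accuracy"))
  structure(list(curve = curve, best = curve[which.max(curve$accuracy), ],
                 method = method, results = res, folds = fold_tab),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s method, %d sizes (incl. baseline 0)\n",
              x$method, nrow(x$curve)))
  print(x$curve, row.names = FALSE)
  cat(sprintf("best: size %g, accuracy %.4f\n", x$best$size,
              x$best$accuracy))
  invisible(x)
}

#' Accuracy surface over superpixel size and neighbourhood extent
#'
#' For each superpixel size, evaluates the combined view at every
#' neighbourhood size (each cell is one image-level cross-validation run of
#' the corresponding single sweep), producing the accuracy surface whose
#' argmax identifies the optimal (superpixel size, neighbourhood size)
#' pair.
#'
#' @param tables named list of regular [feature_table()]s, one per
#'   superpixel size (names = sizes).
#' @param annotations named list of annotation data.frames aligned with
#'   `tables`.
#' @param nbh_sizes increasing vector of neighbourhood sizes.
#' @param method `"knn"` or `"radius"`.
#' @param spec a [classifier_spec()].
#' @param folds number of image folds.
#' @return A `surface_result`: `surface` (matrix, rows = superpixel sizes,
#'   cols = neighbourhood sizes), `best` (argmax), `sweeps` (per-size
#'   `sweep_result`s including baselines).
#' @export
sweep_superpixel_surface <- function(tables, annotations, nbh_sizes,
                                     method = c("knn", "radius"), spec,
                                     folds = 10L) {
  method <- match.arg(method)
  stopifnot(identical(names(tables), names(annotations)))
  sweeps <- lapply(names(tables), function(sz)
    sweep_neighbourhood(tables[[sz]], annotations[[sz]], nbh_sizes,
                        method = method, spec = spec, folds = folds))
  names(sweeps) <- names(tables)
  surface <- do.call(rbind, lapply(sweeps, function(s)
    s$curve$accuracy[match(nbh_sizes, s$curve$size)]))
  dimnames(surface) <- list(names(tables), as.character(nbh_sizes))
  arg <- which(surface == max(surface), arr.ind = TRUE)[1L, ]
  best <- data.frame(superpixel_size = as.numeric(rownames(surface)[arg[1]]),
                     nbh_size = nbh_sizes[arg[2]],
                     accuracy = max(surface))
  structure(list(surface = surface, best = best, sweeps = sweeps,
                 method = method),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat(sprintf("<surface_result> %s method, %d x %d accuracy surface\n",
              x$method, nrow(x$surface), ncol(x$surface)))
  print(round(x$surface, 4))
  cat(sprintf("best: superpixel %g, neighbourhood %g, accuracy %.4f\n",
              x$best$superpixel_size, x$best$nbh_size, x$best$accuracy))
  invisible(x)
}

#' Read an annotation CSV
#'
#' @param path CSV with columns `image_id`, `object_id`, `class`.
#' @param vocabulary optional allowed class labels.
#' @return data.frame of annotations (each object at most once).
#' @export
read_annotations <- function(path, vocabulary = NULL) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "object_id", "class")
  if (!all(req %in% names(ann)))
    stop("annotations need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(ann$image_id, ann$object_id)))
    stop("an object is annotated more than once", call. = FALSE)
  if (!is.null(vocabulary) && length(setdiff(ann$class, vocabulary)))
    stop("annotation labels outside the declared vocabulary", call. = FALSE)
  ann
}
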