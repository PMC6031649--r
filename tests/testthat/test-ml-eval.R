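# small separable dataset builder: n_img images, per_img objects per image,
# k classes with well separated means (class depends only on features)
separable_data <- function(n_img = 12, per_img = 10, k = 3, n_feat = 5,
                           sep = 8, seed = 1) {
  withr::with_seed(seed, {
    n <- n_img * per_img
    cls <- sample(k, n, replace = TRUE)
    x <- matrix(rnorm(n * n_feat), n)
    for (j in seq_len(k)) x[cls == j, 1] <- x[cls == j, 1] + sep * j
    df <- data.frame(image_id = rep(sprintf("im%02d", seq_len(n_img)),
                                    each = per_img),
                     object_id = rep(seq_len(per_img), n_img),
                     centroid_row = runif(n, 0, 100),
                     centroid_col = runif(n, 0, 100))
    for (j in seq_len(n_feat)) df[[sprintf("f%d", j)]] <- x[, j]
    list(tab = feature_table(df),
         ann = data.frame(image_id = df$image_id, object_id = df$object_id,
                          class = letters[cls]))
  })
}

test_that("image folds partition images evenly and deterministically", {
  ann38 <- data.frame(image_id = sprintf("im%02d", rep(1:38, each = 3)),
                      object_id = rep(1:3, 38), class = "x")
  f <- make_image_folds(ann38, 10, seed = 4)
  sizes <- as.vector(table(f$fold))
  expect_equal(sort(sizes), c(3, 3, rep(4, 8)))    # 38 = 8*4 + 2*3
  expect_equal(anyDuplicated(f$image_id), 0L)      # partition: no repeats
  expect_setequal(f$image_id, unique(ann38$image_id))

  ann10 <- data.frame(image_id = sprintf("i%02d", 1:10), object_id = 1,
                      class = "x")
  expect_true(all(table(make_image_folds(ann10, 10, 1)$fold) == 1))

  expect_identical(make_image_folds(ann38, 10, seed = 7),
                   make_image_folds(ann38, 10, seed = 7))
  expect_false(identical(make_image_folds(ann38, 10, seed = 7)$image_id,
                         make_image_folds(ann38, 10, seed = 8)$image_id))

  expect_error(make_image_folds(ann10, 11), "fewer")
})

test_that("pca_reduce retains the minimal components for the coverage", {
  # rank-1 data: one component at any coverage
  withr::with_seed(2, {
    u <- rnorm(50)
    rank1 <- cbind(u, 2 * u, -u)
  })
  expect_equal(pca_reduce(rank1, 0.5)$ncomp, 1L)
  expect_equal(pca_reduce(rank1, 0.99)$ncomp, 1L)

  # isotropic 3-D Gaussian: 99% coverage needs all 3 components;
  # oracle = eigendecomposition of the covariance matrix
  x <- withr::with_seed(3, matrix(rnorm(900), 300, 3))
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  oracle_ncomp <- min(which(cumsum(ev) / sum(ev) >= 0.99))
  expect_equal(oracle_ncomp, 3L)
  expect_equal(pca_reduce(x, 0.99)$ncomp, oracle_ncomp)

  # coverage 1.0: all components with nonzero variance
  expect_equal(pca_reduce(x, 1)$ncomp, 3L)
  expect_equal(pca_reduce(rank1, 1)$ncomp, 1L)

  # zero-variance matrix: a single all-zero component
  z <- matrix(5, 20, 4)
  pz <- pca_reduce(z, 0.99)
  expect_equal(pz$ncomp, 1L)
  expect_true(all(pz$transform(z) == 0))

  # projection dimensions
  expect_equal(dim(pca_reduce(x, 0.99)$transform(x)), c(300L, 3L))
})

test_that("cross-validation is grouped, deterministic and self-consistent", {
  d <- separable_data(seed = 21)
  spec <- classifier_spec("random_forest", seed = 3)
  res <- cross_validate(d$tab, d$ann, 6, spec, view = "regular")

  # perfectly separable classes: perfect accuracy
  expect_equal(res$accuracy, 1.0)
  # definitional identity: trace / total = accuracy, total = n evaluated
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion), res$accuracy)
  expect_equal(sum(res$confusion), res$n)
  # grouping: each image sits in exactly one fold
  expect_equal(anyDuplicated(res$folds$image_id), 0L)
  # determinism
  res2 <- cross_validate(d$tab, d$ann, 6, spec, view = "regular")
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$confusion, res2$confusion)
})

test_that("fold preprocessing never sees test rows (no leakage)", {
  d <- separable_data(seed = 22)
  spec <- classifier_spec("svm_smo", seed = 5)
  folds <- make_image_folds(d$ann, 4, seed = 5)
  x <- as.matrix(as.data.frame(d$tab)[feature_names(d$tab)])
  fold_of <- folds$fold[match(d$ann$image_id, folds$image_id)]
  tr <- fold_of != 1
  fitted <- popcontext:::.fit_preprocess(x[tr, ], spec)
  # the scaler must equal one computed from the training rows alone; a
  # fit that peeked at the withheld fold (e.g. global scaling) would differ
  expect_equal(unname(fitted$scaler$center), unname(colMeans(x[tr, ])))
  expect_equal(unname(fitted$scaler$scale),
               unname(apply(x[tr, ], 2, sd)))
  x_del <- x[tr, ]   # table with the test fold's rows deleted outright
  refit <- popcontext:::.fit_preprocess(x_del, spec)
  expect_identical(fitted$scaler$center, refit$scaler$center)
  expect_identical(fitted$scaler$scale, refit$scaler$scale)
  # PCA likewise depends on training rows only
  spec_pca <- classifier_spec("naive_bayes", seed = 5)
  p1 <- popcontext:::.fit_preprocess(x[tr, ], spec_pca)
  oracle <- stats::prcomp(x[tr, ], center = TRUE, scale. = FALSE)
  expect_equal(abs(p1$pca$rotation),
               abs(oracle$rotation[, seq_len(p1$pca$ncomp), drop = FALSE]),
               tolerance = 1e-8)
})

test_that("a class confined to one image triggers an absent-class warning", {
  d <- separable_data(n_img = 6, seed = 23)
  ann <- d$ann
  ann$class[ann$image_id == "im01"] <- "rare"
  ann$class[ann$image_id != "im01"] <- "common"
  spec <- classifier_spec("random_forest", seed = 1)
  expect_warning(cross_validate(d$tab, ann, 3, spec, view = "regular"),
                 "absent")
})

test_that("all five classifier families separate an easy problem", {
  d <- separable_data(n_img = 9, per_img = 8, seed = 24)
  for (fam in c("naive_bayes", "random_forest", "svm_smo",
                "simple_logistic", "mlp")) {
    res <- cross_validate(d$tab, d$ann, 3, classifier_spec(fam, seed = 2),
                          view = "regular")
    expect_gt(res$accuracy, 0.8)
  }
})

test_that("sweep baseline equals a regular-view cross-validation", {
  d <- separable_data(n_img = 8, per_img = 8, seed = 25)
  spec <- classifier_spec("random_forest", hyperparams = list(ntree = 50L),
                          seed = 6)
  sw <- sweep_neighbourhood(d$tab, d$ann, c(2, 4), "knn", spec, folds = 4)
  base <- cross_validate(d$tab, d$ann,
                         make_image_folds(d$ann, 4, seed = spec$seed),
                         spec, view = "regular")
  expect_equal(sw$curve$accuracy[sw$curve$size == 0], base$accuracy)
  expect_equal(nrow(sw$curve), 3L)
  expect_error(sweep_neighbourhood(d$tab, d$ann, c(4, 2), "knn", spec),
               "sorted")
})

test_that("surface cells equal their single sweep runs and are reproducible", {
  ds <- simulate_tissue(tissue_sim_params(n_images = 6,
                                          image_size = c(210, 210),
                                          annotate_n = 150, seed = 8),
                        sizes = c(35, 70))
  spec <- classifier_spec("random_forest", hyperparams = list(ntree = 50L),
                          seed = 7)
  # rare classes may miss a training fold in this tiny setting: expected
  surf <- suppressWarnings(
    sweep_superpixel_surface(ds$tables, ds$annotations, c(3, 6),
                             "knn", spec, folds = 3))
  # composition identity against an independently run sweep
  sw35 <- suppressWarnings(
    sweep_neighbourhood(ds$tables[["35"]], ds$annotations[["35"]],
                        c(3, 6), "knn", spec, folds = 3))
  expect_equal(unname(surf$surface["35", ]),
               sw35$curve$accuracy[match(c(3, 6), sw35$curve$size)])
  # exact reproducibility on a fixed seed
  surf2 <- suppressWarnings(
    sweep_superpixel_surface(ds$tables, ds$annotations, c(3, 6),
                             "knn", spec, folds = 3))
  expect_identical(surf$surface, surf2$surface)
  expect_equal(dim(surf$surface), c(2L, 2L))
})
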