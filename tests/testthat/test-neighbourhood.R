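test_that("neighbourhood_config enforces exactly one of K and n", {
  expect_error(neighbourhood_config("knn"), "K")
  expect_error(neighbourhood_config("knn", K = 0), "K")
  expect_error(neighbourhood_config("knn", K = 3, n = 5), "not used")
  expect_error(neighbourhood_config("radius"), "n")
  expect_error(neighbourhood_config("radius", n = 0), "n")
  expect_s3_class(neighbourhood_config("radius", n = 50),
                  "neighbourhood_config")
})

test_that("KNN selection matches the brute-force oracle and its edge cases", {
  # two objects: each is the other's sole neighbour at K = 1
  two <- feature_table(data.frame(image_id = "a", object_id = 1:2,
                                  centroid_row = c(0, 3),
                                  centroid_col = c(0, 4), f = c(1, 2)))
  s <- knn_neighbours(two, 1)
  expect_equal(s$records$neighbour_id, c(2L, 1L))
  expect_equal(s$records$distance, c(5, 5))

  # seeded random layouts agree with the O(N^2) oracle
  tab <- random_table(20, n_images = 2, seed = 42)
  expect_same_neighbours(knn_neighbours(tab, 5), brute_knn(tab, 5))

  # with at least K+1 objects per image every set has exactly K members
  sizes <- table(knn_neighbours(tab, 5)$records$object_id,
                 knn_neighbours(tab, 5)$records$image_id)
  expect_true(all(sizes[sizes > 0] == 5))

  # an image with a single object yields an empty set, not an error
  lone <- feature_table(data.frame(image_id = "solo", object_id = 1,
                                   centroid_row = 0, centroid_col = 0,
                                   f = 0))
  s_lone <- knn_neighbours(lone, 3)
  expect_equal(nrow(s_lone$records), 0L)
  expect_equal(nrow(s_lone$objects), 1L)

  # fewer than K available: all are used
  expect_equal(nrow(knn_neighbours(two, 10)$records), 2L)
})

test_that("radius selection matches the oracle, is symmetric and inclusive", {
  tab <- random_table(20, n_images = 2, seed = 43)
  expect_same_neighbours(radius_neighbours(tab, 50), brute_radius(tab, 50))

  # vanishing radius on distinct centroids: all sets empty
  expect_equal(nrow(radius_neighbours(tab, 1e-9)$records), 0L)

  # symmetric pair at distance 40 within n = 50; boundary inclusive
  pair <- feature_table(data.frame(image_id = "a", object_id = 1:2,
                                   centroid_row = c(0, 40),
                                   centroid_col = 0, f = 0))
  expect_equal(radius_neighbours(pair, 50)$records$neighbour_id, c(2L, 1L))
  expect_equal(radius_neighbours(pair, 40)$records$neighbour_id, c(2L, 1L))
  expect_equal(nrow(radius_neighbours(pair, 39.999)$records), 0L)

  # radius symmetry on a random layout
  rec <- radius_neighbours(tab, 80)$records
  key <- paste(rec$image_id, rec$object_id, rec$neighbour_id)
  rev <- paste(rec$image_id, rec$neighbour_id, rec$object_id)
  expect_setequal(key, rev)
})

test_that("KNN is not symmetric: a 3-point counterexample", {
  tri <- feature_table(data.frame(image_id = "a", object_id = 1:3,
                                  centroid_row = c(0, 10, 25),
                                  centroid_col = 0, f = 0))
  rec <- knn_neighbours(tri, 1)$records
  nb <- split(rec$neighbour_id, rec$object_id)
  expect_true(2L %in% nb[["3"]])        # 3's nearest is 2
  expect_false(3L %in% nb[["2"]])       # but 2's nearest is 1
})

test_that("neighbour sets grow monotonically in K and n", {
  tab <- random_table(30, seed = 44)
  key <- function(s) paste(s$records$object_id, s$records$neighbour_id)
  expect_true(all(key(knn_neighbours(tab, 3)) %in% key(knn_neighbours(tab, 6))))
  expect_true(all(key(radius_neighbours(tab, 30)) %in%
                  key(radius_neighbours(tab, 60))))
})

test_that("neighbours never cross image boundaries", {
  # two images with identical coordinates: any cross-image link would pair
  # an object with its clone at distance 0
  one <- random_table(15, seed = 45)
  df <- as.data.frame(one)
  df2 <- df; df2$image_id <- "imgB"
  tab <- feature_table(rbind(df, df2))
  rec <- knn_neighbours(tab, 4)$records
  expect_true(all(rec$distance > 0))
  expect_equal(nrow(rec), 2L * 15L * 4L)
})

test_that("aggregation reproduces hand-computed statistics", {
  df <- data.frame(image_id = "a", object_id = 1:5,
                   centroid_row = c(0, 1, 2, 3, 4), centroid_col = 0,
                   v = c(9, 1, 2, 3, 4))
  tab <- feature_table(df)
  # neighbours of object 1 within radius 4: objects 2..5, values {1,2,3,4}
  agg <- aggregate_neighbourhood(tab, radius_neighbours(tab, 4))
  r1 <- as.data.frame(agg)[1, ]
  expect_equal(r1$mean__v, 2.5)
  expect_equal(r1$median__v, 2.5)
  expect_equal(r1$min__v, 1)
  expect_equal(r1$max__v, 4)
  expect_equal(r1$std__v, sd(c(1, 2, 3, 4)))  # sample convention, 1.2910
  expect_equal(r1$nbr_count, 4)
  expect_equal(r1$nbr_dist_mean, 2.5)
  expect_equal(r1$nbr_dist_min, 1)

  # single neighbour: all aggregates equal its value, std 0
  s1 <- knn_neighbours(tab, 1)
  a1 <- as.data.frame(aggregate_neighbourhood(tab, s1))
  expect_equal(a1$mean__v[1], a1$median__v[1])
  expect_equal(a1$std__v[1], 0)
  expect_equal(a1$min__v[1], a1$max__v[1])
})

test_that("empty neighbour sets yield zero-filled rows with count zero", {
  df <- data.frame(image_id = c("a", "a", "b"), object_id = c(1, 2, 1),
                   centroid_row = c(0, 1000, 0), centroid_col = 0,
                   v = c(5, 6, 7))
  tab <- feature_table(df)
  agg <- as.data.frame(aggregate_neighbourhood(tab, radius_neighbours(tab, 10)))
  expect_equal(agg$mean__v, c(0, 0, 0))
  expect_equal(agg$nbr_count, c(0, 0, 0))
})

test_that("aggregates of a constant feature equal that constant with std 0", {
  df <- random_table(12, seed = 9)
  df$f01 <- 3.25
  rec <- aggregate_neighbourhood(df, knn_neighbours(df, 4))
  d <- as.data.frame(rec)
  expect_true(all(d$mean__f01 == 3.25))
  expect_true(all(d$median__f01 == 3.25))
  expect_true(all(d$std__f01 == 0))
})

test_that("neighbourhood width accounting and combination identities hold", {
  tab <- random_table(8, n_feat = 10, seed = 10)
  nb_r <- aggregate_neighbourhood(tab, radius_neighbours(tab, 300))
  expect_length(feature_names(nb_r), 56L)          # 5*10 + 5 + 1
  nb_k <- aggregate_neighbourhood(tab, knn_neighbours(tab, 3))
  expect_length(feature_names(nb_k), 55L)          # 5*10 + 5

  comb <- combine_features(tab, nb_r)
  expect_length(feature_names(comb), 66L)
  # projection identity: regular view of the combination is the input
  expect_equal(as.data.frame(feature_view(comb, "regular")),
               as.data.frame(tab))

  bad <- feature_table(as.data.frame(nb_r)[c(2:8, 1), ],
                       provenance = attr(nb_r, "provenance"))
  expect_error(combine_features(tab, bad), "order")
})

test_that("include_self puts the focal object first at distance zero", {
  tab <- random_table(6, seed = 11)
  rec <- knn_neighbours(tab, 2, include_self = TRUE)$records
  first <- rec[rec$rank == 1, ]
  expect_equal(first$neighbour_id, first$object_id)
  expect_true(all(first$distance == 0))
})
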