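# Independent oracles and small builders shared across tests.

# O(N^2) brute-force K-nearest-neighbour selection: plain loops, ties by
# ascending object_id, never crossing image boundaries.
brute_knn <- function(tab, K) {
  tab <- as.data.frame(tab)
  out <- list()
  for (img in unique(tab$image_id)) {
    sub <- tab[tab$image_id == img, ]
    for (i in seq_len(nrow(sub))) {
      d <- sqrt((sub$centroid_row - sub$centroid_row[i])^2 +
                (sub$centroid_col - sub$centroid_col[i])^2)
      cand <- setdiff(seq_len(nrow(sub)), i)
      ord <- cand[order(d[cand], sub$object_id[cand])]
      take <- ord[seq_len(min(K, length(ord)))]
      if (length(take))
        out[[length(out) + 1L]] <- data.frame(
          image_id = img, object_id = sub$object_id[i],
          neighbour_id = sub$object_id[take], distance = d[take])
    }
  }
  do.call(rbind, out)
}

# O(N^2) brute-force fixed-radius selection (boundary inclusive).
brute_radius <- function(tab, n) {
  tab <- as.data.frame(tab)
  out <- list()
  for (img in unique(tab$image_id)) {
    sub <- tab[tab$image_id == img, ]
    for (i in seq_len(nrow(sub))) {
      d <- sqrt((sub$centroid_row - sub$centroid_row[i])^2 +
                (sub$centroid_col - sub$centroid_col[i])^2)
      cand <- setdiff(seq_len(nrow(sub)), i)
      take <- cand[d[cand] <= n]
      take <- take[order(d[take], sub$object_id[take])]
      if (length(take))
        out[[length(out) + 1L]] <- data.frame(
          image_id = img, object_id = sub$object_id[i],
          neighbour_id = sub$object_id[take], distance = d[take])
    }
  }
  do.call(rbind, out)
}

# flood-fill connected-component count (4-connectivity), explicit stack
flood_fill_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    while (length(stack)) {
      px <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[px]) next
      seen[px] <- TRUE
      r <- (px - 1L) %% h + 1L; cc <- (px - 1L) %/% h + 1L
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + dd[1]; cc2 <- cc + dd[2]
        if (rr >= 1L && rr <= h && cc2 >= 1L && cc2 <= w) {
          q <- (cc2 - 1L) * h + rr
          if (mask[q] && !seen[q]) stack <- c(stack, q)
        }
      }
    }
  }
  count
}

# random centroid + feature table over several images
random_table <- function(n_obj, n_images = 1, n_feat = 3, seed = 1,
                         extent = 500) {
  withr::with_seed(seed, {
    df <- data.frame(
      image_id = rep(sprintf("img%02d", seq_len(n_images)),
                     each = n_obj),
      object_id = rep(seq_len(n_obj), times = n_images),
      centroid_row = runif(n_obj * n_images, 0, extent),
      centroid_col = runif(n_obj * n_images, 0, extent))
    for (j in seq_len(n_feat))
      df[[sprintf("f%02d", j)]] <- rnorm(n_obj * n_images)
    feature_table(df)
  })
}

# binary image with bright discs at given (row, col, radius), 1-based centres
disc_image <- function(h, w, discs, fg = 1, bg = 0) {
  img <- matrix(bg, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(discs)))
    img[(rows - discs[i, 1])^2 + (cols - discs[i, 2])^2 <= discs[i, 3]^2] <- fg
  img
}

# long-record comparison helper: same neighbour sets and distances
expect_same_neighbours <- function(sets, oracle) {
  rec <- sets$records[c("image_id", "object_id", "neighbour_id", "distance")]
  ord <- function(d) d[order(d$image_id, d$object_id, d$distance,
                             d$neighbour_id), ]
  rec <- ord(rec); oracle <- ord(oracle)
  rownames(rec) <- rownames(oracle) <- NULL
  expect_equal(rec$image_id, oracle$image_id)
  expect_equal(rec$object_id, oracle$object_id)
  expect_equal(rec$neighbour_id, oracle$neighbour_id)
  expect_equal(rec$distance, oracle$distance, tolerance = 1e-12)
}
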