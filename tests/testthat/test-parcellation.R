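test_that("the hybrid distance follows D = alpha X + (1 - alpha) beta Y", {
  cfg <- clustering_config(alpha = 1)
  expect_equal(combined_distance(c(1, 2), c(4, 6), c(0, 0, 0), c(3, 3, 3),
                                 cfg), 5)
  cfg0 <- clustering_config(alpha = 0, beta = 85)
  expect_equal(combined_distance(c(1, 2), c(1, 2), c(0, 0, 0), c(1, 0, 0),
                                 cfg0), 85)
  cfg5 <- clustering_config(alpha = 0.5, beta = 85)
  expect_equal(combined_distance(c(0, 0), c(2, 0), c(0, 0, 0), c(0.5, 0, 0),
                                 cfg5), 0.5 * 2 + 0.5 * 85 * 0.5)  # 22.25
  # symmetry and identity of indiscernibles
  expect_equal(combined_distance(c(1, 2), c(4, 6), c(0, 0, 0), c(3, 3, 3),
                                 cfg5),
               combined_distance(c(4, 6), c(1, 2), c(3, 3, 3), c(0, 0, 0),
                                 cfg5))
  expect_equal(combined_distance(c(1, 2), c(1, 2), c(1, 1, 1), c(1, 1, 1),
                                 cfg5), 0)
  expect_error(combined_distance(c(1, 2), c(1, 2, 3), c(0, 0, 0),
                                 c(0, 0, 0), cfg5), "length")
})

test_that("spatial hierarchical initialization seeds well-separated blobs", {
  set.seed(1)
  blob <- function(center, n = 20) sweep(matrix(runif(3 * n, -1, 1), n, 3),
                                         2, center, "+")
  pos <- rbind(blob(c(0, 0, 0)), blob(c(20, 0, 0)))
  cf <- matrix(rnorm(nrow(pos) * 4), ncol = 4)
  ini <- init_centroids(cf, pos, 2)
  cx <- sort(ini$pos[, 1])
  expect_lt(abs(cx[1] - 0), 1)
  expect_lt(abs(cx[2] - 20), 1)

  # three collinear equidistant blobs -> three centroids at the blob centers
  pos3 <- rbind(blob(c(0, 0, 0)), blob(c(15, 0, 0)), blob(c(30, 0, 0)))
  ini3 <- init_centroids(matrix(0, nrow(pos3), 2), pos3, 3)
  expect_equal(unname(sort(round(ini3$pos[, 1] / 15))), c(0, 1, 2))

  # k = number of voxels: every voxel its own centroid
  inin <- init_centroids(cf[1:4, ], pos[1:4, ], 4)
  expect_equal(unname(sort(inin$pos[, 1])), sort(pos[1:4, 1]))
  expect_error(init_centroids(cf[1:2, ], pos[1:2, ], 3), "fewer voxels")
})

test_that("k = 1 labels every masked voxel identically", {
  ph <- small_phantom(seed = 1, grid = c(10, 12, 8))
  p <- kmeans_segment(ph$fod, ph$mask, clustering_config(k = 1))
  expect_true(all(p$labels[ph$mask] == 1))
  expect_true(all(p$labels[!ph$mask] == 0))
})

test_that("a noise-free phantom is recovered exactly", {
  ph <- small_phantom(seed = 3, snr = 0)
  p <- kmeans_segment(ph$fod, ph$mask, clustering_config())
  m <- match_labels(p, ph$parcellation)
  expect_equal(mean(dice_scores(m, ph$parcellation)), 1)
})

test_that("segmentation is deterministic and its objective non-increasing", {
  ph <- small_phantom(seed = 4, grid = c(12, 14, 10))
  p1 <- kmeans_segment(ph$fod, ph$mask, clustering_config())
  p2 <- kmeans_segment(ph$fod, ph$mask, clustering_config())
  expect_identical(p1$labels, p2$labels)
  expect_true(all(diff(p1$objective) <= 1e-9))
})

test_that("the metric is homogeneous: scaling FOD and beta jointly", {
  ph <- small_phantom(seed = 6, grid = c(10, 12, 8))
  p1 <- kmeans_segment(ph$fod, ph$mask, clustering_config(beta = 85))
  p2 <- kmeans_segment(3 * ph$fod, ph$mask, clustering_config(beta = 3 * 85))
  m2 <- match_labels(p2, p1)
  expect_equal(parcellation_labels(m2), p1$labels)
})

test_that("label matching recovers permutations (brute-force oracle)", {
  ph <- small_phantom(seed = 2, grid = c(10, 12, 8))
  ref <- ph$parcellation
  expect_equal(attr(match_labels(ref, ref), "permutation"), 1:7)
  shift <- ref
  shift[ref > 0] <- (ref[ref > 0] %% 7L) + 1L
  m <- match_labels(shift, ref)
  expect_equal(parcellation_labels(m), ref, ignore_attr = TRUE)

  # 3-label random toys vs exhaustive search over all 3! permutations
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:3, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    got <- attr(match_labels(a, b), "permutation")
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))
    sc <- apply(perms, 1, function(p) sum(p[a] == b))
    expect_equal(sum(got[a] == b), max(sc))
  }
  expect_error(match_labels(c(1, 2, 3), c(1, 2, 2)), "different numbers")
})

test_that("converged objectives match multi-restart search on small instances", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(60:180, 1)
    pos <- matrix(runif(3 * n, 0, 8), n, 3)
    cf <- matrix(rnorm(n * 6, sd = 30), n, 6)
    cfg <- clustering_config(k = 3, beta = 10)
    ours <- kmeans_segment(cf, pos, cfg)
    best <- Inf
    for (r in 1:15) {
      init <- sample(1:3, n, replace = TRUE)
      while (length(unique(init)) < 3) init <- sample(1:3, n, replace = TRUE)
      alt <- kmeans_segment(cf, pos, cfg, init = init)
      best <- min(best, utils::tail(alt$objective, 1))
    }
    expect_gte(utils::tail(ours$objective, 1), best - 1e-6)
  }

  # separable instance: deterministic fit attains the multi-restart optimum
  set.seed(22)
  pos <- rbind(matrix(runif(90, 0, 2), 30, 3),
               matrix(runif(90, 8, 10), 30, 3))
  cf <- rbind(matrix(rnorm(30 * 4, mean = 50, sd = 0.5), 30, 4),
              matrix(rnorm(30 * 4, mean = -50, sd = 0.5), 30, 4))
  cfg <- clustering_config(k = 2, beta = 10)
  ours <- kmeans_segment(cf, pos, cfg)
  best <- Inf
  for (r in 1:10) {
    init <- sample(1:2, 60, replace = TRUE)
    while (length(unique(init)) < 2) init <- sample(1:2, 60, replace = TRUE)
    alt <- kmeans_segment(cf, pos, cfg, init = init)
    best <- min(best, utils::tail(alt$objective, 1))
  }
  expect_equal(utils::tail(ours$objective, 1), best, tolerance = 1e-9)
})

test_that("parcellation objects expose the modelling-idiom methods", {
  ph <- small_phantom(seed = 9, grid = c(10, 12, 8))
  p <- kmeans_segment(ph$fod, ph$mask, clustering_config())
  expect_s3_class(p, "thalamic_parcellation")
  expect_identical(fitted(p), p$labels)
  expect_named(coef(p), c("fod", "pos"))
  expect_output(print(p), "Thalamic parcellation")
  # predict assigns a voxel sitting on a centroid to that centroid
  cent <- coef(p)
  for (j in c(1, 5)) {
    lab <- predict(p, cent$fod[j, ], cent$pos[j, ])
    expect_equal(lab, j)
  }
})
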