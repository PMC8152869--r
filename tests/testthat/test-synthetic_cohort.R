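test_that("phantom generation is deterministic and seed-sensitive", {
  a <- small_phantom(seed = 3)
  b <- small_phantom(seed = 3)
  c <- small_phantom(seed = 4)
  expect_identical(a$fod, b$fod)
  expect_identical(a$tensor, b$tensor)
  expect_false(identical(a$fod, c$fod))
})

test_that("zero noise makes within-nucleus coefficients identical", {
  ph <- small_phantom(seed = 2, snr = 0)
  flat <- matrix(ph$fod, ncol = 28)
  for (j in c(1, 4, 7)) {
    idx <- which(ph$parcellation == j)
    expect_equal(max(apply(flat[idx, ], 2, function(x) diff(range(x)))), 0)
  }
})

test_that("between-nucleus distances dominate within-nucleus distances", {
  ph <- make_phantom(phantom_config(seed = 2), basis = basis3)
  dr <- phantom_distance_ratio(ph)
  expect_gt(dr$between / dr$within, 3)
})

test_that("nucleus orientations too close are rejected", {
  o <- default_orientations(7)
  o[2, ] <- o[1, ] + c(0.01, 0, 0)
  expect_error(phantom_config(orientations = o), "20 degrees")
})

test_that("pathway tubes are disjoint, connected, anchored in their nuclei", {
  ph <- small_phantom(seed = 1)
  pw <- make_pathways(ph$parcellation, n_targets = 5)
  expect_equal(nrow(pw$table), 35)
  expect_equal(sort(unique(pw$labels[pw$labels > 0])), 1:35)
  for (p in c(1, 12, 35)) {
    vx <- pw$voxels[pw$voxels$pathway == p, ]
    # first voxel inside its nucleus
    nuc <- pw$table$nucleus[pw$table$pathway == p]
    expect_equal(ph$parcellation[vx$i[1], vx$j[1], vx$k[1]], nuc)
    # 6-connected tube
    steps <- abs(diff(as.matrix(vx[, c("i", "j", "k")])))
    expect_true(all(rowSums(steps) == 1))
  }
  # tube voxel counts match the label volume
  expect_equal(nrow(pw$voxels), sum(pw$labels > 0))
})

test_that("a single-nucleus single-target grid yields one tube", {
  lab <- thalparc:::block_parcellation(c(12, 12, 10), 1)
  pw <- make_pathways(lab, n_targets = 1)
  expect_equal(nrow(pw$table), 1)
  vx <- pw$voxels
  expect_equal(lab[vx$i[1], vx$j[1], vx$k[1]], 1L)
})

test_that("cohorts are deterministic with the planted group structure", {
  ch1 <- tiny_cohort(seed = 11)
  ch2 <- tiny_cohort(seed = 11)
  expect_identical(ch1$meta, ch2$meta)
  expect_identical(ch1$subjects[[5]]$fod, ch2$subjects[[5]]$fod)
  expect_identical(ch1$subjects[[9]]$field, ch2$subjects[[9]]$field)

  expect_equal(as.vector(table(ch1$meta$group)), c(4, 3, 3))
  # CRS-R planted ordering: VS below MCS on average, HC at ceiling
  expect_lt(mean(ch1$meta$crs_r_total[ch1$meta$group == "VS"]),
            mean(ch1$meta$crs_r_total[ch1$meta$group == "MCS"]))
  expect_true(all(ch1$meta$doc_duration[ch1$meta$group == "HC"] == 0))
  expect_true(all(ch1$meta$crs_r_total >= 0 & ch1$meta$crs_r_total <= 23))
})

test_that("planted deformations hit their per-subject volume targets", {
  ch <- tiny_cohort(seed = 13, n_targets = 0)
  tp <- ch$template$parcellation
  for (s in c(6, 10)) {     # patients
    lj <- log_jacobian(ch$subjects[[s]]$field, mask = ch$subjects[[s]]$mask)
    lam_e <- ch$truth[[s]]$lambda_expand
    lam_s <- ch$truth[[s]]$lambda_shrink
    # numeric field mean = analytic target up to warp-jitter noise
    expect_lt(abs(mean(lj[tp == 6]) - log(lam_e)), 0.06)
    expect_lt(abs(mean(lj[tp == 1]) - log(lam_s)), 0.06)
    # the analytic construction itself is calibrated exactly
    expect_lt(abs(ch$truth[[s]]$logj_analytic_mean["expand"] - log(lam_e)),
              1e-5)
    expect_lt(abs(ch$truth[[s]]$logj_analytic_mean["shrink"] - log(lam_s)),
              1e-5)
  }
})

test_that("a +20 percent planted expansion shows in the measured log-Jacobian", {
  ## deterministic construction: exact-calibration warp without jitter
  dims <- c(20, 24, 16)
  tlab <- thalparc:::block_parcellation(dims, 7)
  w <- thalparc:::nucleus_scale_warp(dims, tlab, 6, 1, 1.2, 1 / 1.2)
  lj <- log_jacobian(w$field)
  expect_lt(abs(mean(lj[tlab == 6]) - log(1.2)), 0.1 * log(1.2))
  expect_lt(abs(mean(lj[tlab == 1]) + log(1.2)), 0.1 * log(1.2))
})
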