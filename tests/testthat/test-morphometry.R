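test_that("log-Jacobian special cases: identity, uniform scale, translation", {
  g <- c(10, 10, 10)
  zero <- array(0, c(g, 3))
  expect_true(all(log_jacobian(zero) == 0))

  pts <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  s <- 1.07
  fld <- array((s - 1) * sweep(pts, 2, c(5.5, 5.5, 5.5)), c(g, 3))
  lj <- log_jacobian(fld)
  expect_lt(max(abs(lj - 3 * log(s))), 1e-6)

  shifted <- fld + 2.5            # constant displacement added
  expect_lt(max(abs(log_jacobian(shifted) - lj)), 1e-10)
})

test_that("an analytic radial expansion is recovered within 1 percent", {
  g <- c(32, 32, 32)
  rf <- radial_deformation(g, (g + 1) / 2, a = 0.2, w = 8)
  lj <- log_jacobian(rf)
  an <- attr(rf, "log_jacobian_analytic")
  core <- abs(an) > 0.05
  expect_gt(sum(core), 100)
  expect_lt(max(abs((lj - an)[core] / an[core])), 0.01)
})

test_that("composed uniform scalings add their log-Jacobians", {
  g <- c(10, 10, 10)
  pts <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  ctr <- c(5.5, 5.5, 5.5)
  f1 <- array(0.05 * sweep(pts, 2, ctr), c(g, 3))
  f2 <- array(0.03 * sweep(pts, 2, ctr), c(g, 3))
  # composition of x -> 1.05(x - c) + c and x -> 1.03(x - c) + c
  comp <- array((1.05 * 1.03 - 1) * sweep(pts, 2, ctr), c(g, 3))
  expect_lt(max(abs(log_jacobian(comp) -
                      (log_jacobian(f1) + log_jacobian(f2)))), 1e-6)
})

test_that("folding deformations are reported", {
  g <- c(8, 8, 8)
  pts <- as.matrix(expand.grid(1:8, 1:8, 1:8))
  fld <- array(-1.5 * sweep(pts, 2, c(4.5, 4.5, 4.5)), c(g, 3))
  expect_error(log_jacobian(fld), "folding")
})

test_that("per-nucleus shape statistics equal brute-force averaging", {
  lab <- thalparc:::block_parcellation(c(12, 14, 10), 7)
  lj <- array(0.37, dim(lab))
  expect_equal(unname(nucleus_shape_stats(lj, lab)), rep(0.37, 7))

  lj2 <- array(0, dim(lab)); lj2[lab == 3] <- 0.2
  m <- nucleus_shape_stats(lj2, lab)
  expect_equal(unname(m[3]), 0.2)
  expect_equal(unname(m[-3]), rep(0, 6))

  set.seed(5)
  lj3 <- array(rnorm(prod(dim(lab))), dim(lab))
  m3 <- nucleus_shape_stats(lj3, lab)
  brute <- vapply(1:7, function(j) mean(lj3[lab == j]), numeric(1))
  expect_equal(unname(m3), brute, tolerance = 1e-14)
})

test_that("volume ratios count labeled voxels", {
  lab <- thalparc:::block_parcellation(c(12, 14, 10), 7)
  expect_equal(unname(volume_ratio_change(lab, lab)), rep(1, 7))
  big <- thalparc:::block_parcellation(c(12, 14, 10), 7,
                                       plane_shift = c(1, 0, 0))
  vr <- volume_ratio_change(big, lab)
  brute <- tabulate(big[big > 0], 7) / tabulate(lab[lab > 0], 7)
  expect_equal(unname(vr), brute)
  empty <- lab; empty[lab == 2] <- 1L
  expect_error(volume_ratio_change(lab, empty), "empty reference")
})

test_that("the adjusted one-sample test nests the classical t-test", {
  r0 <- covariate_adjusted_one_sample_test(rep(0, 8))
  expect_equal(r0$t, 0)
  expect_equal(r0$p.value, 1)

  r <- covariate_adjusted_one_sample_test(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$p.value, t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)

  # a centered covariate effect is fully absorbed: intercept non-significant
  set.seed(2)
  cv <- rnorm(12)
  vals <- 2 * (cv - mean(cv)) + rnorm(12, 0, 0.3)
  rc <- covariate_adjusted_one_sample_test(vals, data.frame(z = cv))
  expect_equal(rc$estimate, mean(vals), tolerance = 1e-10)
  expect_gt(rc$p.value, 0.05)

  expect_error(covariate_adjusted_one_sample_test(
    rnorm(8), data.frame(a = 1:8, b = 2 * (1:8))), "collinear")
})

test_that("the adjusted one-sample test holds its nominal size", {
  set.seed(12)
  rej <- mean(replicate(2000, {
    covariate_adjusted_one_sample_test(
      rnorm(12), matrix(rnorm(36), 12, 3))$p.value <= 0.05
  }))
  expect_lt(abs(rej - 0.05), 2 * sqrt(0.05 * 0.95 / 2000))
})
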