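test_that("an isotropic FOD yields one peakless fixel with the full integral", {
  c0 <- 3
  fx <- extract_fixels(c(c0, rep(0, 27)), basis3)
  expect_equal(nrow(fx), 1)
  expect_true(fx$peakless)
  expect_equal(c(fx$dx, fx$dy, fx$dz), c(0, 0, 1))
  # closed form: integral of c0 * Y00 over the sphere = c0 * 2 sqrt(pi)
  expect_equal(fx$fd, c0 * 2 * sqrt(pi), tolerance = 1e-9)
})

test_that("FD is exactly linear in the FOD amplitude", {
  w <- thalparc:::watson_sh(c(0, 0, 1), basis3, 20)
  f1 <- extract_fixels(w, basis3)
  f3 <- extract_fixels(3 * w, basis3)
  expect_equal(nrow(f1), 1)
  expect_equal(f3$fd, 3 * f1$fd, tolerance = 1e-12)
  # single lobe along z: canonical direction close to +z
  expect_gt(abs(f1$dz), 0.99)
})

test_that("two equal orthogonal lobes give two near-equal fixels", {
  # kappa 12 keeps the band-limited lobes free of ringing sidelobes above
  # the 0.1 peak threshold (sharper lobes leave a ~5 percent sidelobe fixel)
  w <- thalparc:::watson_sh(c(0, 0, 1), basis3, 12) +
    thalparc:::watson_sh(c(1, 0, 0), basis3, 12)
  fx <- extract_fixels(w, basis3)
  expect_equal(nrow(fx), 2)
  expect_lt(abs(fx$fd[1] - fx$fd[2]) / fx$fd[1], 0.02)
  # the sharp-lobe case: the two dominant fixels remain near-equal
  w20 <- thalparc:::watson_sh(c(0, 0, 1), basis3, 20) +
    thalparc:::watson_sh(c(1, 0, 0), basis3, 20)
  fx20 <- extract_fixels(w20, basis3)
  expect_lt(abs(fx20$fd[1] - fx20$fd[2]) / fx20$fd[1], 0.02)
})

test_that("fixels honor max_fixels and the all-nonpositive case", {
  w <- thalparc:::watson_sh(c(0, 0, 1), basis2, 20) +
    thalparc:::watson_sh(c(1, 0, 0), basis2, 20) +
    thalparc:::watson_sh(c(0, 1, 0), basis2, 20)
  fx <- extract_fixels(w, basis2, max_fixels = 2)
  expect_lte(nrow(fx), 2)
  expect_true(all(diff(fx$fd) <= 0))
  neg <- extract_fixels(c(-1, rep(0, 27)), basis2)
  expect_equal(nrow(neg), 0)
})

test_that("FC matches the closed forms and is rotation invariant", {
  expect_equal(fixel_fc(c(0, 0, 1), diag(3)), 1)
  expect_equal(fixel_fc(c(1, 0, 0), 2 * diag(3)), 4)  # s^2 for s = 2
  expect_equal(fixel_fc(c(0, 0, 1), diag(c(2, 3, 4))), 2 * 3)
  set.seed(3)
  for (i in 1:10) {
    J <- diag(3) + 0.2 * matrix(rnorm(9), 3)
    if (det(J) <= 0) next
    d <- runit(1)[1, ]
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(fixel_fc(drop(Q %*% d), Q %*% J %*% t(Q)),
                 fixel_fc(d, J), tolerance = 1e-10)
  }
  expect_error(fixel_fc(c(0, 0, 1), -diag(3)), "degenerate")
})

test_that("FDC is the product of FD and FC", {
  expect_equal(fdc(0.5, 1), 0.5)
  expect_equal(fdc(0, 2), 0)
  expect_equal(fdc(0.3, 1.2), 0.36)
  expect_error(fdc(-1, 1), "non-negative")
  expect_error(fdc(1, 0), "positive")
})

test_that("the batched fixel table agrees with per-voxel extraction", {
  ph <- small_phantom(seed = 5, grid = c(10, 12, 8))
  sub <- which(ph$mask, arr.ind = TRUE)[1:20, ]
  m <- array(FALSE, dim(ph$mask)); m[sub] <- TRUE
  ft <- fixel_table(ph$fod, m, basis2)
  flat <- matrix(ph$fod, ncol = 28)
  for (r in seq_len(nrow(sub))) {
    v <- sub[r, ]
    ref <- extract_fixels(flat[v[1] + dim(m)[1] * (v[2] - 1 + dim(m)[2] *
                                                     (v[3] - 1)), ], basis2)
    got <- ft[ft$i == v[1] & ft$j == v[2] & ft$k == v[3], ]
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$fd, ref$fd, tolerance = 1e-12)
  }
})

test_that("lobe FD sums never exceed the positive-part spherical integral", {
  set.seed(9)
  for (i in 1:20) {
    cf <- rnorm(28)
    amp <- pmax(evaluate_amplitude(cf, basis3), 0)
    total <- sum(amp * basis3$weights)
    fx <- extract_fixels(cf, basis3, max_fixels = 10)
    if (nrow(fx) == 0) next
    expect_lte(sum(fx$fd), total + 1e-9)
  }
})

test_that("template fixels match by angular distance with a 45-degree gate", {
  tmpl <- data.frame(dx = c(0, 1), dy = c(0, 0), dz = c(1, 0))
  subj <- data.frame(dx = c(0.1, 0), dy = c(0, 1), dz = c(0.995, 0))
  subj[1, 1:3] <- subj[1, 1:3] / sqrt(sum(subj[1, 1:3]^2))
  m <- match_fixels(subj, tmpl)
  expect_equal(m[1], 1L)        # near-z matches z
  expect_true(is.na(m[2]))      # x has no subject fixel within 45 degrees
  expect_equal(length(match_fixels(subj, tmpl[0, ])), 0L)
})
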