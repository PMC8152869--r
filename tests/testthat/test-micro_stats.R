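test_that("tensor metrics match closed forms", {
  iso <- tensor_metrics(c(1, 1, 1))
  expect_equal(unlist(iso), c(fa = 0, md = 1, ad = 1, rd = 1))

  stick <- tensor_metrics(c(1, 0, 0))
  expect_equal(stick$fa, 1)
  expect_equal(stick$md, 1 / 3)
  expect_equal(stick$ad, 1)
  expect_equal(stick$rd, 0)

  ev <- c(1.7, 0.3, 0.3) * 1e-3
  tm <- tensor_metrics(ev)
  md <- mean(ev)
  fa_direct <- sqrt(1.5) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
  expect_equal(tm$fa, fa_direct, tolerance = 1e-14)
  expect_equal(tm$md, md)
  expect_equal(tm$rd, 0.3e-3)

  expect_error(tensor_metrics(c(1, -0.1, 0)), "negative")
  expect_error(tensor_metrics(c(0.1, 0.5, 0.2)), "sorted")
})

test_that("FA is scale invariant and bounded", {
  set.seed(3)
  for (i in 1:50) {
    ev <- sort(runif(3, 0, 2), decreasing = TRUE)
    f1 <- tensor_metrics(ev)$fa
    expect_equal(tensor_metrics(ev * runif(1, 0.1, 10))$fa, f1,
                 tolerance = 1e-12)
    expect_gte(f1, 0); expect_lte(f1, 1)
  }
  expect_equal(tensor_metrics(c(0, 0, 0))$fa, 0)
})

test_that("regional aggregation is the masked arithmetic mean", {
  m <- array(0.7, c(4, 4, 4))
  reg <- array(FALSE, c(4, 4, 4)); reg[1:2, 1, 1] <- TRUE
  expect_equal(aggregate_metric(m, reg), 0.7)
  expect_equal(aggregate_metric(c(0.2, 0.4)), 0.3)
  set.seed(1)
  m2 <- array(rnorm(64), c(4, 4, 4))
  reg2 <- array(runif(64) < 0.4, c(4, 4, 4))
  expect_equal(aggregate_metric(m2, reg2), mean(m2[reg2]), tolerance = 1e-14)
  expect_warning(v <- aggregate_metric(m2, array(FALSE, c(4, 4, 4))), "empty")
  expect_true(is.na(v))
})

test_that("BH-FDR matches an independent step-up implementation", {
  bh_oracle <- function(p) {        # textbook step-up, written from scratch
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  expect_true(all(fdr_bh(rep(0.001, 10))$significant))
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.5))
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  r1 <- fdr_bh(0.049)
  expect_equal(r1$q.values, 0.049)
  expect_true(r1$significant)
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    worst <- max(worst, max(abs(fdr_bh(p)$q.values - bh_oracle(p))))
  }
  expect_lt(worst, 1e-14)   # identical up to float association order
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
})

test_that("residualization is idempotent", {
  set.seed(6)
  Y <- matrix(rnorm(60), 20, 3)
  cv <- data.frame(a = rnorm(20), b = rnorm(20))
  R1 <- thalparc:::residualize(Y, cv)
  R2 <- thalparc:::residualize(R1, cv)
  expect_lt(max(abs(R2 - R1)), 1e-10)
})

test_that("partial correlation matches the textbook recursion", {
  set.seed(11)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  plain <- partial_correlation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p.value, cor.test(x, y)$p.value, tolerance = 1e-9)

  cv <- rnorm(30)
  expect_equal(partial_correlation(x, x, data.frame(z = cv))$r, 1)

  # 8-point dataset with one covariate: r_xy.z recursion
  set.seed(12)
  x8 <- rnorm(8); y8 <- rnorm(8); z8 <- rnorm(8)
  rxy <- cor(x8, y8); rxz <- cor(x8, z8); ryz <- cor(y8, z8)
  recursion <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_correlation(x8, y8, data.frame(z = z8))$r, recursion,
               tolerance = 1e-12)

  expect_error(partial_correlation(rep(1, 10), rnorm(10)), "residual variance")
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   data.frame(a = rnorm(4), b = rnorm(4))),
               "at least")
})

test_that("the group permutation test is deterministic and flags constants", {
  set.seed(13)
  Y <- cbind(sig = c(rnorm(8, 2), rnorm(8, 0)), flat = rep(1, 16),
             noise = rnorm(16))
  g <- rep(c("a", "b"), each = 8)
  r1 <- group_permutation_test(Y, g, n_perm = 299, seed = 5)
  r2 <- group_permutation_test(Y, g, n_perm = 299, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_true(r1$constant[2])
  expect_equal(r1$p[2], 1)
  expect_lt(r1$p[1], 0.01)
  expect_gt(r1$statistic[1], 0)
  expect_error(group_permutation_test(Y, rep("a", 16), n_perm = 10),
               "2 levels")
})

test_that("families partition the FDR correction", {
  set.seed(14)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  g <- rep(c("a", "b"), each = 10)
  fam <- rep(c("f1", "f2"), each = 3)
  r <- group_permutation_test(Y, g, n_perm = 199, seed = 2, families = fam)
  for (f in c("f1", "f2")) {
    sel <- r$family == f
    expect_identical(r$q.value[sel], fdr_bh(r$p[sel])$q.values)
  }
})
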