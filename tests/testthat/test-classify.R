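fake_metric_table <- function(n_sub = 10, regions = c("nucleus1", "nucleus2"),
                              with_pathway = TRUE) {
  metrics <- c("fd", "fc", "fdc", "fa", "md", "ad", "rd", "volume")
  reg <- data.frame(region = regions, region_type = "nucleus")
  if (with_pathway)
    reg <- rbind(reg, data.frame(region = "pathway1",
                                 region_type = "pathway"))
  reg <- rbind(reg, data.frame(region = "whole", region_type = "whole"))
  ci <- do.call(rbind, lapply(seq_len(nrow(reg)), function(r)
    data.frame(region = reg$region[r], metric = metrics,
               region_type = reg$region_type[r])))
  X <- matrix(rnorm(n_sub * nrow(ci)), n_sub)
  colnames(X) <- paste(ci$region, ci$metric, sep = "_")
  attr(X, "colinfo") <- ci
  X
}

test_that("feature assembly excludes volume and pathways, supports whole mode", {
  set.seed(1)
  mt <- fake_metric_table()
  X <- build_features(mt, "regions")
  expect_equal(ncol(X), 2 * 7)              # 2 nuclei x 7 metrics
  expect_false(any(grepl("volume", colnames(X))))
  expect_false(any(grepl("pathway", colnames(X))))
  W <- build_features(mt, "whole")
  expect_equal(ncol(W), 7)
  # determinism: identical tables give identical matrices
  expect_identical(build_features(mt, "regions"), X)
  mt2 <- mt; mt2[2, 3] <- NA
  expect_error(build_features(mt2, "regions"), "missing")
})

test_that("14 nuclei x 7 metrics gives 98 columns", {
  mt <- fake_metric_table(regions = paste0("nucleus", 1:14),
                          with_pathway = FALSE)
  expect_equal(ncol(build_features(mt, "regions")), 98)
})

test_that("cross-validation separates wide-margin classes and not shuffles", {
  set.seed(21)
  n <- 12
  y <- rep(c("A", "B"), each = n / 2)
  X <- cbind(ifelse(y == "A", 5, -5) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 5), n))
  cv <- crossval_classify(X, y, seed = 3)
  expect_gte(cv$mean, 0.95)
  expect_length(cv$accuracies, 60)

  # label-independent features: accuracy near chance (averaged over folds)
  y_shuffled <- sample(y)
  Xn <- matrix(rnorm(n * 6), n)
  null_acc <- mean(vapply(1:5, function(s)
    crossval_classify(Xn, y_shuffled, seed = s)$mean, numeric(1)))
  expect_lt(abs(null_acc - 0.5), 0.2)
  cv2 <- crossval_classify(X, y, seed = 3)
  expect_identical(cv$accuracies, cv2$accuracies)
  expect_error(crossval_classify(X[1:4, ], c("A", "A", "A", "B"),
                                 n_folds = 3), "fewer members")
})

test_that("held-out rows never influence the fitted fold model", {
  set.seed(31)
  Xtr <- matrix(rnorm(8 * 6), 8)
  ytr <- factor(rep(c("A", "B"), each = 4))
  Xte <- matrix(rnorm(2 * 6), 2)
  f1 <- thalparc:::fit_logistic_fold(Xtr, ytr, Xte, 10^seq(0, -3, length = 8))
  poisoned <- Xte * 1e6 + 1e6
  f2 <- thalparc:::fit_logistic_fold(Xtr, ytr, poisoned,
                                     10^seq(0, -3, length = 8))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("stronger L1 penalties never add nonzero coefficients", {
  set.seed(41)
  X <- matrix(rnorm(30 * 10), 30)
  y <- factor(rep(c("A", "B"), 15))
  lam <- 10^seq(0.5, -3, length = 12)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = lam)
  nz <- colSums(as.matrix(fit$beta) != 0)
  expect_true(all(diff(nz) >= 0))       # lambda decreasing along the path
})

test_that("PCA embedding matches an eigendecomposition oracle", {
  set.seed(51)
  # collinear data: one component explains everything
  t <- rnorm(20)
  line <- cbind(t, 2 * t, -t) + 0
  suppressWarnings(pl <- pca_embed(line, 3))
  expect_equal(pl$explained[1], 1, tolerance = 1e-10)

  X <- matrix(rnorm(5 * 4), 5, 4)
  p <- pca_embed(X, 3)
  Z <- scale(X)
  ev <- sort(eigen(cov(Z))$values, decreasing = TRUE)
  expect_equal(p$explained, (ev / sum(ev))[1:3], tolerance = 1e-10)
  # spectrum invariant to column permutation and sign flips (the
  # orthogonal maps that commute with per-column standardization)
  perm <- sample(4)
  p2 <- pca_embed(sweep(X[, perm], 2, c(1, -1, 1, -1), "*"), 3)
  expect_equal(p2$explained, p$explained, tolerance = 1e-8)
  # sign canonicalization: largest-magnitude loading positive
  for (j in 1:3)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_warning(pca_embed(cbind(t, t), 3), "rank")
})
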