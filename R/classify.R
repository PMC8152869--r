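## Sparse (L1) logistic classification of clinical groups from regional
## metric features, under repeated stratified 3-fold cross-validation, and
## PCA embedding for visualization.

#' Assemble a feature matrix from a metric table
#'
#' Selects the (region, metric) columns appropriate for classification:
#' volume columns are always excluded, pathway regions are excluded (only
#' nuclei or whole-thalamus means are used), and in \code{"whole"} mode the
#' per-nucleus columns are collapsed to the whole-thalamus mean per metric.
#'
#' @param metric_table Subjects x columns matrix as produced by
#'   \code{\link{compute_metric_table}} (needs attribute \code{"colinfo"}
#'   with per-column \code{region}, \code{metric}, \code{region_type}).
#' @param mode \code{"regions"} (one column per nucleus x metric; used for
#'   the individual / consensus / atlas parcellation tables) or
#'   \code{"whole"}.
#' @return Numeric feature matrix with attribute \code{"colinfo"}.
#' @export
build_features <- function(metric_table, mode = c("regions", "whole")) {
  mode <- match.arg(mode)
  ci <- attr(metric_table, "colinfo")
  if (is.null(ci)) stop("metric_table lacks a 'colinfo' attribute")
  keep <- ci$metric != "volume" & ci$region_type == "nucleus"
  X <- metric_table[, keep, drop = FALSE]
  ci <- ci[keep, , drop = FALSE]
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("missing metric for subject ", rownames(X)[bad[1]] %||% bad[1],
         ", column ", colnames(X)[bad[2]] %||% bad[2])
  }
  if (mode == "whole") {
    mets <- unique(ci$metric)
    W <- vapply(mets, function(m)
      rowMeans(X[, ci$metric == m, drop = FALSE]), numeric(nrow(X)))
    colnames(W) <- paste0("whole_", mets)
    ci <- data.frame(region = "whole", metric = mets, region_type = "whole")
    X <- W
  }
  attr(X, "colinfo") <- ci
  X
}

## Stratified fold assignment: within each class, a random permutation is
## dealt round-robin into n_folds.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds)
      stop("class '", cl, "' has fewer members than folds")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated sparse logistic classification
#'
#' Per repeat: a stratified shuffle into \code{n_folds} folds; per fold:
#' features are standardized on the training rows only, an L1-penalized
#' logistic model (glmnet) is fitted with the penalty chosen by an inner
#' stratified 2-fold validation over a log-spaced grid, and the held-out
#' rows are predicted. Accuracy is recorded per fold. Deterministic given
#' the seed.
#'
#' @param features Subjects x features numeric matrix.
#' @param labels Two-level factor / vector.
#' @param n_folds Outer folds (default 3).
#' @param n_repeats Repeats of the fold shuffle (default 20).
#' @param seed Integer seed.
#' @param lambda Penalty grid (default \code{10^seq(0, -3, length = 8)}).
#' @return Object of class \code{thalparc_cv}: \code{accuracies} (length
#'   \code{n_folds * n_repeats}), \code{mean}, \code{sd}, \code{predictions}
#'   (out-of-fold majority vote per subject).
#' @export
crossval_classify <- function(features, labels, n_folds = 3, n_repeats = 20,
                              seed = 1L, lambda = 10^seq(0, -3, length = 8)) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("'labels' must have exactly 2 levels")
  n <- nrow(X)
  acc <- numeric(0)
  votes <- matrix(0L, n, 2)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      fold <- stratified_folds(y, n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        res <- fit_logistic_fold(X[tr, , drop = FALSE], y[tr],
                                 X[!tr, , drop = FALSE], lambda)
        acc <- c(acc, mean(res$pred == as.character(y[!tr])))
        hit <- match(res$pred, levels(y))
        votes[cbind(which(!tr), hit)] <- votes[cbind(which(!tr), hit)] + 1L
      }
    }
  })
  predictions <- factor(levels(y)[max.col(votes, ties.method = "first")],
                        levels = levels(y))
  structure(list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 predictions = predictions, n_folds = n_folds,
                 n_repeats = n_repeats, levels = levels(y), seed = seed),
            class = "thalparc_cv")
}

## Fit one cross-validation fold: standardize on the training rows only,
## select the L1 penalty by inner leave-one-out deviance, fit, and predict
## the held-out rows. The held-out rows enter only at predict time.
fit_logistic_fold <- function(Xtr, ytr, Xte, lambda) {
  mu <- colMeans(Xtr)
  sd0 <- apply(Xtr, 2, stats::sd)
  sd0[sd0 == 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sd0, "/")
  Zte <- sweep(sweep(Xte, 2, mu), 2, sd0, "/")
  lam <- pick_lambda(Ztr, ytr, lambda)
  ## glmnet warns about tiny class counts on every call at these n
  fit <- suppressWarnings(glmnet::glmnet(Ztr, ytr, family = "binomial",
                                         alpha = 1, lambda = lambda,
                                         standardize = FALSE))
  list(pred = drop(predict(fit, Zte, s = lam, type = "class")),
       coefficients = as.numeric(as.matrix(
         predict(fit, s = lam, type = "coefficients"))),
       lambda = lam)
}

## Inner leave-one-out selection of the L1 penalty by held-out binomial
## deviance (log-loss); with the small training sets here LOO is much more
## stable than an inner k-fold split.
pick_lambda <- function(Z, y, lambda) {
  n <- nrow(Z)
  err <- matrix(NA_real_, n, length(lambda))
  y2 <- levels(factor(y))[2]
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (min(table(factor(y[tr]))) < 2) next   # glmnet needs >= 2 per class
    fit <- suppressWarnings(glmnet::glmnet(Z[tr, , drop = FALSE], y[tr],
                                           family = "binomial", alpha = 1,
                                           lambda = lambda,
                                           standardize = FALSE))
    pr <- predict(fit, Z[i, , drop = FALSE], s = lambda, type = "response")
    pr <- pmin(pmax(pr, 1e-6), 1 - 1e-6)
    yt <- as.numeric(y[i] == y2)
    err[i, ] <- -(yt * log(pr) + (1 - yt) * log(1 - pr))
  }
  m <- colMeans(err, na.rm = TRUE)
  if (all(!is.finite(m))) return(lambda[ceiling(length(lambda) / 2)])
  lambda[which.min(m)]
}

#' @export
print.thalparc_cv <- function(x, ...) {
  cat(sprintf(
    "Sparse logistic CV (%s vs %s): mean accuracy %.1f%% (sd %.1f%%), %d folds x %d repeats\n",
    x$levels[1], x$levels[2], 100 * x$mean, 100 * x$sd, x$n_folds,
    x$n_repeats))
  invisible(x)
}

#' PCA embedding of a feature matrix
#'
#' Columns are z-scored (constant columns are dropped), subjects are
#' projected on the top principal components, and each component's sign is
#' canonicalized so its largest-magnitude loading is positive.
#'
#' @param features Subjects x features numeric matrix.
#' @param n_components Number of components (default 3; fewer are returned
#'   with a warning if the matrix has lower rank).
#' @return List with \code{scores} (subjects x components),
#'   \code{explained} (variance fractions), \code{loadings}.
#' @export
pca_embed <- function(features, n_components = 3) {
  X <- as.matrix(features)
  sd0 <- apply(X, 2, stats::sd)
  X <- X[, sd0 > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  nc <- min(n_components, ncol(pc$rotation))
  if (nc < n_components)
    warning("feature rank ", ncol(pc$rotation), " < ", n_components,
            " components; returning ", nc)
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  sc <- pc$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  list(scores = sc, explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)],
       loadings = rot)
}
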