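## Diffusion-tensor metrics, regional aggregation, covariate-adjusted
## two-group permutation testing with BH-FDR, and partial correlation.

#' Scalar tensor metrics from eigenvalues
#'
#' Standard diffusion-tensor summaries: MD = (l1+l2+l3)/3, AD = l1,
#' RD = (l2+l3)/2, FA = sqrt(3/2) * ||l - MD|| / ||l||, with FA of an
#' all-zero tensor defined as 0. FA is scale-invariant and lies in [0, 1].
#'
#' @param eigs n x 3 matrix (or length-3 vector) of eigenvalues sorted
#'   descending, non-negative (mm^2/s).
#' @return Data frame with columns \code{fa, md, ad, rd}.
#' @export
tensor_metrics <- function(eigs) {
  eigs <- rbind(eigs)
  if (ncol(eigs) != 3L) stop("'eigs' must have 3 columns")
  if (any(eigs < 0)) stop("negative eigenvalue")
  if (any(eigs[, 1] < eigs[, 2] - 1e-12 | eigs[, 2] < eigs[, 3] - 1e-12))
    stop("eigenvalues must be sorted descending")
  md <- rowMeans(eigs)
  ad <- eigs[, 1]
  rd <- (eigs[, 2] + eigs[, 3]) / 2
  num <- sqrt(rowSums((eigs - md)^2))
  den <- sqrt(rowSums(eigs^2))
  fa <- ifelse(den == 0, 0, sqrt(1.5) * num / den)
  data.frame(fa = fa, md = md, ad = ad, rd = rd)
}

#' Regional mean of a voxel metric
#'
#' @param x 3D scalar array (voxel map) or a numeric vector of per-fixel
#'   values.
#' @param region 3D logical array selecting the region (for a voxel map), or
#'   omitted for a fixel-value vector.
#' @return Scalar arithmetic mean (NA with a warning for an empty region).
#' @export
aggregate_metric <- function(x, region = NULL) {
  v <- if (is.null(region)) x else x[region]
  if (length(v) == 0L) { warning("empty region"); return(NA_real_) }
  mean(v)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment with significance flags at level \code{q}.
#'
#' @param pvals P-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{q.values} (BH-adjusted) and \code{significant}.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(pvals, method = "BH")
  list(q.values = qv, significant = qv <= q)
}

## Residualize columns of Y on covariates (with intercept); X = NULL or
## empty leaves Y centered only by the intercept fit.
residualize <- function(Y, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- if (is.null(covariates) || NCOL(covariates) == 0) matrix(1, n, 1)
       else {
         C <- as.matrix(covariates)
         ## center/scale for numerical conditioning (residuals unchanged)
         C <- scale(C, center = TRUE, scale = apply(C, 2, function(x)
           max(stats::sd(x), 1e-12)))
         cbind(1, C)
       }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariate matrix")
  qr.resid(qx, Y)
}

#' Covariate-adjusted two-group permutation test over a metric table
#'
#' For every column, covariates are regressed out on the pooled sample, the
#' statistic is the difference of group means of the residuals, and the null
#' is built by permuting group labels \code{n_perm} times (residualize-then-
#' permute). Two-sided p-values use the add-one convention; BH-FDR is applied
#' within each family given by \code{families} (one family per metric by
#' default usage), or globally when \code{families} is NULL.
#'
#' @param table Subjects x columns numeric matrix (regions x metrics).
#' @param groups Two-level factor / vector of group labels (both >= 3).
#' @param covariates Optional numeric covariate data frame / matrix.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @param q FDR level (default 0.05).
#' @param families Optional vector (length = ncol) naming the FDR family of
#'   each column.
#' @return Data frame of class \code{thalparc_stats}: per column the observed
#'   mean difference (group1 - group2 of residuals), permutation \code{p},
#'   BH \code{q.value} and \code{significant} flag; constant columns get
#'   p = 1 and \code{constant = TRUE}.
#' @export
group_permutation_test <- function(table, groups, covariates = NULL,
                                   n_perm = 2000, seed = 1L, q = 0.05,
                                   families = NULL) {
  Y <- as.matrix(table)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("'groups' must have exactly 2 levels")
  if (any(table(g) < 3)) stop("both groups need at least 3 subjects")
  n <- nrow(Y)
  R <- residualize(Y, covariates)
  i1 <- g == levels(g)[1]
  n1 <- sum(i1); n2 <- n - n1
  wobs <- ifelse(i1, 1 / n1, -1 / n2)
  obs <- drop(crossprod(R, wobs))
  W <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) wobs[sample.int(n)], numeric(n))
  })
  nullmat <- crossprod(R, W)                       # ncol x n_perm
  constant <- apply(R, 2, function(col) stats::sd(col) == 0)
  p <- vapply(seq_len(ncol(Y)), function(j)
    (1 + sum(abs(nullmat[j, ]) >= abs(obs[j]) - 1e-12)) / (n_perm + 1),
    numeric(1))
  p[constant] <- 1
  fam <- if (is.null(families)) rep("all", ncol(Y)) else as.character(families)
  qv <- numeric(ncol(Y))
  for (f in unique(fam)) {
    sel <- fam == f
    qv[sel] <- fdr_bh(p[sel], q)$q.values
  }
  out <- data.frame(column = colnames(Y) %||% paste0("V", seq_len(ncol(Y))),
                    family = fam, statistic = obs, p = p, q.value = qv,
                    significant = qv <= q, constant = constant,
                    row.names = NULL)
  attr(out, "n_perm") <- n_perm
  attr(out, "groups") <- levels(g)
  class(out) <- c("thalparc_stats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thalparc_stats <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf(
    "Covariate-adjusted permutation test (%s - %s, %d permutations)\n",
    gr[1], gr[2], attr(x, "n_perm")))
  cat(sprintf("  %d/%d columns significant after BH-FDR\n",
              sum(x$significant), nrow(x)))
  NextMethod()
}

#' Partial correlation with covariates
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after
#' linear regression on the covariates (with intercept); the p-value uses
#' the t distribution with \code{n - n_covariates - 2} degrees of freedom.
#' Without covariates this is the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric covariate data frame / matrix.
#' @return List with \code{r}, \code{df}, \code{p.value}.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  ncov <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < ncov + 3) stop("need at least ", ncov + 3, " observations")
  rx <- drop(residualize(x, covariates))
  ry <- drop(residualize(y, covariates))
  if (stats::sd(rx) < 1e-10 * max(1, stats::sd(x)) ||
      stats::sd(ry) < 1e-10 * max(1, stats::sd(y)))
    stop("zero residual variance: partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - ncov - 2
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(r = r, df = df, p.value = min(1, p))
}
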