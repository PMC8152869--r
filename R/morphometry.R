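## Tensor-based morphometry of thalamic nuclei: voxelwise Jacobians of a
## deformation field, log-determinant shape maps, per-nucleus aggregation,
## volumetric-ratio changes and the covariate-adjusted one-sample test.

## Finite-difference gradient of a 3D scalar array along one axis:
## central differences in the interior, one-sided at the borders.
fd_gradient <- function(a, axis, spacing = 1) {
  d <- dim(a)
  n <- d[axis]
  if (n < 2) stop("need at least 2 voxels along axis ", axis)
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  sel <- function(ix) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- ix
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  ## per-voxel step (2h in the interior, h at the two borders)
  step <- (idx_p - idx_m) * spacing
  perm <- c(axis, setdiff(1:3, axis))
  sw <- aperm(array(step, dim = c(n, d[-axis])), order(perm))
  (sel(idx_p) - sel(idx_m)) / sw
}

#' Voxelwise Jacobian matrices of a deformation field
#'
#' The field is a displacement volume \code{u} on the template grid (the warp
#' pushes template space into subject space); the local Jacobian is
#' \code{J = I + du/dx}, computed by central finite differences in the
#' interior and one-sided differences at the borders, scaled by the voxel
#' size.
#'
#' @param field 4D array (x, y, z, 3) of displacements in mm.
#' @param voxel_size Length-3 voxel size in mm (default 1).
#' @return 5D array (x, y, z, 3, 3) of Jacobian matrices.
#' @export
jacobian_field <- function(field, voxel_size = c(1, 1, 1)) {
  d <- dim(field)
  if (length(d) != 4L || d[4] != 3L) stop("'field' must be (x, y, z, 3)")
  J <- array(0, c(d[1:3], 3, 3))
  for (m in 1:3) {
    um <- field[, , , m]
    for (a in 1:3) {
      g <- fd_gradient(um, a, voxel_size[a])
      J[, , , m, a] <- g + (m == a)
    }
  }
  J
}

#' Log-Jacobian determinant of a deformation field
#'
#' Shape-change map of the warp: values above 0 mark local expansion of the
#' subject relative to the template, below 0 shrinkage.
#'
#' @inheritParams jacobian_field
#' @param mask Optional 3D logical array; the diffeomorphism check
#'   (\code{det J > 0}) is enforced on these voxels (everywhere if omitted).
#' @return 3D array of \eqn{\ln \det J} (NA where the determinant is
#'   non-positive outside the mask).
#' @export
log_jacobian <- function(field, voxel_size = c(1, 1, 1), mask = NULL) {
  J <- jacobian_field(field, voxel_size)
  a <- J[, , , 1, 1]; b <- J[, , , 1, 2]; c3 <- J[, , , 1, 3]
  d4 <- J[, , , 2, 1]; e <- J[, , , 2, 2]; f <- J[, , , 2, 3]
  g <- J[, , , 3, 1]; h <- J[, , , 3, 2]; i9 <- J[, , , 3, 3]
  det <- a * (e * i9 - f * h) - b * (d4 * i9 - f * g) + c3 * (d4 * h - e * g)
  check <- if (is.null(mask)) rep(TRUE, length(det)) else as.logical(mask)
  if (any(det[check] <= 0)) {
    bad <- which(array(det <= 0, dim(det)) & array(check, dim(det)),
                 arr.ind = TRUE)
    stop("folding deformation: non-positive Jacobian determinant at ",
         nrow(bad), " voxel(s), first at (",
         paste(bad[1, ], collapse = ", "), ")")
  }
  out <- array(NA_real_, dim(det))
  pos <- det > 0
  out[pos] <- log(det[pos])
  out
}

#' Per-nucleus mean log-Jacobian
#'
#' @param logj 3D scalar array (e.g. from \code{\link{log_jacobian}}).
#' @param parcellation A \code{thalamic_parcellation} or 3D integer label
#'   array (0 = background).
#' @return Named numeric vector of per-nucleus means (NA with a warning for
#'   empty nuclei).
#' @export
nucleus_shape_stats <- function(logj, parcellation) {
  labels <- parcellation_labels(parcellation)
  k <- max(labels)
  out <- vapply(seq_len(k), function(j) {
    v <- logj[labels == j]
    if (length(v) == 0L) { warning("nucleus ", j, " is empty"); NA_real_ }
    else mean(v)
  }, numeric(1))
  names(out) <- paste0("nucleus", seq_len(k))
  out
}

#' Per-nucleus volumetric ratio between two parcellations
#'
#' @param subject,reference Parcellations with matched labels (see
#'   \code{\link{match_labels}}).
#' @param voxel_volume_subject,voxel_volume_reference Voxel volumes in mm^3
#'   (default 1).
#' @return Named vector of subject/reference volume ratios per nucleus.
#' @export
volume_ratio_change <- function(subject, reference,
                                voxel_volume_subject = 1,
                                voxel_volume_reference = 1) {
  sl <- parcellation_labels(subject)
  rl <- parcellation_labels(reference)
  k <- max(rl)
  ns <- tabulate(sl[sl > 0], nbins = k)
  nr <- tabulate(rl[rl > 0], nbins = k)
  if (any(nr == 0)) stop("empty reference nucleus: ",
                         paste(which(nr == 0), collapse = ", "))
  out <- (ns * voxel_volume_subject) / (nr * voxel_volume_reference)
  names(out) <- paste0("nucleus", seq_len(k))
  out
}

#' Covariate-adjusted one-sample t-test
#'
#' Tests whether the mean of \code{values} differs from zero after adjusting
#' for covariates: fits \code{value ~ intercept + centered covariates} and
#' tests the intercept with a two-sided t-test (residual degrees of freedom
#' \code{n - p}). With no covariates this is exactly the classical
#' one-sample t-test. Covariates are mean-centered so the intercept is the
#' covariate-adjusted mean.
#'
#' @param values Numeric vector of per-subject scalars.
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @return List with \code{estimate} (adjusted mean), \code{t}, \code{df},
#'   \code{p.value}.
#' @export
covariate_adjusted_one_sample_test <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1)
  } else {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariate rows must match length(values)")
    C <- scale(C, center = TRUE, scale = FALSE)
    X <- cbind(1, C)
  }
  if (n < ncol(X) + 1) stop("need at least ", ncol(X) + 1, " observations")
  if (qr(X)$rank < ncol(X)) stop("collinear covariate matrix")
  fit <- stats::lm.fit(X, values)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[1, 1])
  est <- fit$coefficients[1]
  t <- if (se == 0) { if (est == 0) 0 else sign(est) * Inf } else est / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(estimate = unname(est), t = unname(t), df = df, p.value = unname(p))
}
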