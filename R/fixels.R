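## Fixel (fiber-population) extraction from FOD spherical functions and the
## fixel metrics FD (apparent fiber density), FC (fiber-bundle cross-section)
## and FDC = FD * FC.

## Canonicalize an antipodally symmetric direction: non-negative z,
## ties broken by non-negative y then x.
canonical_direction <- function(d) {
  d <- d / sqrt(sum(d^2))
  if (d[3] < 0 || (d[3] == 0 && (d[2] < 0 || (d[2] == 0 && d[1] < 0)))) -d else d
}

#' Extract fixels (FOD lobes) from one voxel's SH coefficients
#'
#' The FOD is sampled on the basis tessellation (negative amplitudes, i.e.
#' ringing, are clipped to zero), peaks are local maxima above
#' \code{peak_threshold} times the global maximum, every positive sample is
#' assigned to the nearest peak under the antipodal angular metric, and the
#' apparent fiber density (FD) of a fixel is the quadrature integral of the
#' amplitude over its lobe (both antipodal half-lobes). An FOD with no
#' distinct peak (constant amplitude) yields a single "peakless" fixel along
#' +z carrying the full spherical integral.
#'
#' @param coeffs SH coefficient vector.
#' @param basis An \code{\link{sh_basis}}.
#' @param peak_threshold Fraction of the per-voxel maximum amplitude below
#'   which local maxima are ignored (default 0.1).
#' @param max_fixels Maximum number of fixels kept, sorted by descending FD
#'   (default 3).
#' @return A data frame with one row per fixel: canonical unit direction
#'   (\code{dx, dy, dz}), \code{fd}, and a \code{peakless} flag. Zero rows if
#'   all amplitudes are non-positive.
#' @export
extract_fixels <- function(coeffs, basis, peak_threshold = 0.1, max_fixels = 3) {
  amp <- drop(basis$B %*% coeffs)
  amp[amp < 0] <- 0
  empty <- data.frame(dx = numeric(0), dy = numeric(0), dz = numeric(0),
                      fd = numeric(0), peakless = logical(0))
  amax <- max(amp)
  if (amax <= 0) return(empty)
  total <- sum(amp * basis$weights)
  if ((amax - min(amp)) <= 1e-8 * amax) {      # no distinct peak: isotropic
    return(data.frame(dx = 0, dy = 0, dz = 1, fd = total, peakless = TRUE))
  }
  nb <- basis$neighbors
  is_peak <- vapply(seq_along(amp), function(i)
    amp[i] > peak_threshold * amax && all(amp[i] >= amp[nb[[i]]]),
    logical(1))
  peak_idx <- which(is_peak)
  if (length(peak_idx) == 0L) {                # plateau fallback
    return(data.frame(dx = 0, dy = 0, dz = 1, fd = total, peakless = TRUE))
  }
  ## merge antipodal / near-duplicate peaks (angular distance < 15 degrees
  ## under antipodal symmetry), keeping the higher-amplitude representative
  peak_idx <- peak_idx[order(-amp[peak_idx])]
  dirs <- basis$directions
  kept <- integer(0)
  for (p in peak_idx) {
    dup <- FALSE
    for (q in kept) {
      if (abs(sum(dirs[p, ] * dirs[q, ])) > cos(15 * pi / 180)) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, p)
  }
  ## assign every positive sample to the nearest peak (antipodal metric)
  pos <- which(amp > 0)
  cosang <- abs(dirs[pos, , drop = FALSE] %*% t(dirs[kept, , drop = FALSE]))
  assign <- max.col(cosang, ties.method = "first")
  fd <- vapply(seq_along(kept), function(j)
    sum(amp[pos[assign == j]] * basis$weights[pos[assign == j]]), numeric(1))
  lobe_n <- tabulate(assign, nbins = length(kept))
  ord <- order(-fd)
  ord <- ord[seq_len(min(max_fixels, length(ord)))]
  if (any(lobe_n[ord] < 5))
    warning("a retained fixel lobe contains fewer than 5 sphere samples; ",
            "increase the tessellation level")
  dmat <- t(vapply(kept[ord], function(p) canonical_direction(dirs[p, ]),
                   numeric(3)))
  data.frame(dx = dmat[, 1], dy = dmat[, 2], dz = dmat[, 3],
             fd = fd[ord], peakless = FALSE)
}

#' Fiber-bundle cross-section from a warp Jacobian
#'
#' FC is the change in area of the plane perpendicular to the fixel
#' direction under the local affine approximation \code{J} of the
#' template-to-subject warp: \code{FC = |det J| / ||J d||}.
#'
#' @param direction Unit 3-vector (fixel direction).
#' @param jacobian 3 x 3 local Jacobian matrix, \code{det > 0}.
#' @return Positive scalar cross-section factor.
#' @export
fixel_fc <- function(direction, jacobian) {
  direction <- direction / sqrt(sum(direction^2))
  dj <- det(jacobian)
  if (!is.finite(dj) || dj <= 0)
    stop("degenerate warp: Jacobian determinant must be positive")
  abs(dj) / sqrt(sum((jacobian %*% direction)^2))
}

#' Combined fiber density and cross-section
#'
#' @param fd Non-negative apparent fiber density.
#' @param fc Positive cross-section factor.
#' @return \code{fd * fc}.
#' @export
fdc <- function(fd, fc) {
  if (any(fd < 0)) stop("'fd' must be non-negative")
  if (any(fc <= 0)) stop("'fc' must be positive")
  fd * fc
}

#' Voxelwise fixel table for a masked FOD image
#'
#' Runs \code{\link{extract_fixels}} over every masked voxel and, when a
#' deformation field is supplied, attaches FC (from the local warp Jacobian)
#' and FDC to each fixel.
#'
#' @param fod 4D array (x, y, z, n_coeff) of SH coefficients.
#' @param mask 3D logical array of voxels to process.
#' @param basis An \code{\link{sh_basis}}.
#' @param field Optional deformation field (x, y, z, 3) used for FC.
#' @param voxel_size Voxel size (mm) passed to the Jacobian computation.
#' @param peak_threshold,max_fixels Passed to \code{\link{extract_fixels}}.
#' @return Data frame with voxel index columns (\code{i, j, k}, 1-based),
#'   fixel direction, \code{fd} and (if \code{field} given) \code{fc, fdc}.
#' @export
fixel_table <- function(fod, mask, basis, field = NULL, voxel_size = c(1, 1, 1),
                        peak_threshold = 0.1, max_fixels = 3) {
  vox <- which(mask, arr.ind = TRUE)
  flat <- matrix(fod, nrow = prod(dim(fod)[1:3]), ncol = dim(fod)[4])
  coeffs <- flat[which(mask), , drop = FALSE]
  Jfield <- if (!is.null(field)) jacobian_field(field, voxel_size) else NULL
  nv <- nrow(vox)
  ## batched amplitude sampling and neighbor-max computation (voxels x samples)
  AMP <- coeffs %*% t(basis$B)
  AMP[AMP < 0] <- 0
  NBmax <- matrix(-Inf, nv, ncol(AMP))
  for (s in seq_len(ncol(AMP))) {
    nb <- basis$neighbors[[s]]
    m <- AMP[, nb[1]]
    for (q in nb[-1]) m <- pmax(m, AMP[, q])
    NBmax[, s] <- m
  }
  vmax <- apply(AMP, 1, max)
  ispeak <- AMP >= NBmax & AMP > peak_threshold * pmax(vmax, 0) & AMP > 0
  dirs <- basis$directions
  w <- basis$weights
  cos15 <- cos(15 * pi / 180)
  cap <- nv * max_fixels
  o_dir <- matrix(0, cap, 3)
  o_fd <- numeric(cap)
  o_peakless <- logical(cap)
  o_vox <- integer(cap)
  nrec <- 0L
  for (v in seq_len(nv)) {
    amp <- AMP[v, ]
    if (vmax[v] <= 0) next
    if ((vmax[v] - min(amp)) <= 1e-8 * vmax[v] || !any(ispeak[v, ])) {
      nrec <- nrec + 1L
      o_dir[nrec, ] <- c(0, 0, 1)
      o_fd[nrec] <- sum(amp * w)
      o_peakless[nrec] <- TRUE
      o_vox[nrec] <- v
    } else {
      pk <- which(ispeak[v, ])
      pk <- pk[order(-amp[pk])]
      kept <- integer(0)
      for (p in pk) {
        dup <- FALSE
        for (q in kept)
          if (abs(sum(dirs[p, ] * dirs[q, ])) > cos15) { dup <- TRUE; break }
        if (!dup) kept <- c(kept, p)
      }
      pos <- which(amp > 0)
      cosang <- abs(dirs[pos, , drop = FALSE] %*% t(dirs[kept, , drop = FALSE]))
      grp <- max.col(cosang, ties.method = "first")
      fd <- drop(rowsum(amp[pos] * w[pos], grp))
      ord <- order(-fd)
      ord <- ord[seq_len(min(max_fixels, length(ord)))]
      for (oi in ord) {
        nrec <- nrec + 1L
        o_dir[nrec, ] <- canonical_direction(dirs[kept[oi], ])
        o_fd[nrec] <- fd[oi]
        o_vox[nrec] <- v
      }
    }
  }
  sel <- seq_len(nrec)
  res <- data.frame(dx = o_dir[sel, 1], dy = o_dir[sel, 2],
                    dz = o_dir[sel, 3], fd = o_fd[sel],
                    peakless = o_peakless[sel],
                    i = vox[o_vox[sel], 1], j = vox[o_vox[sel], 2],
                    k = vox[o_vox[sel], 3])
  if (!is.null(Jfield) && nrec > 0) {
    vv <- o_vox[sel]
    Jmat <- matrix(0, nrec, 9)
    for (cidx in 1:9)
      Jmat[, cidx] <- Jfield[cbind(vox[vv, , drop = FALSE],
                                   (cidx - 1L) %% 3L + 1L,
                                   (cidx - 1L) %/% 3L + 1L)]
    Jd1 <- Jmat[, 1] * res$dx + Jmat[, 4] * res$dy + Jmat[, 7] * res$dz
    Jd2 <- Jmat[, 2] * res$dx + Jmat[, 5] * res$dy + Jmat[, 8] * res$dz
    Jd3 <- Jmat[, 3] * res$dx + Jmat[, 6] * res$dy + Jmat[, 9] * res$dz
    detJ <- Jmat[, 1] * (Jmat[, 5] * Jmat[, 9] - Jmat[, 8] * Jmat[, 6]) -
      Jmat[, 4] * (Jmat[, 2] * Jmat[, 9] - Jmat[, 8] * Jmat[, 3]) +
      Jmat[, 7] * (Jmat[, 2] * Jmat[, 6] - Jmat[, 5] * Jmat[, 3])
    if (any(detJ <= 0))
      stop("degenerate warp: non-positive Jacobian determinant at ",
           sum(detJ <= 0), " fixel(s)")
    res$fc <- abs(detJ) / sqrt(Jd1^2 + Jd2^2 + Jd3^2)
    res$fdc <- res$fd * res$fc
  } else if (!is.null(Jfield)) {
    res$fc <- numeric(0)
    res$fdc <- numeric(0)
  }
  res
}

#' Match subject fixels to template fixels by angular distance
#'
#' Each template fixel is matched to the closest subject fixel within
#' \code{max_angle} degrees (antipodal metric); unmatched template fixels get
#' \code{NA} and contribute nothing to aggregation.
#'
#' @param subject,template Data frames with columns \code{dx, dy, dz} (one
#'   voxel's fixels each).
#' @param max_angle Maximum angular distance in degrees (default 45).
#' @return Integer vector: for each template fixel, the row index of the
#'   matched subject fixel or \code{NA}.
#' @export
match_fixels <- function(subject, template, max_angle = 45) {
  if (nrow(template) == 0L) return(integer(0))
  if (nrow(subject) == 0L) return(rep(NA_integer_, nrow(template)))
  S <- as.matrix(subject[, c("dx", "dy", "dz")])
  Tm <- as.matrix(template[, c("dx", "dy", "dz")])
  cosang <- abs(Tm %*% t(S))
  best <- max.col(cosang, ties.method = "first")
  ok <- cosang[cbind(seq_len(nrow(Tm)), best)] >= cos(max_angle * pi / 180)
  ifelse(ok, best, NA_integer_)
}
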