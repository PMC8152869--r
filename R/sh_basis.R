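#' Number of even-order real spherical-harmonic basis functions
#'
#' An antipodally symmetric spherical function (such as a fiber orientation
#' distribution) only needs even harmonic orders, giving
#' \eqn{(l_{max}+1)(l_{max}+2)/2} real basis functions; \code{lmax = 6}
#' yields 28 coefficients per voxel.
#'
#' @param lmax Even, non-negative maximum harmonic order.
#' @return Integer number of basis functions.
#' @examples
#' sh_basis_size(6)  # 28
#' @export
sh_basis_size <- function(lmax) {
  if (length(lmax) != 1L || !is.finite(lmax) || lmax < 0 || lmax %% 2 != 0)
    stop("'lmax' must be a single even non-negative integer")
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

## (l, m) index pairs in MRtrix-style ordering: l = 0, 2, ..., lmax;
## within each l, m runs -l..l.
sh_index_table <- function(lmax) {
  l <- unlist(lapply(seq(0, lmax, by = 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, lmax, by = 2), function(li) seq(-li, li)))
  data.frame(l = l, m = m)
}

## Real, orthonormal even-order SH design matrix for unit directions (n x 3).
## Convention: m < 0 -> sqrt(2) * Im(Y_l^|m|), m = 0 -> Y_l^0,
## m > 0 -> sqrt(2) * Re(Y_l^m); associated Legendre from pracma (includes
## the Condon-Shortley phase, which does not affect orthonormality).
sh_matrix <- function(directions, lmax) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("'directions' must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("'directions' must be unit vectors")
  n <- nrow(directions)
  ct <- pmin(1, pmax(-1, directions[, 3]))          # cos(theta)
  phi <- atan2(directions[, 2], directions[, 1])
  idx <- sh_index_table(lmax)
  B <- matrix(0, n, nrow(idx))
  for (li in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(li, ct)                   # (li+1) x n, rows m=0..li
    if (is.null(dim(P))) P <- matrix(P, nrow = li + 1)
    for (mi in seq(-li, li)) {
      am <- abs(mi)
      norm <- sqrt((2 * li + 1) / (4 * pi) *
                   exp(lgamma(li - am + 1) - lgamma(li + am + 1)))
      col <- which(idx$l == li & idx$m == mi)
      if (mi == 0) {
        B[, col] <- norm * P[1, ]
      } else if (mi > 0) {
        B[, col] <- sqrt(2) * norm * P[am + 1, ] * cos(am * phi)
      } else {
        B[, col] <- sqrt(2) * norm * P[am + 1, ] * sin(am * phi)
      }
    }
  }
  B
}

## Unit icosahedron vertices / faces.
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midcache <- new.env(hash = TRUE)
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- midcache[[key]]
    if (!is.null(hit)) return(hit)
    p <- v[i, ] + v[j, ]
    p <- p / sqrt(sum(p^2))
    v <<- rbind(v, p)
    midcache[[key]] <- nrow(v)
    nrow(v)
  }
  nf <- matrix(0L, 4 * nrow(f), 3)
  for (r in seq_len(nrow(f))) {
    a <- f[r, 1]; b <- f[r, 2]; c <- f[r, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf[4 * r - 3, ] <- c(a, ab, ca)
    nf[4 * r - 2, ] <- c(b, bc, ab)
    nf[4 * r - 1, ] <- c(c, ca, bc)
    nf[4 * r, ]     <- c(ab, bc, ca)
  }
  list(vertices = v, faces = nf)
}

## Solid angle of the spherical triangle (a, b, c) (Van Oosterom & Strackee).
spherical_triangle_area <- function(a, b, c) {
  num <- abs(sum(a * pracma::cross(b, c)))
  den <- 1 + sum(a * b) + sum(b * c) + sum(c * a)
  2 * atan2(num, den)
}

#' Even-order spherical-harmonic basis with spherical quadrature
#'
#' Builds the real, even-order, antipodally symmetric SH basis sampled on a
#' subdivided-icosahedron tessellation. Sample directions are face centroids
#' and quadrature weights are the spherical-triangle areas, which sum to
#' \eqn{4\pi}; three subdivisions give the default 1280 directions.
#'
#' @param lmax Even maximum harmonic order (default 6, i.e. 28 coefficients).
#' @param tessellation_level Number of icosahedron subdivisions (default 3).
#' @return An object of class \code{sh_basis}: list with \code{lmax},
#'   \code{n_coeff}, \code{directions} (n x 3), \code{weights} (summing to
#'   \eqn{4\pi}), design matrix \code{B} (n x n_coeff) and face-adjacency
#'   \code{neighbors} used for peak finding.
#' @export
sh_basis <- function(lmax = 6, tessellation_level = 3) {
  n_coeff <- sh_basis_size(lmax)
  mesh <- icosahedron()
  for (i in seq_len(tessellation_level)) mesh <- subdivide_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  ctr <- ctr / sqrt(rowSums(ctr^2))
  w <- vapply(seq_len(nrow(f)), function(r)
    spherical_triangle_area(v[f[r, 1], ], v[f[r, 2], ], v[f[r, 3], ]),
    numeric(1))
  ## faces sharing at least one vertex are neighbors (peak-finding support)
  vert2face <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  neighbors <- lapply(seq_len(nrow(f)), function(r) {
    nb <- unique(unlist(vert2face[as.character(f[r, ])]))
    nb[nb != r]
  })
  structure(list(lmax = lmax, n_coeff = n_coeff, directions = ctr,
                 weights = w, B = sh_matrix(ctr, lmax),
                 neighbors = neighbors,
                 tessellation_level = tessellation_level),
            class = "sh_basis")
}

#' @export
print.sh_basis <- function(x, ...) {
  cat(sprintf("SH basis: lmax = %d (%d coefficients), %d sample directions\n",
              x$lmax, x$n_coeff, nrow(x$directions)))
  invisible(x)
}

#' Evaluate FOD amplitudes along directions
#'
#' @param coeffs SH coefficient vector, or a matrix (rows = voxels).
#' @param directions Unit 3-vectors (n x 3) or an \code{sh_basis} (its sample
#'   directions are used).
#' @return Amplitude vector (or voxels x directions matrix).
#' @export
evaluate_amplitude <- function(coeffs, directions) {
  if (inherits(directions, "sh_basis")) {
    B <- directions$B
    n_coeff <- directions$n_coeff
  } else {
    directions <- rbind(directions)
    n_coeff <- if (is.matrix(coeffs)) ncol(coeffs) else length(coeffs)
    lmax <- lmax_from_ncoeff(n_coeff)
    B <- sh_matrix(directions, lmax)
  }
  if (is.matrix(coeffs)) {
    if (ncol(coeffs) != ncol(B)) stop("coefficient length does not match basis")
    coeffs %*% t(B)
  } else {
    if (length(coeffs) != ncol(B)) stop("coefficient length does not match basis")
    drop(B %*% coeffs)
  }
}

lmax_from_ncoeff <- function(n_coeff) {
  lmax <- (sqrt(8 * n_coeff + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop("coefficient count ", n_coeff, " does not correspond to an even lmax")
  as.integer(round(lmax))
}

#' Project a sampled spherical function onto the SH basis
#'
#' Weighted least-squares fit using the basis quadrature weights; with the
#' orthonormal basis and an adequate tessellation this recovers band-limited
#' coefficients to high precision.
#'
#' @param values Sampled amplitudes at \code{basis$directions} (vector or
#'   matrix with one row per function).
#' @param basis An \code{sh_basis}.
#' @return Coefficient vector (or matrix).
#' @export
sh_fit <- function(values, basis) {
  B <- basis$B
  w <- basis$weights
  BtW <- t(B * w)
  G <- BtW %*% B
  if (is.matrix(values)) t(solve(G, BtW %*% t(values))) else
    drop(solve(G, BtW %*% values))
}
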