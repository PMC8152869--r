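## FOD-based thalamic parcellation: k-means on the hybrid metric
## D = alpha * ||fod_i - fod_j|| + (1 - alpha) * beta * ||pos_i - pos_j||
## with hierarchical (spatial-only) initialization, plus label matching
## across subjects.

#' Clustering configuration for thalamic segmentation
#'
#' @param k Number of nuclei per hemisphere (default 7).
#' @param alpha Weight of the FOD-coefficient distance, in [0, 1]
#'   (default 0.5; the spatial term gets \code{1 - alpha}).
#' @param beta Spatial scale factor bringing voxel-coordinate distances onto
#'   the scale of FOD-coefficient distances (default 85; empirical template
#'   value, configurable per dataset).
#' @param max_iter Maximum k-means iterations (default 300).
#' @param tol Centroid-shift convergence tolerance (default 1e-6).
#' @param seed Stored for provenance; the fit itself is deterministic.
#' @return A list of class \code{clustering_config}.
#' @export
clustering_config <- function(k = 7, alpha = 0.5, beta = 85, max_iter = 300,
                              tol = 1e-6, seed = 1L) {
  stopifnot(k >= 1, alpha >= 0, alpha <= 1, beta > 0, max_iter >= 1, tol >= 0)
  structure(list(k = as.integer(k), alpha = alpha, beta = beta,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

#' Hybrid FOD/spatial distance between voxels
#'
#' \code{D = alpha * ||fod_i - fod_j||_2 + (1 - alpha) * beta *
#' ||pos_i - pos_j||_2}, the clustering metric combining FOD-coefficient
#' dissimilarity with spatial proximity (plain, unsquared Euclidean norms).
#'
#' @param fod_i,fod_j SH coefficient vectors of equal length.
#' @param pos_i,pos_j Voxel coordinates (same frame).
#' @param config A \code{\link{clustering_config}} (supplies alpha, beta).
#' @return Non-negative scalar distance.
#' @export
combined_distance <- function(fod_i, fod_j, pos_i, pos_j,
                              config = clustering_config()) {
  if (length(fod_i) != length(fod_j))
    stop("FOD coefficient vectors differ in length")
  config$alpha * sqrt(sum((fod_i - fod_j)^2)) +
    (1 - config$alpha) * config$beta * sqrt(sum((pos_i - pos_j)^2))
}

#' Initial centroids from spatial hierarchical clustering
#'
#' Ward agglomeration on voxel coordinates only, cut at k clusters; each
#' initial centroid is the mean FOD coefficient vector and mean position of
#' its spatial cluster. Deterministic.
#'
#' @param coeffs Voxels x n_coeff matrix of SH coefficients.
#' @param positions Voxels x 3 matrix of voxel coordinates.
#' @param k Number of clusters.
#' @return List with \code{fod} (k x n_coeff) and \code{pos} (k x 3).
#' @export
init_centroids <- function(coeffs, positions, k) {
  n <- nrow(positions)
  if (n < k) stop("fewer voxels (", n, ") than clusters (", k, ")")
  if (n == k) {
    memb <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::dist(positions), method = "ward.D2")
    memb <- stats::cutree(hc, k = k)
  }
  list(fod = rowsum(coeffs, memb) / as.vector(table(memb)),
       pos = rowsum(positions, memb) / as.vector(table(memb)))
}

## nvox x k matrix of combined distances to centroids
centroid_distances <- function(coeffs, positions, cent, alpha, beta) {
  k <- nrow(cent$fod)
  D <- matrix(0, nrow(coeffs), k)
  for (j in seq_len(k)) {
    df <- sqrt(rowSums(sweep(coeffs, 2, cent$fod[j, ])^2))
    dp <- sqrt(rowSums(sweep(positions, 2, cent$pos[j, ])^2))
    D[, j] <- alpha * df + (1 - alpha) * beta * dp
  }
  D
}

#' Segment a thalamus mask by hybrid FOD/spatial k-means
#'
#' Alternates voxel assignment (each voxel joins the centroid minimizing the
#' hybrid distance) and centroid update (arithmetic mean of member
#' coefficients and positions) from a deterministic spatial hierarchical
#' initialization, until the centroid shift falls below \code{config$tol} or
#' \code{config$max_iter} is reached. The assignment objective (sum of
#' assigned distances) is tracked every iteration and the algorithm stops at
#' the previous partition if an update would increase it, so the recorded
#' objective trace is non-increasing. Clusters emptied during iteration are
#' re-seeded with the voxel farthest from its assigned centroid; assignment
#' ties break to the lowest centroid index.
#'
#' @param fod 4D array (x, y, z, n_coeff) of SH coefficients, or a voxels x
#'   n_coeff matrix when \code{mask} is a voxels x 3 coordinate matrix.
#' @param mask 3D logical array (which voxels to cluster), or a voxels x 3
#'   matrix of coordinates matching a matrix \code{fod}.
#' @param config A \code{\link{clustering_config}}.
#' @param init Optional precomputed spatial cluster membership (integer
#'   vector over masked voxels, values 1..k) replacing the hierarchical
#'   initialization — useful when many subjects share one mask, since the
#'   spatial tree is then identical across subjects.
#' @return An object of class \code{thalamic_parcellation}: the fitted label
#'   volume plus centroids, objective trace and convergence state. Methods:
#'   \code{print}, \code{summary}, \code{fitted} (label volume),
#'   \code{coef} (centroids), \code{predict} (label new voxels), \code{plot}.
#' @export
kmeans_segment <- function(fod, mask, config = clustering_config(),
                           init = NULL) {
  if (is.matrix(mask)) {
    positions <- mask
    coeffs <- fod
    grid_dim <- NULL
  } else {
    vox <- which(mask, arr.ind = TRUE)
    if (nrow(vox) == 0L) stop("empty mask")
    positions <- vox - 1          # 0-based voxel coordinates
    flat <- matrix(fod, nrow = prod(dim(fod)[1:3]), ncol = dim(fod)[4])
    coeffs <- flat[which(mask), , drop = FALSE]
    grid_dim <- dim(mask)
  }
  if (any(!is.finite(coeffs))) stop("non-finite FOD coefficients inside mask")
  k <- config$k
  alpha <- config$alpha
  beta <- config$beta
  cent0 <- if (is.null(init)) init_centroids(coeffs, positions, k) else {
    stopifnot(length(init) == nrow(positions))
    list(fod = rowsum(coeffs, init) / as.vector(table(init)),
         pos = rowsum(positions, init) / as.vector(table(init)))
  }

  lloyd <- function(cent, max_iter) {
    obj_trace <- numeric(0)
    assign_prev <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      D <- centroid_distances(coeffs, positions, cent, alpha, beta)
      assign <- max.col(-D, ties.method = "first")
      ## re-seed empty clusters with the voxel farthest from its centroid
      repeat {
        sizes <- tabulate(assign, nbins = k)
        if (all(sizes > 0)) break
        dmin <- D[cbind(seq_len(nrow(D)), assign)]
        far <- which.max(dmin)
        assign[far] <- which(sizes == 0)[1]
        D[far, ] <- Inf; D[far, assign[far]] <- 0
      }
      obj <- sum(D[cbind(seq_len(nrow(D)), assign)])
      if (length(obj_trace) > 0 && obj > utils::tail(obj_trace, 1) + 1e-9) {
        ## mean update is a heuristic for the unsquared metric; keep the
        ## previous (better) partition and stop
        assign <- assign_prev
        converged <- TRUE
        break
      }
      obj_trace <- c(obj_trace, obj)
      new_cent <- list(fod = rowsum(coeffs, assign) / tabulate(assign, k),
                       pos = rowsum(positions, assign) / tabulate(assign, k))
      shift <- max(sqrt(rowSums((new_cent$fod - cent$fod)^2)) +
                   sqrt(rowSums((new_cent$pos - cent$pos)^2)))
      cent <- new_cent
      assign_prev <- assign
      if (shift < config$tol) { converged <- TRUE; break }
    }
    list(assign = assign, cent = cent, objective = obj_trace,
         converged = converged)
  }

  fit <- lloyd(cent0, config$max_iter)
  if (k >= 2) fit <- refine_merge_split(fit, coeffs, positions, config, lloyd)
  assign <- fit$assign
  obj_trace <- fit$objective
  converged <- fit$converged
  if (!converged)
    warning("k-means did not converge in ", config$max_iter, " iterations")
  labels <- if (is.null(grid_dim)) assign else {
    lab <- array(0L, grid_dim)
    lab[which(mask)] <- assign
    lab
  }
  structure(list(labels = labels, assignment = assign, positions = positions,
                 centroids = fit$cent, objective = obj_trace,
                 iterations = length(obj_trace), converged = converged,
                 config = config, hemisphere = NA_character_,
                 provenance = "individual"),
            class = "thalamic_parcellation")
}

## Deterministic merge-split refinement of a converged k-means fit: the
## spatial-only initialization can seed two centroids in one nucleus and
## none in another; Lloyd iterations cannot escape that basin. Trial moves
## merge the two closest centroids (hybrid metric) and split the cluster
## with the largest within-cluster cost at its spatial median, re-running
## the Lloyd loop; a move is kept only if it lowers the converged objective.
refine_merge_split <- function(fit, coeffs, positions, config, lloyd) {
  k <- config$k
  if (k < 2) return(fit)
  for (round in 1:3) {
    cur_obj <- utils::tail(fit$objective, 1)
    cent <- fit$cent
    cd <- matrix(Inf, k, k)
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      cd[a, b] <- config$alpha *
        sqrt(sum((cent$fod[a, ] - cent$fod[b, ])^2)) +
        (1 - config$alpha) * config$beta *
        sqrt(sum((cent$pos[a, ] - cent$pos[b, ])^2))
    ord <- order(cd)[1:2]
    pairs <- lapply(ord, function(o) arrayInd(o, dim(cd))[1, ])
    D <- centroid_distances(coeffs, positions, cent, config$alpha,
                            config$beta)
    own <- D[cbind(seq_along(fit$assign), fit$assign)]
    cost <- drop(rowsum(own, fit$assign))
    improved <- FALSE
    for (pr in pairs) {
      splits <- setdiff(order(-cost), pr)[1:2]
      for (cl in splits) {
        vox_c <- which(fit$assign == cl)
        if (length(vox_c) < 4) next
        pc <- positions[vox_c, , drop = FALSE]
        ax <- which.max(apply(pc, 2, stats::var))
        med <- stats::median(pc[, ax])
        h1 <- vox_c[pc[, ax] <= med]
        h2 <- vox_c[pc[, ax] > med]
        if (length(h1) == 0 || length(h2) == 0) next
        nc <- cent
        w <- tabulate(fit$assign, k)
        nc$fod[pr[1], ] <- (w[pr[1]] * cent$fod[pr[1], ] +
                              w[pr[2]] * cent$fod[pr[2], ]) /
          (w[pr[1]] + w[pr[2]])
        nc$pos[pr[1], ] <- (w[pr[1]] * cent$pos[pr[1], ] +
                              w[pr[2]] * cent$pos[pr[2], ]) /
          (w[pr[1]] + w[pr[2]])
        nc$fod[pr[2], ] <- colMeans(coeffs[h1, , drop = FALSE])
        nc$pos[pr[2], ] <- colMeans(positions[h1, , drop = FALSE])
        nc$fod[cl, ] <- colMeans(coeffs[h2, , drop = FALSE])
        nc$pos[cl, ] <- colMeans(positions[h2, , drop = FALSE])
        trial <- lloyd(nc, config$max_iter)
        if (utils::tail(trial$objective, 1) < cur_obj - 1e-6) {
          fit <- trial
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  fit
}

#' Extract the label volume from a parcellation object or array
#'
#' @param x A \code{thalamic_parcellation} or a raw label array/vector.
#' @return The integer label volume.
#' @export
parcellation_labels <- function(x) {
  if (inherits(x, "thalamic_parcellation")) x$labels else x
}

#' @export
print.thalamic_parcellation <- function(x, ...) {
  lab <- x$labels
  nvox <- sum(lab > 0)
  cat(sprintf("Thalamic parcellation (%s): %d voxels, %d nuclei\n",
              x$provenance, nvox, length(unique(lab[lab > 0]))))
  if (length(x$objective))
    cat(sprintf("  k-means: %d iterations, objective %.4g, %sconverged\n",
                x$iterations, utils::tail(x$objective, 1),
                if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.thalamic_parcellation <- function(object, ...) {
  lab <- object$labels
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  cat("Nucleus sizes (voxels):\n")
  print(stats::setNames(sizes, paste0("nucleus", seq_along(sizes))))
  print(object)
  invisible(list(sizes = sizes, objective = object$objective))
}

#' @export
fitted.thalamic_parcellation <- function(object, ...) object$labels

#' @export
coef.thalamic_parcellation <- function(object, ...) object$centroids

#' @export
predict.thalamic_parcellation <- function(object, coeffs, positions, ...) {
  D <- centroid_distances(rbind(coeffs), rbind(positions), object$centroids,
                          object$config$alpha, object$config$beta)
  max.col(-D, ties.method = "first")
}

#' @export
plot.thalamic_parcellation <- function(x, slice = NULL, ...) {
  lab <- x$labels
  if (is.null(dim(lab)) || length(dim(lab)) != 3L)
    stop("plot requires a 3D label volume")
  if (is.null(slice)) slice <- round(dim(lab)[3] / 2)
  graphics::image(seq_len(dim(lab)[1]), seq_len(dim(lab)[2]),
                  lab[, , slice], col = c("white", grDevices::hcl.colors(
                    max(lab), "Dark 3")),
                  xlab = "x (voxels)", ylab = "y (voxels)",
                  main = paste0("axial slice ", slice), ...)
  invisible(x)
}

#' Match parcellation labels to a reference by maximum overlap
#'
#' Finds the label permutation maximizing total voxel overlap with the
#' reference (exhaustive assignment search for k <= 8, greedy above) and
#' returns the relabeled parcellation.
#'
#' @param parcellation,reference Parcellation objects or label arrays with
#'   the same number of labels on a common grid.
#' @return The relabeled parcellation (same type as the input); the applied
#'   permutation is attached as attribute \code{"permutation"} (entry j =
#'   reference label assigned to input label j).
#' @export
match_labels <- function(parcellation, reference) {
  lab <- parcellation_labels(parcellation)
  ref <- parcellation_labels(reference)
  k <- max(lab, ref)
  if (max(lab[lab > 0]) != max(ref[ref > 0]) ||
      length(unique(lab[lab > 0])) != length(unique(ref[ref > 0])))
    stop("parcellations have different numbers of labels")
  overlap <- matrix(0, k, k)
  both <- lab > 0 & ref > 0
  tab <- table(factor(lab[both], levels = 1:k), factor(ref[both], levels = 1:k))
  overlap <- matrix(as.numeric(tab), k, k)
  perm <- best_assignment(overlap)
  newlab <- lab
  newlab[lab > 0] <- perm[lab[lab > 0]]
  out <- if (inherits(parcellation, "thalamic_parcellation")) {
    parcellation$labels <- newlab
    if (!is.null(parcellation$assignment))
      parcellation$assignment <- perm[parcellation$assignment]
    parcellation
  } else newlab
  attr(out, "permutation") <- perm
  out
}

## Permutation p maximizing sum_j overlap[j, p[j]]; exhaustive for k <= 8.
best_assignment <- function(overlap) {
  k <- nrow(overlap)
  if (k <= 8) {
    perms <- pracma::perms(seq_len(k))
    scores <- perms
    best <- -Inf; bp <- seq_len(k)
    for (r in seq_len(nrow(perms))) {
      s <- sum(overlap[cbind(seq_len(k), perms[r, ])])
      if (s > best) { best <- s; bp <- perms[r, ] }
    }
    bp
  } else {
    warning("k > 8: using greedy label assignment")
    bp <- integer(k)
    ov <- overlap
    for (i in seq_len(k)) {
      idx <- arrayInd(which.max(ov), dim(ov))
      bp[idx[1]] <- idx[2]
      ov[idx[1], ] <- -Inf; ov[, idx[2]] <- -Inf
    }
    bp
  }
}

#' Per-nucleus Dice overlap between two parcellations
#'
#' @param parcellation,reference Matched-label parcellations or label arrays.
#' @return Numeric vector of Dice coefficients per reference label.
#' @export
dice_scores <- function(parcellation, reference) {
  lab <- parcellation_labels(parcellation)
  ref <- parcellation_labels(reference)
  k <- max(ref)
  vapply(seq_len(k), function(j) {
    a <- lab == j; b <- ref == j
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
}
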