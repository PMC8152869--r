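## Synthetic cohorts: analytic radial deformation fields with closed-form
## Jacobians, thalamo-cortical pathway tubes, and group-structured subjects
## (HC / MCS / VS) with planted expansion/shrinkage, fiber-density reduction
## and behavioral-score couplings.

#' Analytic radial (Gaussian-bump) deformation field
#'
#' Displacement \eqn{u(x) = a\, e^{-r^2/(2w^2)} (x - c)} with \eqn{r = |x-c|}:
#' a smooth radial expansion (a > 0) or contraction (a < 0) about \code{center}
#' blending to the identity away from it. The Jacobian has the closed form
#' \eqn{\det J = g(r)^2 (g(r) + r g'(r))} with \eqn{g(r) = 1 + a e^{-r^2/(2w^2)}},
#' attached as attribute \code{"log_jacobian_analytic"}.
#'
#' @param grid_shape 3D voxel extents.
#' @param center Bump center (continuous voxel coordinates, 1-based).
#' @param a Bump amplitude (|a| < 0.5 keeps the map diffeomorphic).
#' @param w Bump width (voxels).
#' @return 4D displacement array (x, y, z, 3) with the analytic log-Jacobian
#'   volume as an attribute.
#' @export
radial_deformation <- function(grid_shape, center, a, w) {
  g <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                             j = seq_len(grid_shape[2]),
                             k = seq_len(grid_shape[3])))
  dx <- sweep(g, 2, center)
  r2 <- rowSums(dx^2)
  e <- exp(-r2 / (2 * w^2))
  u <- dx * (a * e)
  gg <- 1 + a * e
  radial <- 1 + a * e * (1 - r2 / w^2)
  logj <- 2 * log(gg) + log(radial)
  field <- array(u, c(grid_shape, 3))
  attr(field, "log_jacobian_analytic") <- array(logj, grid_shape)
  attr(field, "params") <- list(center = center, a = a, w = w)
  field
}

## Wendland-type compact radial kernel: phi(s) = (1-s)^4 (4s+1) on [0, 1],
## zero outside; C2-smooth at the support boundary. Its compact support
## keeps planted nucleus deformations strictly inside the thalamus block,
## so pathway tubes in the surrounding shell see an identity warp.
wendland_phi <- function(s) ifelse(s < 1, (1 - s)^4 * (4 * s + 1), 0)
wendland_dphi <- function(s) ifelse(s < 1, -20 * s * (1 - s)^3, 0)

## Displacement of a sum of compact radial bumps, evaluated at continuous
## points (n x 3). bumps: list of list(center, a, R).
bump_displacement <- function(points, bumps) {
  u <- matrix(0, nrow(points), 3)
  for (b in bumps) {
    dx <- sweep(points, 2, b$center)
    s <- sqrt(rowSums(dx^2)) / b$R
    u <- u + dx * (b$a * wendland_phi(s))
  }
  u
}

## Closed-form log-Jacobian of a single compact radial bump at radii r:
## tangential stretch g = 1 + a phi(s), radial stretch g + r g' =
## 1 + a (phi(s) + s phi'(s)), s = r / R.
bump_logj <- function(r, a, R) {
  s <- r / R
  gg <- 1 + a * wendland_phi(s)
  radial <- 1 + a * (wendland_phi(s) + s * wendland_dphi(s))
  if (any(gg <= 0) || any(radial <= 0)) return(NULL)
  2 * log(gg) + log(radial)
}

## --- separable nucleus-scaling warp ------------------------------------
## Per axis, a monotone map of the box interval onto itself that scales the
## nucleus slab by gamma about the box face it touches and compresses the
## complementary slab, with a 2-voxel C1 transition band around the interior
## plane so central finite differences of the resulting field are accurate.
## The map is the identity at and beyond the box faces, so the warp never
## touches the pathway shell. An axis the nucleus spans fully is left
## untouched.

## profile parameters for one axis: list(type = "identity") or
## list(type, B0, B1, M, gamma) with type "lower" / "upper"
axis_profile <- function(rng, box_lo, box_hi, gamma) {
  B0 <- box_lo - 0.5; B1 <- box_hi + 0.5
  lower <- rng[1] == box_lo; upper <- rng[2] == box_hi
  if (lower && upper) return(list(type = "identity"))
  if (lower) list(type = "lower", B0 = B0, B1 = B1, M = rng[2] + 0.5,
                  gamma = gamma)
  else list(type = "upper", B0 = B0, B1 = B1, M = rng[1] - 0.5,
            gamma = gamma)
}

## evaluate f(t) and f'(t) for a "lower" profile (slab [B0, M] scaled by
## gamma about B0); gamma2 compresses the complement so f(B1) = B1
eval_lower <- function(t, B0, B1, M, gamma) {
  gamma2 <- (B1 - B0 - gamma * (M - B0)) / (B1 - M)
  t1 <- M - 1; t2 <- M + 1
  f <- numeric(length(t)); sl <- numeric(length(t))
  lo <- t <= t1; band <- t > t1 & t < t2; hi <- t >= t2
  f[lo] <- B0 + gamma * (t[lo] - B0); sl[lo] <- gamma
  fb1 <- B0 + gamma * (t1 - B0)
  f[band] <- fb1 + gamma * (t[band] - t1) +
    (gamma2 - gamma) * (t[band] - t1)^2 / 4
  sl[band] <- gamma + (gamma2 - gamma) * (t[band] - t1) / 2
  fb2 <- fb1 + gamma + gamma2                    # f(t2): integral over band
  f[hi] <- fb2 + gamma2 * (t[hi] - t2); sl[hi] <- gamma2
  out <- ifelse(t <= B0 | t >= B1, t, f)
  slo <- ifelse(t <= B0 | t >= B1, 1, sl)
  list(f = out, slope = slo)
}

eval_profile <- function(t, pr) {
  if (pr$type == "identity") return(list(f = t, slope = rep(1, length(t))))
  if (pr$type == "lower") return(eval_lower(t, pr$B0, pr$B1, pr$M, pr$gamma))
  ## upper: reflect through the interval midpoint
  r <- eval_lower(pr$B0 + pr$B1 - t, pr$B0, pr$B1, pr$B0 + pr$B1 - pr$M,
                  pr$gamma)
  list(f = pr$B0 + pr$B1 - r$f, slope = r$slope)
}

## composed per-axis maps for an expand and a shrink nucleus; returns per
## axis f(t) and slope(t) evaluated at t = 1..dims[axis]
scale_warp_axes <- function(dims, box, slabs_e, slabs_s, gam_e, gam_s) {
  lapply(1:3, function(a) {
    t <- seq_len(dims[a])
    pe <- axis_profile(slabs_e[[a]], box$lo[a], box$hi[a], gam_e)
    ps <- axis_profile(slabs_s[[a]], box$lo[a], box$hi[a], gam_s)
    s1 <- eval_profile(t, ps)
    s2 <- eval_profile(s1$f, pe)
    list(f = s2$f, slope = s2$slope * s1$slope)
  })
}

## Calibrate the per-axis scale factors so the mean analytic log-Jacobian
## over each designated nucleus equals log(lambda_e) / log(lambda_s), then
## return the separable displacement field and its analytic log-Jacobian.
nucleus_scale_warp <- function(dims, tlab, expand_nucleus, shrink_nucleus,
                               lambda_e, lambda_s) {
  box <- phantom_box(dims)
  slabs <- function(j) {
    v <- which(tlab == j, arr.ind = TRUE)
    lapply(1:3, function(a) range(v[, a]))
  }
  se <- slabs(expand_nucleus); ss <- slabs(shrink_nucleus)
  nfree <- function(sl) sum(vapply(1:3, function(a)
    !(sl[[a]][1] == box$lo[a] && sl[[a]][2] == box$hi[a]), logical(1)))
  ne <- max(1, nfree(se)); ns <- max(1, nfree(ss))
  vox_e <- which(tlab == expand_nucleus, arr.ind = TRUE)
  vox_s <- which(tlab == shrink_nucleus, arr.ind = TRUE)
  adj_e <- lambda_e; adj_s <- lambda_s
  ax <- NULL
  for (it in 1:10) {
    ax <- scale_warp_axes(dims, box, se, ss, adj_e^(1 / ne), adj_s^(1 / ns))
    logslope <- lapply(ax, function(x) log(x$slope))
    ljvox <- function(v) logslope[[1]][v[, 1]] + logslope[[2]][v[, 2]] +
      logslope[[3]][v[, 3]]
    m_e <- mean(ljvox(vox_e)); m_s <- mean(ljvox(vox_s))
    adj_e <- adj_e * (lambda_e / exp(m_e))
    adj_s <- adj_s * (lambda_s / exp(m_s))
    if (abs(m_e - log(lambda_e)) < 1e-10 &&
        abs(m_s - log(lambda_s)) < 1e-10) break
  }
  ## each displacement component is windowed in the two transverse axes
  ## (smoothstep taper over 2.5 voxels beyond the box) so the warp is the
  ## identity in the pathway shell; inside the box the window is 1 and the
  ## separable map is exact
  win <- lapply(1:3, function(a) {
    t <- seq_len(dims[a])
    d <- pmax(box$lo[a] - 0.5 - t, t - (box$hi[a] + 0.5))
    s <- pmin(pmax(d / 2.5, 0), 1)
    1 - 3 * s^2 + 2 * s^3
  })
  field <- array(0, c(dims, 3))
  for (a in 1:3) {
    u1 <- ax[[a]]$f - seq_len(dims[a])
    ua <- array(switch(a,
      rep(u1, times = dims[2] * dims[3]),
      rep(rep(u1, each = dims[1]), times = dims[3]),
      rep(u1, each = dims[1] * dims[2])), dims)
    tr <- setdiff(1:3, a)
    w1 <- array(switch(tr[1],
      rep(win[[1]], times = dims[2] * dims[3]),
      rep(rep(win[[2]], each = dims[1]), times = dims[3]),
      rep(win[[3]], each = dims[1] * dims[2])), dims)
    w2 <- array(switch(tr[2],
      rep(win[[1]], times = dims[2] * dims[3]),
      rep(rep(win[[2]], each = dims[1]), times = dims[3]),
      rep(win[[3]], each = dims[1] * dims[2])), dims)
    field[, , , a] <- ua * w1 * w2
  }
  logj <- outer(log(ax[[1]]$slope),
                outer(log(ax[[2]]$slope), log(ax[[3]]$slope), "+"), "+")
  list(field = field, logj = logj)
}

#' Route thalamo-cortical pathway tubes
#'
#' For every (nucleus, cortical target) pair a 6-connected single-voxel tube
#' is routed by breadth-first search from a surface voxel of the nucleus
#' through the unoccupied shell outside the thalamus block to the grid face
#' standing in for that cortical target. Tubes are pairwise disjoint; the
#' first voxel of each tube lies inside its nucleus.
#'
#' @param parcellation 3D ground-truth label array (block layout).
#' @param n_targets Number of cortical targets, <= 6 (default 5: prefrontal,
#'   motor, somatosensory, parietal-occipital, temporal).
#' @param seed Unused (routing is deterministic); kept for interface
#'   stability.
#' @return List of class \code{pathway_set}: \code{labels} (3D int array,
#'   values 1..k*n_targets), \code{table} (pathway, nucleus, target),
#'   \code{voxels} (per-voxel pathway id and local tube direction).
#' @export
make_pathways <- function(parcellation, n_targets = 5, seed = 1L) {
  lab <- parcellation_labels(parcellation)
  dims <- dim(lab)
  k <- max(lab)
  if (n_targets < 1 || n_targets > 6) stop("n_targets must be in 1..6")
  ## target grid faces: +y, +x, -x, -y, +z, -z
  faces <- list(c(2, 1), c(1, 1), c(1, -1), c(2, -1), c(3, 1), c(3, -1))
  target_names <- c("prefrontal", "motor", "somatosensory",
                    "parietal-occipital", "temporal", "extra")[seq_len(n_targets)]
  occupied <- lab > 0
  path_lab <- array(0L, dims)
  nb_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  ## voxels within the deformation taper band around the block (< 3 voxels
  ## from a box face) are avoided by the BFS so tubes run through warp-free
  ## shell; the straight exit segment crosses the band perpendicular to it
  box <- phantom_box(dims)
  band <- array(FALSE, dims)
  gidx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                seq_len(dims[3])))
  dband <- pmax(sweep(-gidx, 2, -(box$lo - 0.5)),   # (lo-0.5) - t
                sweep(gidx, 2, box$hi + 0.5))
  band[gidx] <- apply(dband, 1, max) < 2.5 & !occupied[gidx]
  rows <- list()
  tube_vox <- list()
  pid <- 0L
  for (j in seq_len(k)) {
    nuc <- which(lab == j, arr.ind = TRUE)
    for (t in seq_len(n_targets)) {
      pid <- pid + 1L
      ax <- faces[[t]][1]; sgn <- faces[[t]][2]
      goal <- if (sgn > 0) dims[ax] else 1L
      ## start: free nucleus voxel with a free outside-block neighbor and a
      ## collision-free straight exit segment crossing the taper band,
      ## preferring starts close to the target face
      cand <- nuc[order(sgn * -nuc[, ax]), , drop = FALSE]
      find_prefix <- function(require_clear) {
        for (r in seq_len(nrow(cand))) {
          v <- cand[r, ]
          if (path_lab[v[1], v[2], v[3]] != 0L) next
          for (o in seq_len(6)) {
            seg <- v
            cur <- v
            ok <- FALSE
            repeat {
              cur <- cur + nb_off[o, ]
              if (any(cur < 1) || any(cur > dims)) break
              if (occupied[cur[1], cur[2], cur[3]] ||
                  path_lab[cur[1], cur[2], cur[3]] != 0L) break
              seg <- rbind(seg, cur)
              if (!band[cur[1], cur[2], cur[3]] || !require_clear) {
                ok <- TRUE; break
              }
            }
            if (ok) return(seg)
          }
        }
        NULL
      }
      prefix <- find_prefix(TRUE)      # exit segment clears the taper band
      if (is.null(prefix)) prefix <- find_prefix(FALSE)  # tight shell
      if (is.null(prefix))
        stop("grid too small to route pathway tubes (nucleus ", j, ")")
      path_lab[prefix] <- pid
      tail_v <- prefix[nrow(prefix), ]
      path <- if (tail_v[ax] == goal) prefix[0, , drop = FALSE] else
        bfs_route(tail_v, ax, goal, dims,
                  occupied | (path_lab > 0L) | band)
      if (is.null(path))   # tight shell: allow routing through the band
        path <- bfs_route(tail_v, ax, goal, dims,
                          occupied | (path_lab > 0L))
      if (is.null(path)) {
        path_lab[prefix] <- 0L
        stop("grid too small to route pathway tubes (nucleus ", j,
             ", target ", t, ")")
      }
      path <- rbind(prefix, path[-1, , drop = FALSE])
      path_lab[path] <- pid
      rows[[pid]] <- data.frame(pathway = pid, nucleus = j,
                                target = target_names[t])
      step <- diff(path)
      step <- rbind(step, step[nrow(step), , drop = FALSE])
      dirs <- step / sqrt(rowSums(step^2))
      tube_vox[[pid]] <- data.frame(i = path[, 1], j = path[, 2],
                                    k = path[, 3], pathway = pid,
                                    dx = dirs[, 1], dy = dirs[, 2],
                                    dz = dirs[, 3])
    }
  }
  structure(list(labels = path_lab, table = do.call(rbind, rows),
                 voxels = do.call(rbind, tube_vox), n_targets = n_targets),
            class = "pathway_set")
}

## BFS from `start` (inside a nucleus) through free voxels (outside the
## blocked set, except the start itself) to any voxel with coordinate
## `goal` on axis `ax`. Returns the path as an n x 3 matrix or NULL.
bfs_route <- function(start, ax, goal, dims, blocked) {
  lin <- function(v) as.integer(v[1] + dims[1] * (v[2] - 1L + dims[2] * (v[3] - 1L)))
  nb_off <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L),
                  c(0L, 0L, 1L), c(0L, 0L, -1L))
  n <- prod(dims)
  prev <- integer(n)              # 0 = unvisited
  s <- lin(start)
  prev[s] <- -1L
  queue <- s
  head <- 1L
  found <- 0L
  coords <- function(l) {
    l0 <- as.integer(l) - 1L
    as.integer(c(l0 %% dims[1] + 1L, (l0 %/% dims[1]) %% dims[2] + 1L,
                 l0 %/% (dims[1] * dims[2]) + 1L))
  }
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    cv <- coords(cur)
    if (cv[ax] == goal && cur != s) { found <- cur; break }
    for (o in seq_len(6)) {
      nv <- cv + nb_off[o, ]
      if (any(nv < 1L) || any(nv > dims)) next
      l <- lin(nv)
      if (prev[l] != 0L) next
      if (blocked[l]) next
      prev[l] <- cur
      queue <- c(queue, l)
    }
  }
  if (found == 0L) return(NULL)
  path <- integer(0)
  cur <- found
  while (cur != -1L) {
    path <- c(cur, path)
    cur <- prev[cur]
    if (cur == s) { path <- c(s, path); break }
  }
  t(vapply(path, coords, integer(3)))
}

#' Effect configuration for the synthetic cohort
#'
#' Group effects planted into patient subjects, following the directions
#' reported for disorders of consciousness: expansion of a dorsal-posterior
#' stand-in nucleus, shrinkage of an anterior stand-in, fiber-density
#' reduction in designated nuclei and pathways, increased diffusivity along
#' pathways, and CRS-R totals negatively coupled to the volume change and
#' positively to FD.
#'
#' @param expand_nucleus Label with planted expansion (default 6).
#' @param shrink_nucleus Label with planted shrinkage (default 1).
#' @param volume_effect Expansion factor at full severity (default 1.2; the
#'   shrink nucleus uses its reciprocal).
#' @param fd_reduction Fractional FD decrease at full severity, in [0, 1)
#'   (default 0.3).
#' @param fd_nuclei Labels with planted FD reduction (default c(2, 6),
#'   antero-medial and dorsal-posterior stand-ins).
#' @param diffusivity_increase Fractional radial-eigenvalue increase along
#'   pathways at full severity (default 0.3).
#' @param volume_noise Standard deviation of additive severity-independent
#'   noise on the per-subject expansion/shrinkage factors (default 0.04):
#'   individual nucleus volumes vary for reasons unrelated to disease, so
#'   deformation-derived metrics are an imperfect severity readout.
#' @param boundary_jitter Maximum per-subject shift (voxels) of the nucleus
#'   block midplanes, drawn uniformly from \code{-boundary_jitter ..
#'   boundary_jitter} per axis for every subject regardless of group
#'   (default 1). This models individual anatomical variability in nucleus
#'   geometry — the substrate on which an individualized parcellation can
#'   outperform a population atlas.
#' @param warp_jitter Standard deviation of the amplitudes of six random
#'   compact deformation bumps added to every subject's field across the
#'   whole grid (default 0.08), giving deformation-derived metrics
#'   (log-Jacobian, FC) realistic between-subject variability.
#' @param crs_base,crs_slope,crs_sd CRS-R total = round(crs_base + crs_slope
#'   * severity + N(0, crs_sd)), clipped to [0, 23] (defaults 16, -12, 1;
#'   observed patient totals then span roughly 4-15).
#' @return List of class \code{effect_config}.
#' @export
effect_config <- function(expand_nucleus = 6, shrink_nucleus = 1,
                          volume_effect = 1.2, fd_reduction = 0.3,
                          fd_nuclei = c(2, 6), diffusivity_increase = 0.3,
                          volume_noise = 0.04,
                          boundary_jitter = 1, warp_jitter = 0.08,
                          crs_base = 16, crs_slope = -12, crs_sd = 1) {
  stopifnot(fd_reduction >= 0, fd_reduction < 1, volume_effect > 0,
            boundary_jitter >= 0, warp_jitter >= 0, crs_slope <= 0)
  structure(list(expand_nucleus = as.integer(expand_nucleus),
                 shrink_nucleus = as.integer(shrink_nucleus),
                 volume_effect = volume_effect, fd_reduction = fd_reduction,
                 fd_nuclei = as.integer(fd_nuclei),
                 diffusivity_increase = diffusivity_increase,
                 volume_noise = volume_noise,
                 boundary_jitter = as.integer(boundary_jitter),
                 warp_jitter = warp_jitter,
                 crs_base = crs_base, crs_slope = crs_slope, crs_sd = crs_sd),
            class = "effect_config")
}

#' Generate a synthetic cohort with planted group effects
#'
#' Builds a clean template phantom plus pathway tubes, then one subject at a
#' time: a severity score (0 for HC, moderate for MCS, high for VS) drives a
#' per-subject analytic deformation field (expanding/shrinking the
#' designated nuclei), a warped subject parcellation and mask, FOD
#' coefficients with FD scaled down in designated nuclei and pathways,
#' tensor eigenvalues with increased pathway diffusivity, and a metadata
#' row (group, CRS-R total, age, intracranial volume, DOC duration).
#'
#' @param n_hc,n_mcs,n_vs Group sizes (defaults 10, 5, 5).
#' @param phantom A \code{\link{phantom_config}}.
#' @param effects An \code{\link{effect_config}}.
#' @param seed Integer master seed.
#' @param n_targets Cortical targets for pathways (0 disables pathways).
#' @return List of class \code{synthetic_cohort}: \code{template} (clean
#'   phantom + \code{pathways}), \code{subjects} (per subject: \code{fod},
#'   \code{field}, \code{tensor}, \code{mask}, \code{labels_truth}),
#'   \code{meta} (data frame), \code{truth} (planted ground-truth manifest),
#'   \code{basis}.
#' @export
make_cohort <- function(n_hc = 10, n_mcs = 5, n_vs = 5,
                        phantom = phantom_config(), effects = effect_config(),
                        seed = 1L, n_targets = 5) {
  basis <- sh_basis(phantom$lmax, phantom$tessellation_level)
  template <- make_phantom(
    phantom_config(grid_shape = phantom$grid_shape,
                   k_nuclei = phantom$k_nuclei, lmax = phantom$lmax,
                   orientations = phantom$orientations, kappa = phantom$kappa,
                   amplitude = phantom$amplitude, snr = 0,
                   tessellation_level = phantom$tessellation_level,
                   seed = phantom$seed), basis = basis)
  pathways <- if (n_targets > 0)
    make_pathways(template$parcellation, n_targets, seed) else NULL
  k <- phantom$k_nuclei
  dims <- phantom$grid_shape
  grid_pts <- as.matrix(expand.grid(i = seq_len(dims[1]),
                                    j = seq_len(dims[2]),
                                    k = seq_len(dims[3])))
  tlab <- template$parcellation
  groups <- c(rep("HC", n_hc), rep("MCS", n_mcs), rep("VS", n_vs))
  n <- length(groups)
  ## age and intracranial volume are drawn once and snake-assigned between
  ## HC and patients so the groups are covariate-balanced, emulating the
  ## study's matched cohort ("no significant difference in age"); chance
  ## covariate-group correlation would otherwise absorb part of any group
  ## effect during residualization
  snake_assign <- function(v) {
    v <- sort(v)
    is_pat <- groups != "HC"
    pat_idx <- which(is_pat); hc_idx <- which(!is_pat)
    pattern <- rep(c(TRUE, FALSE, FALSE, TRUE), length.out = n)
    out <- numeric(n)
    pi_ <- 1L; hi_ <- 1L
    for (r in seq_len(n)) {
      to_pat <- if (pi_ > length(pat_idx)) FALSE else
        if (hi_ > length(hc_idx)) TRUE else pattern[r]
      if (to_pat) { out[pat_idx[pi_]] <- v[r]; pi_ <- pi_ + 1L }
      else { out[hc_idx[hi_]] <- v[r]; hi_ <- hi_ + 1L }
    }
    out
  }
  icv_assigned <- with_seed(seed + 777L,
                            snake_assign(round(stats::rnorm(n, 1.45e6,
                                                            1.2e5))))
  age_assigned <- with_seed(seed + 778L,
                            snake_assign(pmin(80, pmax(18, round(
                              stats::rnorm(n, 48, 14))))))
  lobe_cache <- new.env(hash = TRUE)
  lobe_for_direction <- function(d) {
    key <- paste(round(d, 3), collapse = ",")
    hit <- lobe_cache[[key]]
    if (is.null(hit)) {
      hit <- watson_sh(d, basis, phantom$kappa) * phantom$amplitude
      lobe_cache[[key]] <- hit
    }
    hit
  }
  subjects <- vector("list", n)
  meta <- vector("list", n)
  truth <- vector("list", n)
  p <- basis$n_coeff
  for (s in seq_len(n)) {
    sub_seed <- seed + 1000L * s
    dat <- with_seed(sub_seed, {
      grp <- groups[s]
      sev <- switch(grp, HC = 0,
                    MCS = stats::runif(1, 0.1, 0.5),
                    VS = stats::runif(1, 0.6, 1.0))
      jit <- function() exp(stats::rnorm(1, 0, 0.05))
      vnoise <- function() stats::rnorm(1, 0, effects$volume_noise)
      lam_e <- if (grp == "HC") exp(stats::rnorm(1, 0, 0.01)) + vnoise() else
        1 + (effects$volume_effect - 1) * sev * jit() + vnoise()
      lam_s <- if (grp == "HC") exp(stats::rnorm(1, 0, 0.01)) + vnoise() else
        1 / (1 + (effects$volume_effect - 1) * sev * jit()) + vnoise()
      lam_e <- min(1.45, max(0.7, lam_e))
      lam_s <- min(1.45, max(0.7, lam_s))
      fd_factor <- if (grp == "HC") 1 else
        max(0.05, 1 - effects$fd_reduction * sev * jit())
      diff_factor <- if (grp == "HC") 1 else
        1 + effects$diffusivity_increase * sev * jit()
      crs <- if (grp == "HC") 23L else
        as.integer(min(23, max(0, round(effects$crs_base +
          effects$crs_slope * sev + stats::rnorm(1, 0, effects$crs_sd)))))
      age <- age_assigned[s]
      icv <- icv_assigned[s]
      dur <- if (grp == "HC") 0 else round(stats::runif(1, 1, 12), 1)
      noise <- stats::rnorm(prod(dims) * p,
                            sd = phantom$snr * mean(template$lobes[, 1]))
      tjit <- abs(1 + phantom$snr *
                    matrix(stats::rnorm(prod(dims) * 3, sd = 0.5),
                           prod(dims), 3))
      plane_shift <- if (effects$boundary_jitter > 0)
        sample(seq(-effects$boundary_jitter, effects$boundary_jitter), 5,
               replace = TRUE) else rep(0L, 5)
      jitter_bumps <- if (effects$warp_jitter > 0) lapply(1:6, function(b)
        list(center = stats::runif(3, 0, 1) * dims,
             R = stats::runif(1, 3, 6),
             a = stats::rnorm(1, 0, effects$warp_jitter))) else list()
      list(grp = grp, sev = sev, lam_e = lam_e, lam_s = lam_s,
           fd_factor = fd_factor, diff_factor = diff_factor, crs = crs,
           age = age, icv = icv, dur = dur, noise = noise, tjit = tjit,
           plane_shift = plane_shift, jitter_bumps = jitter_bumps)
    })
    warp <- nucleus_scale_warp(dims, tlab, effects$expand_nucleus,
                               effects$shrink_nucleus, dat$lam_e, dat$lam_s)
    field <- warp$field
    if (length(dat$jitter_bumps))
      field <- field + array(bump_displacement(grid_pts, dat$jitter_bumps),
                             c(dims, 3))
    ## subject ground-truth labels: the block partition with this subject's
    ## anatomical midplane shifts, on the common template mask
    ## (template-space workflow)
    slab <- block_parcellation(dims, k, dat$plane_shift)
    slab[!template$mask] <- 0L
    hole <- template$mask & slab == 0L
    if (any(hole)) slab[hole] <- tlab[hole]
    smask <- template$mask
    flat <- matrix(0, prod(dims), p)
    sidx <- which(smask)
    flat[sidx, ] <- template$lobes[slab[sidx], , drop = FALSE]
    if (dat$fd_factor != 1) {
      red <- sidx[slab[sidx] %in% effects$fd_nuclei]
      flat[red, ] <- flat[red, ] * dat$fd_factor
    }
    tensor_flat <- matrix(0, prod(dims), 3)
    tensor_flat[sidx, ] <- rep(c(1.7e-3, 0.3e-3, 0.3e-3), each = length(sidx))
    if (!is.null(pathways)) {
      pv <- pathways$voxels
      plin <- pv$i + dims[1] * (pv$j - 1L + dims[2] * (pv$k - 1L))
      keep <- !smask[plin]          # thalamus takes precedence
      for (r in which(keep)) {
        flat[plin[r], ] <- lobe_for_direction(c(pv$dx[r], pv$dy[r], pv$dz[r])) *
          dat$fd_factor
      }
      tensor_flat[plin[keep], 1] <- 1.7e-3 *
        (1 + 0.3 * (dat$diff_factor - 1))
      tensor_flat[plin[keep], 2:3] <- 0.3e-3 * dat$diff_factor
    }
    allmask <- tensor_flat[, 1] > 0
    flat[allmask, ] <- flat[allmask, ] +
      matrix(dat$noise[seq_len(sum(allmask) * p)], sum(allmask), p)
    tensor_flat[allmask, ] <- tensor_flat[allmask, ] *
      dat$tjit[seq_len(sum(allmask)), ]
    tensor_flat[allmask, ] <- t(apply(tensor_flat[allmask, , drop = FALSE],
                                      1, sort, decreasing = TRUE))
    subjects[[s]] <- list(
      id = sprintf("S%02d", s),
      fod = array(flat, c(dims, p)),
      field = field,
      tensor = array(tensor_flat, c(dims, 3)),
      mask = smask,
      labels_truth = slab)
    meta[[s]] <- data.frame(id = sprintf("S%02d", s), group = dat$grp,
                            crs_r_total = dat$crs, age = dat$age,
                            icv = dat$icv, doc_duration = dat$dur)
    truth[[s]] <- list(severity = dat$sev, lambda_expand = dat$lam_e,
                       lambda_shrink = dat$lam_s, fd_factor = dat$fd_factor,
                       diff_factor = dat$diff_factor,
                       plane_shift = dat$plane_shift,
                       logj_analytic_mean = c(
                         expand = mean(warp$logj[tlab ==
                                                   effects$expand_nucleus]),
                         shrink = mean(warp$logj[tlab ==
                                                   effects$shrink_nucleus])))
  }
  meta <- do.call(rbind, meta)
  meta$group <- factor(meta$group, levels = c("HC", "MCS", "VS"))
  structure(list(template = c(template, list(pathways = pathways)),
                 subjects = subjects, meta = meta, truth = truth,
                 basis = basis, phantom = phantom, effects = effects,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %s (grid %s, %d nuclei)\n",
              paste(sprintf("%d %s", table(x$meta$group),
                            levels(x$meta$group)), collapse = ", "),
              paste(x$phantom$grid_shape, collapse = "x"),
              x$phantom$k_nuclei))
  invisible(x)
}
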