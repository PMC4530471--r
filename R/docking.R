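#' Rigid-body poses
#'
#' A pose is a unit quaternion plus a translation in Angstrom; applied
#' to a structure it rotates the coordinates about the structure's
#' heavy-atom centroid and then translates.
#'
#' @param quaternion length-4 numeric (w, x, y, z); normalised on
#'   construction.
#' @param translation length-3 numeric, Angstrom.
#' @return An object of class `pose`.
#' @export
pose <- function(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("zero quaternion")
  structure(list(quaternion = q / nq, translation = as.numeric(translation)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: q = (%.4f, %.4f, %.4f, %.4f), t = (%.2f, %.2f, %.2f) A\n",
              x$quaternion[1], x$quaternion[2], x$quaternion[3],
              x$quaternion[4], x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion for a rotation about an axis
#' @param axis length-3 rotation axis (any norm).
#' @param angle_deg rotation angle in degrees.
#' @return Unit quaternion (w, x, y, z).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180 / 2
  c(cos(th), sin(th) * a)
}

#' Angular distance between two rotations
#' @param q1,q2 unit quaternions (w, x, y, z).
#' @return Rotation angle in degrees of the relative rotation.
#' @export
rotation_distance <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d) * 180 / pi
}

#' Compose two poses
#' @param p2,p1 `pose` objects; the result applies p1 first, then p2,
#'   with both rotations taken about the same centroid.
#' @param centroid the rotation centre both poses refer to.
#' @return A `pose`.
#' @export
pose_compose <- function(p2, p1, centroid = c(0, 0, 0)) {
  q <- quat_multiply(p2$quaternion, p1$quaternion)
  R2 <- quat_to_matrix(p2$quaternion)
  t_new <- as.numeric(R2 %*% (p1$translation) + p2$translation)
  pose(q, t_new)
}

#' Invert a pose
#' @param p a `pose`.
#' @return The inverse pose (same rotation centre convention).
#' @export
pose_inverse <- function(p) {
  qi <- c(p$quaternion[1], -p$quaternion[2:4])
  Ri <- quat_to_matrix(qi)
  pose(qi, as.numeric(-Ri %*% p$translation))
}

#' Apply a pose to an atomic structure
#'
#' Coordinates are rotated about the structure's heavy-atom centroid
#' and translated: `x' = R (x - c) + c + t`.
#'
#' @param structure an `atomic_structure`.
#' @param p a `pose`.
#' @param centroid optional explicit rotation centre (defaults to the
#'   heavy-atom centroid).
#' @return The transformed `atomic_structure`.
#' @export
apply_pose <- function(structure, p, centroid = NULL) {
  if (is.null(centroid)) centroid <- colMeans(coords(heavy_atoms(structure)))
  xyz <- coords(structure)
  R <- quat_to_matrix(p$quaternion)
  xyz_new <- sweep(sweep(xyz, 2, centroid) %*% t(R), 2,
                   centroid + p$translation, "+")
  set_coords(structure, xyz_new)
}

#' Deterministic near-uniform orientation grid
#'
#' Super-Fibonacci spiral on the unit quaternion 3-sphere: a fixed
#' enumeration whose covering radius scales with the requested angular
#' step, used as the rotational part of the exhaustive search.
#'
#' @param angular_step target angular resolution in degrees, in
#'   [5, 60].
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
orientation_grid <- function(angular_step) {
  if (angular_step < 5 || angular_step > 60)
    stop("angular_step must lie in [5, 60] degrees")
  s <- angular_step * pi / 180
  # number of rotation balls of radius `s` needed to cover SO(3) is
  # pi / (s - sin s); factor 3 covering overhead, factor 2 for the
  # quaternion double cover
  n <- as.integer(ceiling(6 * pi / (s - sin(s))))
  i <- seq_len(n) - 0.5
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041  # real root of psi^4 = psi + 4
  t <- i / n
  d <- 2 * pi * i
  r <- sqrt(t); R <- sqrt(1 - t)
  alpha <- d / phi
  beta <- d / psi
  cbind(r * sin(alpha), r * cos(alpha), R * sin(beta), R * cos(beta))
}

# Stamp points as trilinear-weighted deltas on a wrapped grid; returns
# the flat accumulation vector of length prod(dims).
stamp_deltas_wrapped <- function(dims, frac_idx, weights) {
  n <- nrow(frac_idx)
  base <- floor(frac_idx)
  fr <- frac_idx - base
  vec <- numeric(prod(dims))
  idx_all <- integer(0); val_all <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- (base[, 1] + dx) %% dims[1]
    iy <- (base[, 2] + dy) %% dims[2]
    iz <- (base[, 3] + dz) %% dims[3]
    w <- weights *
      (if (dx == 0) 1 - fr[, 1] else fr[, 1]) *
      (if (dy == 0) 1 - fr[, 2] else fr[, 2]) *
      (if (dz == 0) 1 - fr[, 3] else fr[, 3])
    idx_all <- c(idx_all, 1L + ix + dims[1] * (iy + dims[2] * iz))
    val_all <- c(val_all, w)
  }
  acc <- rowsum(val_all, idx_all)
  vec[as.integer(rownames(acc))] <- acc[, 1]
  vec
}

# Circularly-centred separable Gaussian kernel (unit mass as a discrete
# point-spread: value = normalised 3D Gaussian density at the voxel).
wrapped_gaussian_kernel <- function(dims, voxel, sigma) {
  axis_g <- function(n) {
    i <- 0:(n - 1)
    d <- pmin(i, n - i) * voxel
    exp(-d^2 / (2 * sigma^2))
  }
  k <- outer(outer(axis_g(dims[1]), axis_g(dims[2])), axis_g(dims[3]))
  array(k / ((2 * pi)^1.5 * sigma^3), dim = dims)
}

# Wrapped 6-neighbour Laplacian stencil as an array for Fourier use.
wrapped_laplacian_stencil <- function(dims) {
  s <- array(0, dim = dims)
  s[1, 1, 1] <- -6
  s[2, 1, 1] <- s[dims[1], 1, 1] <- s[1, 2, 1] <- s[1, dims[2], 1] <-
    s[1, 1, 2] <- s[1, 1, dims[3]] <- 1
  s
}

#' Exhaustive six-dimensional rigid-body search
#'
#' For every rotation in a fixed near-uniform orientation grid at the
#' given angular step, the probe structure is blurred to `resolution`
#' and all translations on the map grid are scanned at once by FFT
#' cross-correlation; the best translation per rotation is retained.
#' Scores are full-grid Pearson correlations.  With `laplacian = TRUE`
#' both the target map and the probe density are Laplacian-filtered
#' before correlation, which penalises mismatches in surface features;
#' the full map is always correlated (no density cut-off).  Hits are
#' clustered (rotation radius `2 * angular_step`, translation radius
#' `1.5 * voxel`) and ranked by correlation; ties resolve to the lower
#' enumeration index, so results are deterministic.
#'
#' @param map target `density_map`.
#' @param probe an `atomic_structure`.
#' @param resolution blurring resolution in Angstrom.
#' @param angular_step orientation grid spacing in degrees, in [5, 60]
#'   (default 20).
#' @param laplacian apply Laplacian filtering (default FALSE).
#' @param top_n number of clusters to report (default 10).
#' @return An object of class `dock_result`: `hits` data frame (rank,
#'   qw, qx, qy, qz, tx, ty, tz, cc, normalized_cc, cluster_size) and
#'   `settings` list.
#' @export
exhaustive_search <- function(map, probe, resolution, angular_step = 20,
                              laplacian = FALSE, top_n = 10L) {
  st <- heavy_atoms(probe)
  if (n_atoms(st) == 0L) stop("probe has no heavy atoms")
  dims <- dim(map$values)
  if (any(dims < 4L)) stop("map grid too small")
  vox <- map$voxel_size
  ext <- dims * vox
  xyz <- coords(st)
  centroid <- colMeans(xyz)
  span <- apply(xyz, 2, function(v) diff(range(v)))
  if (any(span > ext)) stop("probe larger than map extent")
  if (stats::sd(as.vector(map$values)) == 0) stop("empty (constant) map")

  target <- if (laplacian) laplacian_filter(map) else map
  tvec <- as.vector(target$values)
  N <- length(tvec)
  mu_t <- mean(tvec); sd_t <- stats::sd(tvec)
  Ft_conj <- Conj(stats::fft(array(tvec, dim = dims)))

  sigma <- resolution_sigma(resolution)
  Fk <- stats::fft(wrapped_gaussian_kernel(dims, vox, sigma))
  if (laplacian) Fk <- Fk * stats::fft(wrapped_laplacian_stencil(dims))
  w <- atomic_number(st$atoms$element)
  xyz_c <- sweep(xyz, 2, centroid)

  quats <- orientation_grid(angular_step)
  n_rot <- nrow(quats)
  best_cc <- numeric(n_rot)
  best_shift <- matrix(0L, n_rot, 3)
  for (k in seq_len(n_rot)) {
    R <- quat_to_matrix(quats[k, ])
    xr <- xyz_c %*% t(R)
    delta <- stamp_deltas_wrapped(dims, xr / vox, w)
    Fp <- stats::fft(array(delta, dim = dims)) * Fk
    # probe-map mean and sd from the spectrum (Parseval), shift-invariant
    mu_p <- Re(Fp[1, 1, 1]) / N
    var_p <- (sum(Mod(Fp)^2) / N - N * mu_p^2) / (N - 1)
    if (var_p <= 0) { best_cc[k] <- -Inf; next }
    sd_p <- sqrt(var_p)
    score <- Re(stats::fft(Ft_conj * Fp, inverse = TRUE)) / N
    cc_vol <- (score - N * mu_t * mu_p) / ((N - 1) * sd_t * sd_p)
    imax <- which.max(cc_vol)
    best_cc[k] <- cc_vol[imax]
    i0 <- imax - 1L
    best_shift[k, ] <- c(i0 %% dims[1],
                         (i0 %/% dims[1]) %% dims[2],
                         i0 %/% (dims[1] * dims[2]))
  }

  ord <- order(-best_cc, seq_len(n_rot))
  clusters <- list()
  rot_radius <- 2 * angular_step
  trans_radius <- 1.5 * vox
  for (k in ord) {
    if (!is.finite(best_cc[k])) next
    # centroid target position for this hit (shift is circular)
    tpos <- map$origin + best_shift[k, ] * vox
    tr <- tpos - centroid
    assigned <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (rotation_distance(cl$q, quats[k, ]) <= rot_radius &&
          sqrt(sum((cl$t - tr)^2)) <= trans_radius) {
        clusters[[ci]]$size <- cl$size + 1L
        assigned <- TRUE
        break
      }
    }
    if (!assigned)
      clusters[[length(clusters) + 1L]] <-
        list(q = quats[k, ], t = tr, cc = best_cc[k], size = 1L)
  }
  clusters <- clusters[seq_len(min(top_n, length(clusters)))]
  hits <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(rank = i, qw = cl$q[1], qx = cl$q[2], qy = cl$q[3],
               qz = cl$q[4], tx = cl$t[1], ty = cl$t[2], tz = cl$t[3],
               cc = cl$cc, cluster_size = cl$size)
  }))
  hits$normalized_cc <- hits$cc / hits$cc[1]
  hits <- hits[, c("rank", "qw", "qx", "qy", "qz", "tx", "ty", "tz",
                   "cc", "normalized_cc", "cluster_size")]
  structure(list(hits = hits,
                 settings = list(angular_step = angular_step,
                                 laplacian = laplacian,
                                 resolution = resolution,
                                 n_rotations = n_rot),
                 centroid = centroid),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("dock_result: %d cluster(s) from %d orientations (step %g deg%s)\n",
              nrow(x$hits), x$settings$n_rotations, x$settings$angular_step,
              if (x$settings$laplacian) ", Laplacian" else ""))
  print(utils::head(x$hits[, c("rank", "cc", "normalized_cc", "cluster_size")], 5))
  invisible(x)
}

#' Extract a hit as a pose
#' @param result a `dock_result`.
#' @param rank hit rank (default 1).
#' @return A `pose`.
#' @export
dock_pose <- function(result, rank = 1L) {
  h <- result$hits[result$hits$rank == rank, ]
  if (nrow(h) == 0L) stop("no hit with rank ", rank)
  pose(c(h$qw, h$qx, h$qy, h$qz), c(h$tx, h$ty, h$tz))
}

# exact full-grid Pearson correlation of the map against the probe
# simulated at a pose (NA if the pose throws the probe off-grid)
pose_cc <- function(map, probe, p, resolution, centroid,
                    mask_mode = "full") {
  moved <- apply_pose(probe, p, centroid = centroid)
  xyz <- coords(heavy_atoms(moved))
  d <- dim(map$values)
  hi <- map$origin + (d - 1) * map$voxel_size
  c_new <- colMeans(xyz)
  if (any(c_new < map$origin) || any(c_new > hi)) return(NA_real_)
  sim <- simulate_map_on_grid(moved, map, resolution)
  tryCatch(cross_correlation(map, sim, mask_mode), error = function(e) NA_real_)
}

#' Local rigid-body refinement of a pose
#'
#' Derivative-free pattern search over the six pose parameters, scored
#' by the exact full-grid Pearson correlation between the map and the
#' probe blurred at `resolution`.  Moves are accepted only when they
#' improve the correlation, so the returned value is never below the
#' starting one; the search stops when the trial steps fall below
#' 0.25 degrees and 0.1 Angstrom.  Poses that would move the probe
#' centroid off the map are skipped (a boundary warning is issued if
#' every neighbour of the start is off-grid).
#'
#' @param map target `density_map`.
#' @param probe an `atomic_structure`.
#' @param start starting `pose`.
#' @param resolution blurring resolution in Angstrom.
#' @param init_rot_step,init_trans_step initial step sizes (degrees,
#'   Angstrom).
#' @return List with `pose` and `cc`.
#' @export
refine_pose <- function(map, probe, start, resolution,
                        init_rot_step = 4, init_trans_step = 1) {
  centroid <- colMeans(coords(heavy_atoms(probe)))
  cur <- start
  f_cur <- pose_cc(map, probe, cur, resolution, centroid)
  if (is.na(f_cur)) stop("start pose places the probe outside the map")
  rot_step <- init_rot_step
  trans_step <- init_trans_step
  axes <- diag(3)
  any_off <- FALSE
  while (rot_step >= 0.25 || trans_step >= 0.1) {
    improved <- FALSE
    for (ax in 1:3) for (sgn in c(1, -1)) {
      if (rot_step >= 0.25) {
        qd <- quat_from_axis_angle(axes[ax, ], sgn * rot_step)
        cand <- pose(quat_multiply(qd, cur$quaternion), cur$translation)
        f <- pose_cc(map, probe, cand, resolution, centroid)
        if (is.na(f)) any_off <- TRUE
        else if (f > f_cur) { cur <- cand; f_cur <- f; improved <- TRUE }
      }
      if (trans_step >= 0.1) {
        cand <- pose(cur$quaternion,
                     cur$translation + sgn * trans_step * axes[ax, ])
        f <- pose_cc(map, probe, cand, resolution, centroid)
        if (is.na(f)) any_off <- TRUE
        else if (f > f_cur) { cur <- cand; f_cur <- f; improved <- TRUE }
      }
    }
    if (!improved) {
      rot_step <- rot_step / 2
      trans_step <- trans_step / 2
    }
  }
  if (any_off)
    warning("probe touched the map boundary during refinement; best in-bounds pose returned")
  list(pose = cur, cc = f_cur)
}

#' Refine and rank alternative placements
#'
#' Each candidate (structure, pose) is locally refined in place and
#' then scored against the map with model-support masking; candidates
#' are returned ranked by correlation, the score used to decide which
#' atomic model a given density region belongs to.
#'
#' @param map target `density_map`.
#' @param candidates list of `list(structure = , pose = )` entries
#'   (at least 2, or 1 which is returned scored but unranked against
#'   alternatives).
#' @param resolution blurring resolution in Angstrom.
#' @return Data frame with `index`, `cc`, ordered by cc descending,
#'   with the refined poses in attribute `poses`.
#' @export
compare_placements <- function(map, candidates, resolution) {
  if (length(candidates) < 1L) stop("no candidates")
  ccs <- numeric(length(candidates))
  poses <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    ref <- refine_pose(map, cand$structure, cand$pose, resolution)
    centroid <- colMeans(coords(heavy_atoms(cand$structure)))
    ccs[i] <- pose_cc(map, cand$structure, ref$pose, resolution, centroid,
                      mask_mode = "model_support")
    poses[[i]] <- ref$pose
  }
  ord <- order(-ccs)
  out <- data.frame(index = ord, cc = ccs[ord])
  attr(out, "poses") <- poses[ord]
  out
}
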