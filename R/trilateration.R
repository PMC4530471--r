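#' Spherical-shell locus of an acceptor position
#'
#' Each donor-anchored distance constraint confines the acceptor to a
#' spherical shell around the donor; the locus is the voxelised
#' intersection of all shells.  A voxel with centre x is occupied iff
#' for every constraint i
#' `| ||x - donor_i|| - distance_i | <= max(grid_step, tolerance_scale * uncertainty_i) + h`
#' where `h = sqrt(3)/2 * grid_step` is the voxel half-diagonal: the
#' voxelised locus is an outer cover of the continuous shell
#' intersection, so no part of the true locus is lost at coarse grids
#' and the volume converges from above as the grid is refined.  An
#' empty intersection returns a locus with volume 0 rather than an
#' error: inconsistent distances are a legitimate experimental outcome.
#'
#' @param constraints list of at least 3 [distance_constraint()]s.
#' @param grid_step voxel edge in Angstrom (default 2).
#' @param tolerance_scale multiplier on each constraint's uncertainty
#'   (default 1); the shell half-thickness is never below `grid_step`.
#' @return An object of class `locus_volume` with fields `grid`
#'   (a `density_map` of 0/1 occupancy), `centroid`, `volume` (A^3),
#'   `n_occupied` and `constraints_used`.
#' @export
shell_locus <- function(constraints, grid_step = 2, tolerance_scale = 1) {
  if (length(constraints) < 3L)
    stop("under-determined: at least 3 distance constraints required")
  if (grid_step <= 0) stop("grid_step must be > 0")
  D <- t(vapply(constraints, function(c) c$donor_coord, numeric(3)))
  r <- vapply(constraints, function(c) c$distance, numeric(1))
  u <- vapply(constraints, function(c) c$uncertainty, numeric(1))
  tol <- pmax(grid_step, tolerance_scale * u) + sqrt(3) / 2 * grid_step
  lo <- apply(D - (r + tol), 2, min)
  hi <- apply(D + (r + tol), 2, max)
  dims <- as.integer(ceiling((hi - lo) / grid_step)) + 1L
  gx <- lo[1] + (seq_len(dims[1]) - 1) * grid_step
  gy <- lo[2] + (seq_len(dims[2]) - 1) * grid_step
  gz <- lo[3] + (seq_len(dims[3]) - 1) * grid_step
  occ <- array(TRUE, dim = dims)
  for (i in seq_len(nrow(D))) {
    dx2 <- (gx - D[i, 1])^2
    dy2 <- (gy - D[i, 2])^2
    dz2 <- (gz - D[i, 3])^2
    dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    occ <- occ & (abs(dist - r[i]) <= tol[i])
  }
  n_occ <- sum(occ)
  if (n_occ > 0) {
    idx <- which(occ, arr.ind = TRUE)
    centroid <- c(mean(gx[idx[, 1]]), mean(gy[idx[, 2]]), mean(gz[idx[, 3]]))
  } else {
    centroid <- c(NA_real_, NA_real_, NA_real_)
  }
  structure(list(grid = density_map(occ + 0, grid_step, lo),
                 centroid = centroid,
                 volume = n_occ * grid_step^3,
                 n_occupied = n_occ,
                 constraints_used = constraints),
            class = "locus_volume")
}

#' @export
print.locus_volume <- function(x, ...) {
  cat(sprintf("locus_volume: %d occupied voxels, volume %.1f A^3\n",
              x$n_occupied, x$volume))
  if (x$n_occupied > 0)
    cat(sprintf("  centroid (%.2f, %.2f, %.2f) A\n",
                x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Does a locus contain a point?
#' @param locus a `locus_volume`.
#' @param point length-3 coordinate in Angstrom.
#' @return TRUE if the voxel containing the point is occupied.
#' @export
locus_contains <- function(locus, point) {
  g <- locus$grid
  idx <- round((as.numeric(point) - g$origin) / g$voxel_size) + 1
  d <- dim(g$values)
  if (any(idx < 1 | idx > d)) return(FALSE)
  g$values[idx[1], idx[2], idx[3]] > 0
}

# Closed-form linearised multilateration: subtracting the first sphere
# equation from the others gives a linear system in x.  Used as the
# default starting point for the nonlinear refinement (and, in tests,
# as an independent oracle).
linearised_multilateration <- function(D, r) {
  d1 <- D[1, ]; r1 <- r[1]
  A <- 2 * sweep(D[-1, , drop = FALSE], 2, d1)
  b <- r1^2 - r[-1]^2 + rowSums(D[-1, , drop = FALSE]^2) - sum(d1^2)
  qr.solve(A, b, tol = 1e-12)
}

#' Least-squares point estimate of the acceptor position
#'
#' Minimises `sum_i w_i (||x - donor_i|| - distance_i)^2` with
#' inverse-variance weights (unit weights when uncertainties are zero
#' or absent), using BFGS with analytic gradient from multiple starts:
#' the linearised closed-form solution, the donor centroid and each
#' donor.  With exactly 3 non-collinear donors the problem has two
#' mirror-image solutions symmetric about the donor plane; both are
#' returned and `ambiguity_flag` is set.
#'
#' @param constraints list of at least 3 [distance_constraint()]s.
#' @return List with `coord` (best estimate), `rms_residual`
#'   (Angstrom), `ambiguity_flag`, and `alternate` (the mirror solution
#'   when flagged, else NULL).
#' @export
point_estimate <- function(constraints) {
  if (length(constraints) < 3L)
    stop("under-determined: at least 3 distance constraints required")
  D <- t(vapply(constraints, function(c) c$donor_coord, numeric(3)))
  r <- vapply(constraints, function(c) c$distance, numeric(1))
  u <- vapply(constraints, function(c) c$uncertainty, numeric(1))
  w <- if (all(u > 0)) 1 / u^2 else rep(1, length(r))
  # collinearity check: rank of centred donor matrix
  Dc <- sweep(D, 2, colMeans(D))
  sv <- svd(Dc)$d
  if (sum(sv > 1e-8 * max(sv, 1)) < 2L)
    stop("degenerate geometry: donors are collinear")
  obj <- function(x) {
    dd <- sqrt(colSums((t(D) - x)^2))
    sum(w * (dd - r)^2)
  }
  grad <- function(x) {
    diff <- -(t(D) - x)                 # 3 x n, x - donor_i
    dd <- sqrt(colSums(diff^2))
    dd[dd < 1e-12] <- 1e-12
    as.vector(diff %*% (2 * w * (dd - r) / dd))
  }
  starts <- rbind(
    tryCatch(t(linearised_multilateration(D, r)), error = function(e) NULL),
    colMeans(D), D)
  # coplanar donors leave the whole start set on the donor plane, where
  # the objective is mirror-symmetric; add off-plane starts
  if (sv[3] < 1e-6 * max(sv, 1)) {
    nrm0 <- svd(Dc)$v[, 3]
    starts <- rbind(starts,
                    colMeans(D) + nrm0 * mean(r),
                    colMeans(D) - nrm0 * mean(r))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  x_hat <- best$par
  rms <- sqrt(best$value / sum(w))
  ambiguity <- FALSE; alternate <- NULL
  if (length(constraints) == 3L) {
    # mirror across the donor plane
    nrm <- pracma_cross(D[2, ] - D[1, ], D[3, ] - D[1, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    h <- sum((x_hat - D[1, ]) * nrm)
    if (abs(h) > 1e-6) {
      ambiguity <- TRUE
      alternate <- x_hat - 2 * h * nrm
    }
  }
  list(coord = x_hat, rms_residual = rms,
       ambiguity_flag = ambiguity, alternate = alternate)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Accessible-volume model of a tethered fluorophore
#'
#' @param attachment_atom row index into the structure's atom table.
#' @param linker_length tether radius in Angstrom (default 20).
#' @param clash_distance minimum allowed distance to any protein heavy
#'   atom in Angstrom (default 3).
#' @param n_samples number of uniform trial points (default 2000).
#' @param seed RNG seed making the cloud reproducible.
#' @return An object of class `probe_model`.
#' @export
probe_model <- function(attachment_atom, linker_length = 20,
                        clash_distance = 3.0, n_samples = 2000L, seed = 1L) {
  if (linker_length <= 0) stop("linker_length must be > 0")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  structure(list(attachment_atom = as.integer(attachment_atom),
                 linker_length = linker_length,
                 clash_distance = clash_distance,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "probe_model")
}

#' Sample plausible dye positions around an attachment site
#'
#' Uniform rejection sampling inside the sphere of radius
#' `linker_length` about the attachment atom; trial points closer than
#' `clash_distance` to any protein heavy atom are rejected.  A stand-in
#' for full dye-linker conformational modelling: it yields a physically
#' plausible mean fluorophore position and positional spread.
#'
#' @param structure an `atomic_structure`.
#' @param probe a [probe_model()].
#' @return List with `mean_position`, `position_cloud` (accepted
#'   samples, n x 3), and `acceptance_fraction`.
#' @export
place_probe <- function(structure, probe) {
  heavy <- heavy_atoms(structure)
  if (probe$attachment_atom < 1L || probe$attachment_atom > n_atoms(structure))
    stop("attachment atom index out of range")
  centre <- coords(structure)[probe$attachment_atom, ]
  xyz <- coords(heavy)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(probe$seed)
  # uniform in the ball via radius ~ U^(1/3)
  n <- probe$n_samples
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- probe$linker_length * stats::runif(n)^(1 / 3)
  pts <- sweep(dir * rad, 2, centre, "+")
  # clash test against all heavy atoms
  ok <- rep(TRUE, n)
  cd2 <- probe$clash_distance^2
  for (j in seq_len(nrow(xyz))) {
    dif <- sweep(pts, 2, xyz[j, ])
    ok <- ok & (rowSums(dif^2) >= cd2)
    if (!any(ok)) break
  }
  if (!any(ok)) stop("buried site: no sterically allowed dye positions")
  cloud <- pts[ok, , drop = FALSE]
  list(mean_position = colMeans(cloud),
       position_cloud = cloud,
       acceptance_fraction = mean(ok))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Export a locus as an MRC occupancy map
#' @param locus a `locus_volume`.
#' @param path output MRC file.
#' @return The path, invisibly.
#' @export
write_locus_mrc <- function(locus, path) write_mrc(locus$grid, path)
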