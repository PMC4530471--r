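#' Density maps
#'
#' A `density_map` holds a 3D scalar grid with isotropic voxel size and
#' an origin giving the position (Angstrom) of the centre of grid voxel
#' (1,1,1).  The grid is stored as an R array indexed `[x, y, z]` with x
#' fastest, matching the on-disk layout of MRC/CCP4 maps.
#'
#' @param values 3D numeric array.
#' @param voxel_size voxel edge length in Angstrom.
#' @param origin length-3 numeric, position of voxel (1,1,1) centre.
#' @param resolution_label nominal resolution in Angstrom (provenance
#'   only; not used in computation).
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0),
                        resolution_label = NA_real_) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(values = values,
                 voxel_size = voxel_size,
                 origin = as.numeric(origin),
                 resolution_label = resolution_label),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, %.3f A/voxel, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range [%.4g, %.4g]", min(x$values), max(x$values)))
  if (!is.na(x$resolution_label))
    cat(sprintf(", nominal resolution %.2f A", x$resolution_label))
  cat("\n")
  invisible(x)
}

# Gaussian sigma for a stated resolution under the FWHM convention.
resolution_sigma <- function(resolution) resolution / (2 * sqrt(2 * log(2)))

# Add a separable 3D patch value[i,j,k] = gx[i]*gy[j]*gz[k] into `arr`
# at integer index windows (clipped to the array bounds).
stamp_separable <- function(arr, ix, iy, iz, gx, gy, gz) {
  d <- dim(arr)
  kx <- ix >= 1L & ix <= d[1]; ky <- iy >= 1L & iy <= d[2]
  kz <- iz >= 1L & iz <= d[3]
  if (!any(kx) || !any(ky) || !any(kz)) return(arr)
  patch <- outer(outer(gx[kx], gy[ky]), gz[kz])
  arr[ix[kx], iy[ky], iz[kz]] <- arr[ix[kx], iy[ky], iz[kz]] + patch
  arr
}

# Core Gaussian rasteriser shared by simulate_map() and the docking
# scorer: stamps one isotropic Gaussian of total weight w per point.
rasterise_gaussians <- function(dims, origin, voxel, xyz, weights, sigma,
                                truncation = 4) {
  arr <- array(0, dim = dims)
  amp <- weights / ((2 * pi)^1.5 * sigma^3)   # peak density for unit mass
  r_vox <- ceiling(truncation * sigma / voxel)
  off <- (-r_vox):r_vox
  for (i in seq_len(nrow(xyz))) {
    # nearest voxel index of the atom centre
    c_idx <- round((xyz[i, ] - origin) / voxel) + 1
    ix <- as.integer(c_idx[1] + off)
    iy <- as.integer(c_idx[2] + off)
    iz <- as.integer(c_idx[3] + off)
    gx <- exp(-((origin[1] + (ix - 1) * voxel - xyz[i, 1])^2) / (2 * sigma^2))
    gy <- exp(-((origin[2] + (iy - 1) * voxel - xyz[i, 2])^2) / (2 * sigma^2))
    gz <- exp(-((origin[3] + (iz - 1) * voxel - xyz[i, 3])^2) / (2 * sigma^2))
    arr <- stamp_separable(arr, ix, iy, iz, amp[i] * gx, gy, gz)
  }
  arr
}

#' Simulate a density map from an atomic structure
#'
#' Each heavy atom contributes an isotropic 3D Gaussian centred on its
#' coordinate with FWHM equal to the stated resolution and total
#' integral equal to its atomic number.  The grid spans the structure's
#' bounding box plus `padding` on every side.  Gaussians are truncated
#' at four standard deviations, which keeps 99.9 percent of each atom's
#' mass.
#'
#' @param structure an `atomic_structure` (hydrogens and HETATM records
#'   are excluded).
#' @param resolution target resolution in Angstrom (FWHM of the
#'   blurring Gaussian); must be at least `2 * voxel_size`.
#' @param voxel_size grid spacing in Angstrom.
#' @param padding margin around the bounding box in Angstrom.
#' @return A `density_map`.
#' @export
simulate_map <- function(structure, resolution, voxel_size,
                         padding = 2 * resolution) {
  st <- heavy_atoms(structure)
  if (n_atoms(st) == 0L) stop("structure has no heavy atoms")
  if (resolution < 2 * voxel_size)
    stop("resolution must be >= 2 * voxel_size (Nyquist)")
  xyz <- coords(st)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  sigma <- resolution_sigma(resolution)
  w <- atomic_number(st$atoms$element)
  vals <- rasterise_gaussians(dims, lo, voxel_size, xyz, w, sigma)
  density_map(vals, voxel_size, lo, resolution_label = resolution)
}

#' Simulate a structure's density on an existing map grid
#'
#' Same Gaussian model as [simulate_map()] but rasterised onto the grid
#' geometry of `template`, so the two maps are directly comparable
#' voxel by voxel.
#'
#' @param structure an `atomic_structure`.
#' @param template a `density_map` supplying dims, voxel size, origin.
#' @param resolution blurring resolution in Angstrom.
#' @return A `density_map` on the template grid.
#' @export
simulate_map_on_grid <- function(structure, template, resolution) {
  st <- heavy_atoms(structure)
  if (n_atoms(st) == 0L) stop("structure has no heavy atoms")
  sigma <- resolution_sigma(resolution)
  w <- atomic_number(st$atoms$element)
  vals <- rasterise_gaussians(dim(template$values), template$origin,
                              template$voxel_size, coords(st), w, sigma)
  density_map(vals, template$voxel_size, template$origin,
              resolution_label = resolution)
}

#' Discrete Laplacian filter
#'
#' Applies the 6-neighbour Laplacian stencil (face neighbours summed
#' minus six times the centre, unit lattice spacing) with zero padding
#' at the boundary.  Laplacian filtering emphasises surface and edge
#' features, which adds penalties for shape mismatches when the result
#' is used in correlation scoring.
#'
#' @param map a `density_map` with at least 3 voxels per axis.
#' @return The filtered `density_map`.
#' @export
laplacian_filter <- function(map) {
  v <- map$values
  d <- dim(v)
  if (any(d < 3L)) stop("grid must be at least 3 voxels per axis")
  shift_pad <- function(a, axis, by) {
    out <- array(0, dim = dim(a))
    n <- dim(a)[axis]
    src <- seq_len(n) + by
    ok <- src >= 1L & src <= n
    idx_dst <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
    idx_src <- idx_dst
    idx_dst[[axis]] <- which(ok)
    idx_src[[axis]] <- src[ok]
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  lap <- -6 * v
  for (axis in 1:3) {
    lap <- lap + shift_pad(v, axis, 1L) + shift_pad(v, axis, -1L)
  }
  density_map(lap, map$voxel_size, map$origin, map$resolution_label)
}

#' Resample a map onto another map's grid
#'
#' Trilinear interpolation of `map`'s values at the voxel centres of
#' `template`; points outside `map` evaluate to zero.
#'
#' @param map the `density_map` to resample.
#' @param template the `density_map` whose grid is authoritative.
#' @return A `density_map` on the template grid.
#' @export
resample_map <- function(map, template) {
  d_t <- dim(template$values)
  # voxel-centre positions of the template grid, in source fractional index
  gx <- (template$origin[1] + (seq_len(d_t[1]) - 1) * template$voxel_size -
           map$origin[1]) / map$voxel_size
  gy <- (template$origin[2] + (seq_len(d_t[2]) - 1) * template$voxel_size -
           map$origin[2]) / map$voxel_size
  gz <- (template$origin[3] + (seq_len(d_t[3]) - 1) * template$voxel_size -
           map$origin[3]) / map$voxel_size
  out <- trilinear_sample(map$values, gx, gy, gz)
  density_map(out, template$voxel_size, template$origin, map$resolution_label)
}

# Trilinear interpolation of a 3D array on the tensor grid of fractional
# 0-based indices gx, gy, gz; outside values are zero.
trilinear_sample <- function(v, gx, gy, gz) {
  d <- dim(v)
  f <- function(g, n) {
    i0 <- floor(g); list(i0 = i0 + 1, w1 = g - i0)   # 1-based lower index
  }
  X <- f(gx, d[1]); Y <- f(gy, d[2]); Z <- f(gz, d[3])
  out <- array(0, dim = c(length(gx), length(gy), length(gz)))
  at <- function(ix, iy, iz) {
    okx <- ix >= 1 & ix <= d[1]; oky <- iy >= 1 & iy <= d[2]
    okz <- iz >= 1 & iz <= d[3]
    a <- array(0, dim = c(length(ix), length(iy), length(iz)))
    if (any(okx) && any(oky) && any(okz))
      a[okx, oky, okz] <- v[ix[okx], iy[oky], iz[okz]]
    a
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - X$w1 else X$w1
    wy <- if (dy == 0) 1 - Y$w1 else Y$w1
    wz <- if (dz == 0) 1 - Z$w1 else Z$w1
    w <- outer(outer(wx, wy), wz)
    out <- out + w * at(X$i0 + dx, Y$i0 + dy, Z$i0 + dz)
  }
  out
}

#' Map-to-map cross-correlation
#'
#' Pearson correlation of two maps over a voxel mask.  With
#' `mask_mode = "full"` all voxels count; with `"model_support"` only
#' voxels where `map_b` exceeds 10 percent of its maximum count (the
#' usual convention when `map_b` is a model-simulated map).  If the two
#' grids differ, `map_b` is first resampled onto `map_a`'s grid by
#' trilinear interpolation.
#'
#' @param map_a,map_b `density_map` objects.
#' @param mask_mode "full" or "model_support".
#' @return Pearson correlation in [-1, 1].
#' @export
cross_correlation <- function(map_a, map_b, mask_mode = c("full", "model_support")) {
  mask_mode <- match.arg(mask_mode)
  same_grid <- identical(dim(map_a$values), dim(map_b$values)) &&
    isTRUE(all.equal(map_a$voxel_size, map_b$voxel_size)) &&
    isTRUE(all.equal(map_a$origin, map_b$origin))
  if (!same_grid) map_b <- resample_map(map_b, map_a)
  a <- as.vector(map_a$values)
  b <- as.vector(map_b$values)
  if (mask_mode == "model_support") {
    keep <- b > 0.1 * max(b)
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2L) stop("undefined correlation: empty mask")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance under mask")
  stats::cor(a, b)
}
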