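#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `coords_b` onto
#' `coords_a` in the least-squares sense (SVD with determinant sign
#' correction, so a reflection is never returned).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3, same atom order.
#' @return List with `rotation` (3 x 3, det +1), `translation`
#'   (length 3; the fit is `coords_b %*% t(rotation) + translation`),
#'   and `rmsd` after superposition (Angstrom).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must have equal atom counts")
  if (nrow(coords_a) < 3L) stop("at least 3 atoms required")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% t(R)), rmsd = rmsd)
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix.
#' @param fit result of [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

select_atom_names <- function(atoms, which = c("CA-only", "backbone", "all-heavy")) {
  which <- match.arg(which)
  nm <- atoms$atom_name
  keep <- switch(which,
    "CA-only" = nm == "CA",
    "backbone" = nm %in% c("N", "CA", "C", "O"),
    "all-heavy" = toupper(atoms$element) != "H")
  keep & atoms$record == "ATOM" & toupper(atoms$element) != "H"
}

#' Per-residue RMSD profile between two models
#'
#' One global Kabsch superposition on all paired selected atoms, then
#' the RMSD of each paired residue over its own selected atoms.
#' Residues lacking the selected atoms in either model are skipped and
#' listed in `alignment_note`.
#'
#' @param model_a,model_b `atomic_structure` objects.
#' @param pairing named integer vector mapping residue numbers of
#'   `model_a` to residue numbers of `model_b` (names = a, values = b);
#'   NULL pairs identical residue numbers.
#' @param atoms which atoms to compare: "CA-only" (default),
#'   "backbone" or "all-heavy".
#' @return An object of class `rmsd_profile`: data frame with
#'   `residue_number` (model_a numbering) and `rmsd`, plus attributes
#'   `alignment_note` and `global_rmsd`.
#' @export
per_residue_rmsd <- function(model_a, model_b, pairing = NULL,
                             atoms = c("CA-only", "backbone", "all-heavy")) {
  atoms <- match.arg(atoms)
  a <- model_a$atoms[select_atom_names(model_a$atoms, atoms), , drop = FALSE]
  b <- model_b$atoms[select_atom_names(model_b$atoms, atoms), , drop = FALSE]
  if (is.null(pairing)) {
    res_a <- sort(unique(a$residue_number))
    pairing <- stats::setNames(res_a, res_a)
  }
  if (length(pairing) == 0L) stop("empty residue pairing")
  pa <- c(); pb <- c(); res_kept <- c(); skipped <- c()
  groups <- list()
  for (k in seq_along(pairing)) {
    ra <- as.integer(names(pairing)[k]); rb <- as.integer(pairing[k])
    ia <- which(a$residue_number == ra)
    ib <- which(b$residue_number == rb)
    names_a <- a$atom_name[ia]; names_b <- b$atom_name[ib]
    common <- intersect(names_a, names_b)
    if (length(common) == 0L) { skipped <- c(skipped, ra); next }
    ia <- ia[match(common, names_a)]
    ib <- ib[match(common, names_b)]
    groups[[length(groups) + 1L]] <-
      list(res = ra, ia = ia, ib = ib)
  }
  if (length(groups) == 0L) stop("no residues could be paired")
  ia_all <- unlist(lapply(groups, `[[`, "ia"))
  ib_all <- unlist(lapply(groups, `[[`, "ib"))
  xa <- as.matrix(a[ia_all, c("x", "y", "z")])
  xb <- as.matrix(b[ib_all, c("x", "y", "z")])
  fit <- kabsch_superpose(xa, xb)
  xb_fit <- apply_superposition(xb, fit)
  dev2 <- rowSums((xb_fit - xa)^2)
  offsets <- cumsum(c(0L, vapply(groups, function(g) length(g$ia), integer(1))))
  rmsd <- numeric(length(groups)); resno <- integer(length(groups))
  for (k in seq_along(groups)) {
    idx <- (offsets[k] + 1L):offsets[k + 1L]
    rmsd[k] <- sqrt(mean(dev2[idx]))
    resno[k] <- groups[[k]]$res
  }
  out <- data.frame(residue_number = resno, rmsd = rmsd)
  attr(out, "alignment_note") <- sprintf(
    "%s atoms; %d residues paired; skipped: %s", atoms, length(groups),
    if (length(skipped)) paste(skipped, collapse = ",") else "none")
  attr(out, "global_rmsd") <- fit$rmsd
  class(out) <- c("rmsd_profile", "data.frame")
  out
}

#' Per-secondary-structure-element map correlation
#'
#' Simulates a map from the full model on the target grid, then for
#' each annotated segment computes the Pearson correlation between the
#' experimental and simulated maps over voxels within `local_radius`
#' of the segment's heavy atoms.
#'
#' @param model an `atomic_structure` with an `sse` annotation.
#' @param map target `density_map`.
#' @param resolution blurring resolution in Angstrom.
#' @param local_radius inclusion radius around segment atoms (default 3).
#' @return Data frame with `label`, `kind`, `chain_id`,
#'   `start_residue`, `end_residue`, `cc`, `n_voxels`.
#' @export
per_sse_map_cc <- function(model, map, resolution, local_radius = 3) {
  sse <- attr(model, "sse")
  if (is.null(sse)) stop("model carries no secondary-structure annotation")
  sim <- simulate_map_on_grid(model, map, resolution)
  d <- dim(map$values)
  exp_v <- as.vector(map$values); sim_v <- as.vector(sim$values)
  out <- list()
  for (k in seq_len(nrow(sse))) {
    seg <- sse[k, ]
    a <- heavy_atoms(model)$atoms
    sel <- a$chain_id == seg$chain_id &
      a$residue_number >= seg$start_residue &
      a$residue_number <= seg$end_residue
    if (!any(sel)) { warning("segment ", seg$label, " has no atoms; skipped"); next }
    mask <- voxel_mask_near_atoms(as.matrix(a[sel, c("x", "y", "z")]),
                                  d, map$origin, map$voxel_size, local_radius)
    if (sum(mask) < 2L) { warning("segment ", seg$label, " covers <2 voxels; skipped"); next }
    cc <- suppressWarnings(stats::cor(exp_v[mask], sim_v[mask]))
    out[[length(out) + 1L]] <- data.frame(
      label = seg$label, kind = seg$kind, chain_id = seg$chain_id,
      start_residue = seg$start_residue, end_residue = seg$end_residue,
      cc = cc, n_voxels = sum(mask))
  }
  do.call(rbind, out)
}

# logical vector (flattened) of voxels within `radius` of any point
voxel_mask_near_atoms <- function(xyz, dims, origin, voxel, radius) {
  mask <- array(FALSE, dim = dims)
  r_vox <- ceiling(radius / voxel)
  off <- (-r_vox):r_vox
  for (i in seq_len(nrow(xyz))) {
    ci <- round((xyz[i, ] - origin) / voxel) + 1
    ix <- as.integer(ci[1] + off); iy <- as.integer(ci[2] + off)
    iz <- as.integer(ci[3] + off)
    kx <- ix >= 1L & ix <= dims[1]; ky <- iy >= 1L & iy <= dims[2]
    kz <- iz >= 1L & iz <= dims[3]
    if (!any(kx) || !any(ky) || !any(kz)) next
    px <- origin[1] + (ix[kx] - 1) * voxel - xyz[i, 1]
    py <- origin[2] + (iy[ky] - 1) * voxel - xyz[i, 2]
    pz <- origin[3] + (iz[kz] - 1) * voxel - xyz[i, 3]
    inside <- outer(outer(px^2, py^2, "+"), pz^2, "+") <= radius^2
    mask[ix[kx], iy[ky], iz[kz]] <- mask[ix[kx], iy[ky], iz[kz]] | inside
  }
  as.vector(mask)
}

# Deterministic near-uniform points on the unit sphere (golden-spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic rolling-probe quadrature: near-uniform test points on each
#' atom's expanded sphere (radius = VDW + probe); the unoccluded
#' fraction times the expanded-sphere area is that atom's SASA.
#'
#' @param structure an `atomic_structure` (heavy ATOM atoms are used).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_sphere_points quadrature points per atom (>= 92,
#'   default 960).
#' @return Numeric vector of per-atom areas (A^2) for the heavy atoms,
#'   with the total as attribute `total`.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960L) {
  if (n_sphere_points < 92L) stop("n_sphere_points must be >= 92")
  st <- heavy_atoms(structure)
  xyz <- coords(st)
  rad <- st$atoms$vdw_radius + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  areas <- numeric(n)
  # neighbour lists via squared-distance cutoff
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dif <- sweep(p, 2, xyz[j, ])
      exposed <- exposed & (rowSums(dif^2) > rad[j]^2)
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * rad[i]^2 * mean(exposed)
  }
  attr(areas, "total") <- sum(areas)
  areas
}

#' Interface burial and van der Waals contacts between two chains
#'
#' Buried area is computed by the SASA-difference convention:
#' `(sasa(A) + sasa(B) - sasa(A+B)) / 2` is the headline per-complex
#' value, with the total loss also reported.  Contact pairs are residue
#' pairs with any inter-atomic distance at or below the sum of VDW
#' radii plus `contact_cutoff`.
#'
#' @param chain_a,chain_b `atomic_structure` objects.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param contact_cutoff contact allowance beyond VDW contact in
#'   Angstrom (default 0.4).
#' @param n_sphere_points SASA quadrature density (default 960).
#' @return An object of class `interface_report`: list with
#'   `buried_area` (per complex), `buried_area_total`, and
#'   `contact_pairs` (data frame residue_a, residue_b,
#'   min_atom_distance).
#' @export
interface_report <- function(chain_a, chain_b, probe_radius = 1.4,
                             contact_cutoff = 0.4, n_sphere_points = 960L) {
  if (n_atoms(chain_a) == 0L || n_atoms(chain_b) == 0L)
    stop("both chains must be non-empty")
  ha <- heavy_atoms(chain_a); hb <- heavy_atoms(chain_b)
  sa <- attr(sasa(ha, probe_radius, n_sphere_points), "total")
  sb <- attr(sasa(hb, probe_radius, n_sphere_points), "total")
  combo <- atomic_structure(rbind(ha$atoms, hb$atoms))
  sab <- attr(sasa(combo, probe_radius, n_sphere_points), "total")
  loss <- max(0, sa + sb - sab)
  xa <- coords(ha); xb <- coords(hb)
  ra <- ha$atoms$vdw_radius; rb <- hb$atoms$vdw_radius
  pairs <- list()
  for (i in seq_len(nrow(xa))) {
    d <- sqrt(colSums((t(xb) - xa[i, ])^2))
    hit <- which(d <= ra[i] + rb + contact_cutoff)
    for (j in hit) {
      key <- paste(ha$atoms$residue_number[i], hb$atoms$residue_number[j])
      if (is.null(pairs[[key]]) || d[j] < pairs[[key]]$min_atom_distance)
        pairs[[key]] <- data.frame(
          residue_a = ha$atoms$residue_number[i],
          residue_b = hb$atoms$residue_number[j],
          min_atom_distance = d[j])
    }
  }
  cp <- if (length(pairs)) do.call(rbind, unname(pairs)) else
    data.frame(residue_a = integer(0), residue_b = integer(0),
               min_atom_distance = numeric(0))
  cp <- cp[order(cp$residue_a, cp$residue_b), , drop = FALSE]
  rownames(cp) <- NULL
  structure(list(buried_area = loss / 2, buried_area_total = loss,
                 contact_pairs = cp),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: buries %.1f A^2 per complex (%.1f total), %d contact pair(s)\n",
              x$buried_area, x$buried_area_total, nrow(x$contact_pairs)))
  invisible(x)
}
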