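test_that("Kabsch superposition recovers rigid transforms and matches Horn's method", {
  set.seed(11)
  A <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  q <- random_unit_quaternion()
  R <- fretdock:::quat_to_matrix(q)
  B <- sweep(A %*% t(R), 2, c(4, -7, 2), "+")
  fit <- kabsch_superpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # displaced point: agree with an independent closed-form algorithm
  B2 <- B; B2[4, ] <- B2[4, ] + c(3, 0, 0)
  expect_equal(kabsch_superpose(A, B2)$rmsd, horn_superpose_rmsd(A, B2),
               tolerance = 1e-9)
  # symmetry of the rmsd
  expect_equal(kabsch_superpose(A, B2)$rmsd, kabsch_superpose(B2, A)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_superpose(A, B2[1:5, ]), "equal")
})

test_that("superposition never returns a reflection", {
  set.seed(3)
  A <- matrix(stats::rnorm(15), ncol = 3)
  B <- A %*% diag(c(-1, 1, 1))   # mirror image
  fit <- kabsch_superpose(A, B)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("per-residue RMSD is zero against a rigid copy and flags displaced residues", {
  st <- make_toy_structure(2, 10, seed = 5)
  prof_self <- per_residue_rmsd(st, st)
  expect_true(all(prof_self$rmsd < 1e-9))
  moved <- apply_pose(st, pose(quat_from_axis_angle(c(1, 1, 1), 40),
                               c(3, -2, 8)))
  prof_rigid <- per_residue_rmsd(st, moved, atoms = "all-heavy")
  expect_true(all(prof_rigid$rmsd < 1e-9))
  # displace one residue by 5 A along x
  bumped <- st
  i <- bumped$atoms$residue_number == 7
  bumped$atoms$x[i] <- bumped$atoms$x[i] + 5
  prof <- per_residue_rmsd(st, bumped, atoms = "all-heavy")
  expect_equal(which.max(prof$rmsd), 7L)
  expect_equal(prof$rmsd[7], 5, tolerance = 0.2)
})

test_that("per-residue RMSD equals a naive per-residue recomputation", {
  st <- make_toy_structure(2, 8, seed = 6)
  set.seed(9)
  other <- set_coords(st, coords(st) + matrix(stats::rnorm(3 * n_atoms(st),
                                                           sd = 0.8), ncol = 3))
  prof <- per_residue_rmsd(st, other, atoms = "all-heavy")
  # naive oracle: one global superposition then an explicit residue loop
  xa <- coords(st); xb <- coords(other)
  fit <- kabsch_superpose(xa, xb)
  xb_fit <- apply_superposition(xb, fit)
  for (k in seq_len(nrow(prof))) {
    idx <- st$atoms$residue_number == prof$residue_number[k]
    naive <- sqrt(mean(rowSums((xb_fit[idx, ] - xa[idx, ])^2)))
    expect_equal(prof$rmsd[k], naive, tolerance = 1e-9)
  }
})

test_that("single-sphere SASA matches the analytic area", {
  st <- single_atom_structure()
  a <- sasa(st, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(a[1], 4 * pi * 3.1^2, tolerance = 0.02)
  expect_error(sasa(st, n_sphere_points = 50), "92")
})

test_that("two-sphere SASA matches the spherical-cap closed form", {
  for (d in c(2.0, 3.0, 4.0)) {
    st <- atomic_structure(make_atom_df(c(0, d), c(0, 0), c(0, 0)))
    total <- attr(sasa(st, 1.4, 960), "total")
    expect_equal(total, two_sphere_area(3.1, 3.1, d), tolerance = 0.01)
  }
  # far apart: isolated values
  st_far <- atomic_structure(make_atom_df(c(0, 100), c(0, 0), c(0, 0)))
  a_far <- sasa(st_far, 1.4, 960)
  expect_equal(a_far[1], a_far[2])
  expect_equal(a_far[1], 4 * pi * 3.1^2, tolerance = 0.02)
})

test_that("SASA is invariant under rigid transforms up to quadrature error", {
  # the quadrature points are fixed in the lab frame, so invariance
  # holds only to the angular resolution of the point set
  st <- make_toy_structure(1, 8, seed = 2)
  a1 <- attr(sasa(st, 1.4, 960), "total")
  moved <- apply_pose(st, pose(quat_from_axis_angle(c(0, 1, 2), 65),
                               c(12, -3, 4)))
  a2 <- attr(sasa(moved, 1.4, 960), "total")
  expect_equal(a1, a2, tolerance = 0.005)
})

test_that("interface burial follows the half-SASA-loss convention", {
  # two single-atom chains at touching distance
  d <- 3.0
  a <- atomic_structure(make_atom_df(0, 0, 0, chain = "A"))
  b <- atomic_structure(make_atom_df(d, 0, 0, chain = "B"))
  rep_ab <- interface_report(a, b)
  lost <- 2 * (4 * pi * 3.1^2) - two_sphere_area(3.1, 3.1, d)
  expect_equal(rep_ab$buried_area, lost / 2, tolerance = 0.02 * lost)
  expect_equal(rep_ab$buried_area_total, lost, tolerance = 0.02 * lost)
  expect_equal(nrow(rep_ab$contact_pairs), 1L)
  # symmetry in the chains
  rep_ba <- interface_report(b, a)
  expect_equal(rep_ba$buried_area, rep_ab$buried_area, tolerance = 1e-9)
  # distant chains: nothing buried, no contacts
  far <- atomic_structure(make_atom_df(100, 0, 0, chain = "B"))
  rep_far <- interface_report(a, far)
  expect_equal(rep_far$buried_area, 0)
  expect_equal(nrow(rep_far$contact_pairs), 0L)
})

test_that("contact criterion is inclusive at exactly the VDW sum", {
  a <- atomic_structure(make_atom_df(0, 0, 0, chain = "A"))
  b <- atomic_structure(make_atom_df(3.4, 0, 0, chain = "B"))  # 1.7 + 1.7
  rep0 <- interface_report(a, b, contact_cutoff = 0)
  expect_equal(nrow(rep0$contact_pairs), 1L)
})

test_that("per-segment map correlation is 1 for self-simulated maps and ranks damage", {
  st <- make_toy_structure(3, 8, seed = 4)
  m <- simulate_map(st, 6, 1.5, padding = 9)
  cc <- per_sse_map_cc(st, m, 6)
  expect_equal(nrow(cc), 3L)
  expect_true(all(abs(cc$cc - 1) < 1e-6))
  # zero out the density around helix 2: its cc becomes the minimum
  atoms2 <- st$atoms[st$atoms$residue_number %in% 9:16, ]
  dmg <- m
  mask <- fretdock:::voxel_mask_near_atoms(as.matrix(atoms2[, c("x", "y", "z")]),
                                           dim(m$values), m$origin,
                                           m$voxel_size, 2)
  dmg$values[array(mask, dim = dim(m$values))] <- 0
  cc_dmg <- per_sse_map_cc(st, dmg, 6)
  expect_equal(which.min(cc_dmg$cc), 2L)
  # intensity scaling leaves correlations unchanged
  scaled <- density_map(5 * m$values, m$voxel_size, m$origin)
  expect_equal(per_sse_map_cc(st, scaled, 6)$cc, cc$cc, tolerance = 1e-9)
})
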