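test_that("shell locus contains a point consistent with all constraints", {
  D <- default_donor_sites()[1:4, ]
  p <- c(18, 15, 10)
  cons <- exact_constraints(D, p)
  loc <- shell_locus(cons, grid_step = 2, tolerance_scale = 1)
  expect_gt(loc$volume, 0)
  expect_true(locus_contains(loc, p))
  expect_equal(loc$volume, loc$n_occupied * 2^3)
})

test_that("locus centroid converges to the target and volume grows with tolerance", {
  D <- default_donor_sites()
  p <- default_acceptor_site()
  cons <- exact_constraints(D, p, uncertainty = 0.5)
  fine <- shell_locus(cons, grid_step = 0.5, tolerance_scale = 1e-6)
  expect_lt(sqrt(sum((fine$centroid - p)^2)), 0.5)
  v <- vapply(c(1, 2, 4), function(ts)
    shell_locus(cons, grid_step = 2, tolerance_scale = ts)$volume, numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("inconsistent shells give an empty locus; too few give an error", {
  d1 <- distance_constraint(c(0, 0, 0), 10)
  d2 <- distance_constraint(c(100, 0, 0), 10)
  d3 <- distance_constraint(c(50, 80, 0), 10)
  loc <- shell_locus(list(d1, d2, d3), grid_step = 2)
  expect_equal(loc$volume, 0)
  expect_equal(loc$n_occupied, 0L)
  expect_error(shell_locus(list(d1, d2), grid_step = 2), "under-determined")
  expect_error(point_estimate(list(d1, d2)), "under-determined")
})

test_that("point estimate matches the linearised closed-form oracle on exact data", {
  D <- default_donor_sites()[1:4, ]
  p <- c(22, 18, 12)
  cons <- exact_constraints(D, p)
  pe <- point_estimate(cons)
  expect_lt(sqrt(sum((pe$coord - p)^2)), 1e-3)
  expect_lt(pe$rms_residual, 1e-4)
  # independent closed-form check
  r <- vapply(cons, function(c) c$distance, numeric(1))
  lin <- fretdock:::linearised_multilateration(D, r)
  expect_equal(as.numeric(pe$coord), as.numeric(lin), tolerance = 1e-4)
})

test_that("noisy distances still localise the target to a few Angstrom", {
  D <- default_donor_sites()
  p <- c(25, 20, 12)
  r_true <- sqrt(colSums((t(D) - p)^2))
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    cons <- lapply(1:5, function(i)
      distance_constraint(D[i, ], max(1, r_true[i] + stats::rnorm(1, 0, 2)),
                          2, paste0("D", i)))
    sqrt(sum((point_estimate(cons)$coord - p)^2))
  }, numeric(1))
  expect_lt(stats::median(errs), 3)
})

test_that("three donors give mirror solutions and collinear donors error", {
  D3 <- rbind(c(0, 0, 0), c(30, 0, 0), c(15, 25, 0))
  p <- c(14, 9, 17)   # off-plane target
  pe <- point_estimate(exact_constraints(D3, p))
  expect_true(pe$ambiguity_flag)
  expect_false(is.null(pe$alternate))
  errs <- sort(c(sqrt(sum((pe$coord - p)^2)),
                 sqrt(sum((pe$alternate - p)^2))))
  expect_lt(errs[1], 1e-3)
  mirror <- c(p[1], p[2], -p[3])
  expect_lt(min(sqrt(sum((pe$coord - mirror)^2)),
                sqrt(sum((pe$alternate - mirror)^2))), 1e-3)
  Dlin <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  expect_error(point_estimate(exact_constraints(Dlin, p)),
               "collinear")
})

test_that("locus is invariant under a global rigid transform", {
  D <- default_donor_sites()
  p <- default_acceptor_site()
  cons <- exact_constraints(D, p, uncertainty = 1)
  loc1 <- shell_locus(cons, grid_step = 2)
  q <- quat_from_axis_angle(c(1, 0.5, -0.2), 33)
  R <- fretdock:::quat_to_matrix(q)
  shift <- c(10, -4, 6)
  D2 <- t(R %*% t(D)) + rep(1, 5) %o% shift
  p2 <- as.numeric(R %*% p) + shift
  cons2 <- lapply(seq_len(5), function(i)
    distance_constraint(D2[i, ], cons[[i]]$distance, cons[[i]]$uncertainty))
  loc2 <- shell_locus(cons2, grid_step = 2)
  expect_true(locus_contains(loc2, p2))
  # volumes agree up to re-voxelisation
  expect_equal(loc2$volume, loc1$volume, tolerance = 0.5)
})

test_that("probe placement samples the accessible sphere deterministically", {
  st <- single_atom_structure()
  pm <- probe_model(1, linker_length = 20, clash_distance = 3,
                    n_samples = 4000, seed = 7)
  out <- place_probe(st, pm)
  expect_gt(out$acceptance_fraction, 0.99)
  # mean within 3 standard errors of the attachment coordinate
  se <- apply(out$position_cloud, 2, stats::sd) / sqrt(nrow(out$position_cloud))
  expect_true(all(abs(out$mean_position) < 3 * se + 1e-9))
  out2 <- place_probe(st, pm)
  expect_identical(out$position_cloud, out2$position_cloud)
  # fully buried site errors
  buried <- probe_model(1, linker_length = 20, clash_distance = 30,
                        n_samples = 500, seed = 1)
  expect_error(place_probe(st, buried), "buried")
})
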