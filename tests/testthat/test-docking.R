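test_that("pose algebra: unit quaternions, inverse composition is identity", {
  set.seed(21)
  for (i in 1:10) {
    p <- pose(random_unit_quaternion(), stats::rnorm(3, sd = 5))
    expect_equal(sum(p$quaternion^2), 1, tolerance = 1e-12)
    st <- make_toy_structure(1, 5, seed = i)
    centroid <- colMeans(coords(heavy_atoms(st)))
    back <- apply_pose(apply_pose(st, p, centroid), pose_inverse(p), centroid)
    expect_equal(coords(back), coords(st), tolerance = 1e-6)
  }
})

test_that("orientation grid is deterministic and covers rotation space", {
  g1 <- orientation_grid(30)
  g2 <- orientation_grid(30)
  expect_identical(g1, g2)
  expect_true(all(abs(rowSums(g1^2) - 1) < 1e-12))
  set.seed(5)
  worst <- max(vapply(1:50, function(i) {
    q <- random_unit_quaternion()
    min(apply(g1, 1, function(g) rotation_distance(g, q)))
  }, numeric(1)))
  expect_lt(worst, 30)
  expect_error(orientation_grid(3), "5, 60")
})

test_that("exhaustive search recovers the generative pose within one grid step", {
  st <- make_toy_structure(2, c(12, 7), seed = 3)
  p_true <- pose(quat_from_axis_angle(c(0, 1, 1), 18), c(1.5, -2, 1))
  map <- simulate_map(apply_pose(st, p_true), 6, 1.5, padding = 8)
  res <- exhaustive_search(map, st, 6, angular_step = 30)
  expect_equal(res$hits$normalized_cc[1], 1.0)
  expect_true(all(diff(res$hits$cc) <= 0))
  top <- dock_pose(res, 1)
  expect_lt(rotation_distance(top$quaternion, p_true$quaternion), 30)
  # the grid translation compensates part of the rotational offset, so
  # only the refined pose pins down the translation tightly
  ref <- refine_pose(map, st, top, 6)
  expect_lt(rotation_distance(ref$pose$quaternion, p_true$quaternion), 1)
  expect_lt(sqrt(sum((ref$pose$translation - p_true$translation)^2)), 0.5)
  # cluster representatives are separated by more than the clustering radii
  h <- res$hits
  for (i in seq_len(nrow(h) - 1)) for (j in (i + 1):nrow(h)) {
    rot_d <- rotation_distance(c(h$qw[i], h$qx[i], h$qy[i], h$qz[i]),
                               c(h$qw[j], h$qx[j], h$qy[j], h$qz[j]))
    tr_d <- sqrt((h$tx[i] - h$tx[j])^2 + (h$ty[i] - h$ty[j])^2 +
                   (h$tz[i] - h$tz[j])^2)
    expect_true(rot_d > 2 * 30 || tr_d > 1.5 * map$voxel_size)
  }
})

test_that("search scores are invariant to map intensity scaling and runs are deterministic", {
  st <- make_toy_structure(2, c(10, 6), seed = 8)
  map <- simulate_map(st, 6, 1.5, padding = 8)
  r1 <- exhaustive_search(map, st, 6, angular_step = 45)
  map10 <- density_map(10 * map$values, map$voxel_size, map$origin)
  r2 <- exhaustive_search(map10, st, 6, angular_step = 45)
  expect_equal(r2$hits$cc, r1$hits$cc, tolerance = 1e-9)
  expect_equal(r2$hits$normalized_cc, r1$hits$normalized_cc, tolerance = 1e-12)
  expect_identical(r2$hits[, c("qw", "qx", "qy", "qz", "tx", "ty", "tz")],
                   r1$hits[, c("qw", "qx", "qy", "qz", "tx", "ty", "tz")])
  r3 <- exhaustive_search(map, st, 6, angular_step = 45)
  expect_identical(r1$hits, r3$hits)
})

test_that("refinement improves a perturbed pose and never lowers the score", {
  st <- make_toy_structure(2, c(12, 7), seed = 3)
  p_true <- pose(quat_from_axis_angle(c(1, 0, 0), 10), c(1, 0.5, -1))
  map <- simulate_map(apply_pose(st, p_true), 6, 1.5, padding = 8)
  centroid <- colMeans(coords(heavy_atoms(st)))
  perturbed <- pose(fretdock:::quat_multiply(
    quat_from_axis_angle(c(0, 0, 1), 5), p_true$quaternion),
    p_true$translation + c(1.5, -1, 0.5))
  cc_start <- fretdock:::pose_cc(map, st, perturbed, 6, centroid)
  ref <- refine_pose(map, st, perturbed, 6)
  expect_gte(ref$cc, cc_start)
  expect_lt(rotation_distance(ref$pose$quaternion, p_true$quaternion), 1)
  expect_lt(sqrt(sum((ref$pose$translation - p_true$translation)^2)), 0.5)
  # starting at the optimum stays within the termination tolerance
  ref0 <- refine_pose(map, st, p_true, 6)
  expect_gte(ref0$cc, fretdock:::pose_cc(map, st, p_true, 6, centroid))
  expect_lt(rotation_distance(ref0$pose$quaternion, p_true$quaternion), 4)
})

test_that("placement comparison ranks the complete model above a damaged one", {
  st <- make_toy_structure(2, c(12, 7), seed = 13)
  map <- simulate_map(st, 6, 1.5, padding = 8)
  # candidate B: first helix deleted
  stB <- atomic_structure(st$atoms[st$atoms$residue_number > 12, , drop = FALSE])
  cand <- list(list(structure = st, pose = pose()),
               list(structure = stB, pose = pose()))
  ranked <- compare_placements(map, cand, 6)
  expect_equal(ranked$index[1], 1L)
  expect_gt(ranked$cc[1], ranked$cc[2])
  # duplicate candidates score identically
  dup <- compare_placements(map, list(cand[[1]], cand[[1]]), 6)
  expect_equal(dup$cc[1], dup$cc[2], tolerance = 1e-6)
  # single candidate passes through with its score
  single <- compare_placements(map, list(cand[[1]]), 6)
  expect_equal(nrow(single), 1L)
  expect_gt(single$cc[1], 0.99)
})
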