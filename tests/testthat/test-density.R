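test_that("simulated map integrates to the total atomic number", {
  st <- make_toy_structure(2, 8, seed = 3)
  m <- simulate_map(st, 6, 1.5, padding = 12)
  z_total <- sum(atomic_number(heavy_atoms(st)$atoms$element))
  expect_equal(sum(m$values) * m$voxel_size^3, z_total, tolerance = 0.01)
})

test_that("a single atom's density peaks at the voxel containing it", {
  st <- single_atom_structure()
  m <- simulate_map(st, 6, 1.5, padding = 9)
  peak <- which(m$values == max(m$values), arr.ind = TRUE)
  origin_idx <- round((c(0, 0, 0) - m$origin) / m$voxel_size) + 1
  expect_equal(as.integer(peak[1, ]), as.integer(origin_idx))
})

test_that("translating the structure by whole voxels shifts the grid contents", {
  st <- make_toy_structure(1, 6, seed = 2)
  m1 <- simulate_map(st, 6, 1.5, padding = 9)
  st2 <- set_coords(st, coords(st) + rep(3, 3))  # exactly 2 voxels
  m2 <- simulate_map(st2, 6, 1.5, padding = 9)
  # same padding rule: identical grids up to the shifted origin
  expect_equal(m2$origin, m1$origin + 3)
  expect_equal(m2$values, m1$values, tolerance = 1e-12)
})

test_that("map simulation is linear in the structure", {
  a <- make_toy_structure(1, 6, seed = 4)
  b <- set_coords(a, coords(a) + 8)
  both <- atomic_structure(rbind(a$atoms, transform(b$atoms, serial = serial + 100)))
  template <- simulate_map(both, 6, 1.5, padding = 12)
  ma <- simulate_map_on_grid(a, template, 6)
  mb <- simulate_map_on_grid(b, template, 6)
  expect_equal(ma$values + mb$values, template$values, tolerance = 1e-10)
})

test_that("simulation rejects sub-Nyquist resolution and empty structures", {
  st <- single_atom_structure()
  expect_error(simulate_map(st, 2, 1.5), "Nyquist")
  h_only <- atomic_structure(make_atom_df(0, 0, 0, element = "H"))
  expect_error(simulate_map(h_only, 6, 1.5), "no heavy atoms")
})

test_that("Laplacian filter matches the hand-computed stencil", {
  v <- array(0, dim = c(5, 5, 5))
  v[3, 3, 3] <- 1
  lp <- laplacian_filter(density_map(v, 1))
  expect_equal(lp$values[3, 3, 3], -6)
  expect_equal(lp$values[2, 3, 3], 1)
  expect_equal(lp$values[4, 3, 3], 1)
  expect_equal(lp$values[3, 2, 3], 1)
  expect_equal(lp$values[3, 3, 4], 1)
  expect_equal(lp$values[2, 2, 3], 0)
  expect_equal(sum(lp$values), 0)
  # annihilates constants
  flat <- laplacian_filter(density_map(array(7, dim = c(4, 4, 4)), 1))
  expect_true(all(flat$values[2:3, 2:3, 2:3] == 0))
  # commutes with scaling
  m <- simulate_map(make_toy_structure(1, 5, seed = 1), 6, 1.5, padding = 6)
  m10 <- density_map(10 * m$values, m$voxel_size, m$origin)
  expect_equal(laplacian_filter(m10)$values, 10 * laplacian_filter(m)$values)
  expect_error(laplacian_filter(density_map(array(0, dim = c(2, 5, 5)), 1)),
               "3 voxels")
})

test_that("cross-correlation behaves like a Pearson coefficient", {
  m <- simulate_map(make_toy_structure(2, 6, seed = 5), 6, 1.5, padding = 6)
  expect_equal(cross_correlation(m, m), 1.0)
  aff <- density_map(3.2 * m$values + 1.7, m$voxel_size, m$origin)
  expect_equal(cross_correlation(m, aff), 1.0)
  neg <- density_map(-m$values, m$voxel_size, m$origin)
  expect_equal(cross_correlation(m, neg), -1.0)
  # symmetric under full masking
  other <- simulate_map(make_toy_structure(2, 6, seed = 9), 6, 1.5, padding = 6)
  other_rs <- resample_map(other, m)
  expect_equal(cross_correlation(m, other_rs),
               cross_correlation(other_rs, m))
  flat <- density_map(array(1, dim = dim(m$values)), m$voxel_size, m$origin)
  expect_error(cross_correlation(m, flat), "zero variance")
})

test_that("model-support masking restricts scoring to the model footprint", {
  st <- make_toy_structure(1, 8, seed = 6)
  m <- simulate_map(st, 6, 1.5, padding = 9)
  # corrupt a far corner: full-mask cc drops, model-support cc stays 1
  corrupt <- m
  corrupt$values[1:3, 1:3, 1:3] <- max(m$values)
  expect_lt(cross_correlation(corrupt, m, "full"), 1)
  expect_equal(cross_correlation(corrupt, m, "model_support"), 1.0,
               tolerance = 1e-9)
})

test_that("MRC round trip preserves grid, voxel size and origin", {
  st <- make_toy_structure(1, 6, seed = 8)
  m <- simulate_map(st, 6, 1.5, padding = 6)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, path)
  m2 <- read_mrc(path)
  expect_equal(dim(m2$values), dim(m$values))
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  # float32 storage: a second round trip is bit-exact
  path2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m2, path2)
  m3 <- read_mrc(path2)
  expect_identical(m3$values, m2$values)
  expect_identical(m3$origin, m2$origin)
})

test_that("resampling onto the same grid is the identity", {
  m <- simulate_map(make_toy_structure(1, 5, seed = 2), 6, 1.5, padding = 6)
  rs <- resample_map(m, m)
  expect_equal(rs$values, m$values, tolerance = 1e-12)
})
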