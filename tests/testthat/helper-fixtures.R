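# Shared fixtures and independent oracles used across the test files.

make_atom_df <- function(x, y, z, element = "C", chain = "A",
                         resno = seq_along(x), atom_name = "CA") {
  data.frame(serial = seq_along(x), element = element, x = x, y = y, z = z,
             occupancy = 1, b_factor = 0, chain_id = chain,
             residue_number = resno, residue_name = "ALA",
             atom_name = atom_name, record = "ATOM",
             stringsAsFactors = FALSE)
}

single_atom_structure <- function(element = "C") {
  atomic_structure(make_atom_df(0, 0, 0, element))
}

# Independent superposition oracle: Horn's closed-form quaternion method
# (a different algorithm from the SVD route used in the package).
horn_superpose_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  M <- t(Bc) %*% Ac
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
}

# Closed-form area of two intersecting spheres of radius r1, r2 with
# centre distance d: total outer surface (spherical-cap subtraction).
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  # height of the cap removed from each sphere
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# Exact distance constraints from donors to a known point.
exact_constraints <- function(donors, point, uncertainty = 0.5) {
  lapply(seq_len(nrow(donors)), function(i) {
    distance_constraint(donors[i, ],
                        sqrt(sum((donors[i, ] - point)^2)),
                        uncertainty, paste0("D", i))
  })
}

random_unit_quaternion <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}
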