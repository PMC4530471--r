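#' Synthetic ground-truth data generators
#'
#' Every generator in this file is a pure function of its arguments
#' including the seed, and attaches a `ground_truth` attribute so that
#' downstream recovery can be measured exactly.  The generators emulate
#' the kinds of inputs the pipeline consumes in practice: multi-domain
#' toy structures, blurred density maps with noise, acceptor-photobleach
#' FRET tables generated from a known acceptor position, dye-reported
#' melt sigmoids and one-site binding/dissociation series.
#'
#' @name synthetic
NULL

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

#' Build an idealised multi-helix toy structure
#'
#' Poly-alanine alpha-helices (rise 1.5 Angstrom and 100 degrees per
#' residue; backbone N, CA, C, O plus CB) packed on a hexagonal grid
#' with 10 Angstrom spacing, with a small seeded rigid jitter per
#' helix.  Each helix is annotated as one secondary-structure segment.
#'
#' Identical helix lengths give the bundle an approximate symmetry that
#' is visible at low resolution; pass per-helix lengths to break it
#' when a unique docking solution is wanted.
#'
#' @param n_helices number of helices (>= 1, default 3).
#' @param helix_length residues per helix; scalar or one value per
#'   helix (default 20).
#' @param seed RNG seed.
#' @return An `atomic_structure` with an `sse` annotation.
#' @export
make_toy_structure <- function(n_helices = 3L, helix_length = 20L, seed = 1L) {
  if (n_helices < 1L) stop("n_helices must be >= 1")
  helix_length <- rep(as.integer(helix_length), length.out = n_helices)
  with_seed(seed, {
    # cylindrical parameters of an ideal alpha-helix (radius A, phase
    # offset deg, rise offset A) for each backbone atom type
    geom <- list(N  = c(1.56, -28,  -0.95),
                 CA = c(2.30,   0,   0.00),
                 C  = c(1.64,  27,   1.04),
                 O  = c(1.90,  23,   2.30),
                 CB = c(3.30,  -6,  -0.77))
    elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
    hex <- function(i) {
      row <- (i - 1L) %/% 3L; col <- (i - 1L) %% 3L
      c(col * 10 + (row %% 2L) * 5, row * 8.66, 0)
    }
    rows <- list(); serial <- 0L; res0 <- 0L
    sse_list <- list()
    for (h in seq_len(n_helices)) {
      centre <- hex(h)
      jitter_q <- quat_from_axis_angle(stats::rnorm(3), stats::runif(1, 0, 5))
      Rj <- quat_to_matrix(jitter_q)
      tj <- stats::rnorm(3, 0, 0.5)
      len_h <- helix_length[h]
      for (res in seq_len(len_h)) {
        phi0 <- 100 * (res - 1)
        z0 <- 1.5 * (res - 1)
        for (an in names(geom)) {
          g <- geom[[an]]
          ang <- (phi0 + g[2]) * pi / 180
          p <- c(g[1] * cos(ang), g[1] * sin(ang), z0 + g[3])
          p <- as.numeric(Rj %*% p) + centre + tj
          serial <- serial + 1L
          rows[[serial]] <- data.frame(
            serial = serial, element = elements[[an]],
            x = p[1], y = p[2], z = p[3],
            occupancy = 1, b_factor = 0, chain_id = "A",
            residue_number = res0 + res, residue_name = "ALA",
            atom_name = an, record = "ATOM", stringsAsFactors = FALSE)
        }
      }
      sse_list[[h]] <- data.frame(kind = "helix", chain_id = "A",
                                  start_residue = res0 + 1L,
                                  end_residue = res0 + len_h,
                                  label = sprintf("H%d", h))
      res0 <- res0 + len_h
    }
    sse <- do.call(rbind, sse_list)
    atomic_structure(do.call(rbind, rows),
                     sse = sse_segments(sse$kind, sse$chain_id,
                                        sse$start_residue, sse$end_residue,
                                        sse$label))
  })
}

#' Default synthetic donor-site geometry
#'
#' Five donor positions with pairwise separations between 31 and 59
#' Angstrom, the scale of a handful of dye labelling sites viewed from
#' a binding partner tens of Angstrom away, over which a 59 Angstrom
#' Forster radius is informative.
#'
#' @return 5 x 3 matrix of coordinates (Angstrom), rownames D1..D5.
#' @export
default_donor_sites <- function() {
  rbind(D1 = c(0, 0, 0),
        D2 = c(40, 0, 0),
        D3 = c(20, 34, 0),
        D4 = c(20, 12, 30),
        D5 = c(-2, 34, 22))
}

#' Default synthetic acceptor position
#'
#' Acceptor coordinate used as ground truth in the bundled synthetic
#' FRET scenario: 43 to 75 Angstrom from the [default_donor_sites()],
#' so every donor reports an efficiency in the well-conditioned part
#' of the Forster curve (about 0.19 to 0.87 at R0 = 59 Angstrom).
#'
#' @return Length-3 coordinate (Angstrom).
#' @export
default_acceptor_site <- function() c(48, 44, 38)

#' Simulate an acceptor-photobleach FRET dataset
#'
#' For each donor the true efficiency follows from the Forster relation
#' at the known acceptor position; per cell, Gaussian efficiency noise
#' is added (clipped to [0, 1]) and the result is expressed as a
#' pre-/post-bleach intensity pair with `f_post = 100`.
#'
#' @param donor_coords n x 3 matrix (>= 3 donors) of donor positions.
#' @param acceptor length-3 true acceptor position.
#' @param forster_radius Forster distance R0 in Angstrom (default 59).
#' @param noise_sd_efficiency per-cell efficiency noise SD (default
#'   0.05).
#' @param n_cells cells per donor (default 30, the scale of the
#'   reported 27-36 cells per construct).
#' @param seed RNG seed.
#' @return List of `fret_measurement` (one per donor per cell) with a
#'   `ground_truth` attribute.
#' @export
simulate_fret_dataset <- function(donor_coords, acceptor,
                                  forster_radius = 59,
                                  noise_sd_efficiency = 0.05,
                                  n_cells = 30L, seed = 1L) {
  donor_coords <- as.matrix(donor_coords)
  if (nrow(donor_coords) < 3L) stop("at least 3 donors required")
  if (noise_sd_efficiency < 0) stop("noise_sd must be >= 0")
  sites <- rownames(donor_coords)
  if (is.null(sites)) sites <- paste0("D", seq_len(nrow(donor_coords)))
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(donor_coords))) {
      r_true <- sqrt(sum((donor_coords[i, ] - acceptor)^2))
      e_true <- distance_to_efficiency(r_true, forster_radius)
      e_cells <- pmin(1, pmax(0, e_true + stats::rnorm(n_cells, 0,
                                                       noise_sd_efficiency)))
      for (ec in e_cells) {
        out[[length(out) + 1L]] <- fret_measurement(
          donor_site = sites[i],
          f_prebleach = 100 * (1 - ec), f_postbleach = 100,
          n_cells = 1L)
      }
    }
    attr(out, "ground_truth") <- list(
      acceptor_coord = as.numeric(acceptor),
      donor_coords = donor_coords,
      forster_radius = forster_radius,
      noise_sd_efficiency = noise_sd_efficiency,
      n_cells = n_cells, seed = seed)
    out
  })
}

#' Simulate a noisy density map from a structure
#'
#' [simulate_map()] output plus white Gaussian noise whose variance is
#' the signal variance over the model-support region (voxels above 10
#' percent of the maximum) divided by `snr`.
#'
#' @param structure an `atomic_structure`.
#' @param resolution blurring resolution in Angstrom.
#' @param voxel_size grid spacing in Angstrom.
#' @param snr signal-to-noise variance ratio (> 0; Inf gives the clean
#'   map).
#' @param seed RNG seed.
#' @param padding margin in Angstrom (defaults as in [simulate_map()]).
#' @return A `density_map` with a `ground_truth` attribute.
#' @export
simulate_noisy_map <- function(structure, resolution, voxel_size, snr,
                               seed = 1L, padding = 2 * resolution) {
  if (snr <= 0) stop("snr must be > 0")
  clean <- simulate_map(structure, resolution, voxel_size, padding)
  out <- clean
  if (is.finite(snr)) {
    support <- clean$values > 0.1 * max(clean$values)
    sig_var <- stats::var(clean$values[support])
    out$values <- with_seed(seed, {
      clean$values + array(stats::rnorm(length(clean$values), 0,
                                        sqrt(sig_var / snr)),
                           dim = dim(clean$values))
    })
  }
  attr(out, "ground_truth") <- list(
    structure = structure, generative_pose = pose(),
    resolution = resolution, snr = snr, seed = seed)
  out
}

#' Simulate a dye-reported thermal melt curve
#'
#' Sum of logistic unfolding sigmoids on the 25-95 Celsius grid in 0.5
#' degree steps, a linear post-transition decay segment (aggregation
#' and dye release above the last transition), and Gaussian noise
#' scaled to the total amplitude.
#'
#' @param midpoints transition midpoints in Celsius.
#' @param amplitudes per-transition amplitudes (same length).
#' @param slopes per-transition logistic widths in Celsius (> 0,
#'   default 1.2 each).
#' @param noise_sd noise SD as a fraction of the total amplitude
#'   (default 0).
#' @param seed RNG seed.
#' @return A `melt_curve` with a `ground_truth` attribute.
#' @export
simulate_melt_curve <- function(midpoints, amplitudes = rep(1, length(midpoints)),
                                slopes = rep(1.2, length(midpoints)),
                                noise_sd = 0, seed = 1L) {
  if (length(midpoints) != length(amplitudes) ||
      length(midpoints) != length(slopes))
    stop("midpoints, amplitudes and slopes must have equal length")
  if (any(slopes <= 0)) stop("slopes must be > 0")
  tt <- seq(25, 95, by = 0.5)
  f <- rep(0, length(tt))
  for (k in seq_along(midpoints))
    f <- f + amplitudes[k] / (1 + exp(-(tt - midpoints[k]) / slopes[k]))
  total <- sum(abs(amplitudes))
  if (total > 0) {
    t_decay <- max(midpoints) + 8
    decay <- pmax(0, tt - t_decay) * 0.02 * total
    f <- f - decay
  }
  if (noise_sd > 0 && total > 0)
    f <- f + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd * total))
  curve <- melt_curve(tt, f)
  attr(curve, "ground_truth") <- list(midpoints = midpoints,
                                      amplitudes = amplitudes,
                                      slopes = slopes, noise_sd = noise_sd,
                                      seed = seed)
  curve
}

#' Simulate one-site binding and dissociation series
#'
#' Saturation: 8 log-spaced concentrations spanning kd/30 to 30 kd with
#' signal `bmax c / (kd + c)`.  Dissociation: 12 time points spanning 0
#' to 5/koff with signal `bmax exp(-koff t)`.  Both get multiplicative
#' Gaussian noise of relative SD `noise_sd`.
#'
#' @param kd equilibrium dissociation constant (> 0; any concentration
#'   unit).
#' @param bmax maximal binding signal (> 0).
#' @param koff dissociation rate in 1/min (> 0).
#' @param noise_sd relative noise SD (default 0).
#' @param seed RNG seed.
#' @return List with `saturation` and `dissociation`
#'   [binding_series()] objects and a `ground_truth` attribute.
#' @export
simulate_binding <- function(kd, bmax, koff, noise_sd = 0, seed = 1L) {
  if (kd <= 0 || bmax <= 0 || koff <= 0) stop("kd, bmax, koff must be > 0")
  conc <- exp(seq(log(kd / 30), log(30 * kd), length.out = 8))
  tim <- seq(0, 5 / koff, length.out = 12)
  y_sat <- bmax * conc / (kd + conc)
  y_dis <- bmax * exp(-koff * tim)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(conc) + length(tim), 0,
                                          noise_sd))
    y_sat <- y_sat * (1 + noise[seq_along(conc)])
    y_dis <- y_dis * (1 + noise[length(conc) + seq_along(tim)])
  }
  out <- list(saturation = binding_series(conc, y_sat, "saturation"),
              dissociation = binding_series(tim, y_dis, "dissociation"))
  attr(out, "ground_truth") <- list(kd = kd, bmax = bmax, koff = koff,
                                    noise_sd = noise_sd, seed = seed)
  out
}
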