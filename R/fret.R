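#' FRET measurements and distance constraints
#'
#' Acceptor-photobleach FRET compares donor fluorescence before and
#' after destroying the acceptor: any energy transfer suppresses the
#' donor signal pre-bleach, so the efficiency follows directly from the
#' intensity ratio, and the Forster relation turns it into a
#' donor-acceptor distance.
#'
#' @param donor_site label of the labelled donor position (e.g. "D32").
#' @param f_prebleach,f_postbleach donor intensities before/after
#'   acceptor photobleaching (arbitrary but identical units).
#' @param n_cells number of cells averaged into the intensities.
#' @param sem_efficiency optional standard error of the mean efficiency.
#' @return An object of class `fret_measurement`.
#' @export
fret_measurement <- function(donor_site, f_prebleach, f_postbleach,
                             n_cells = 1L, sem_efficiency = NA_real_) {
  if (f_prebleach < 0 || f_postbleach < 0) stop("intensities must be >= 0")
  if (f_postbleach <= 0) stop("f_postbleach must be > 0")
  if (n_cells < 1L) stop("n_cells must be >= 1")
  structure(list(donor_site = donor_site,
                 f_prebleach = f_prebleach,
                 f_postbleach = f_postbleach,
                 n_cells = as.integer(n_cells),
                 sem_efficiency = sem_efficiency),
            class = "fret_measurement")
}

#' A donor-anchored distance constraint
#'
#' @param donor_coord length-3 donor position in Angstrom.
#' @param distance FRET-derived donor-acceptor distance in Angstrom.
#' @param uncertainty 1-sigma distance uncertainty in Angstrom.
#' @param donor_site label.
#' @return An object of class `distance_constraint`.
#' @export
distance_constraint <- function(donor_coord, distance, uncertainty = 0,
                                donor_site = "") {
  if (distance <= 0) stop("distance must be > 0")
  if (uncertainty < 0) stop("uncertainty must be >= 0")
  structure(list(donor_coord = as.numeric(donor_coord),
                 distance = distance, uncertainty = uncertainty,
                 donor_site = donor_site),
            class = "distance_constraint")
}

#' FRET efficiency from pre-/post-bleach donor intensities
#'
#' E = 1 - F_prebleach / F_postbleach.  Noisy no-transfer data can give
#' E <= 0; the value is returned as computed, with a `below_zero`
#' attribute flagging it so callers can exclude the constraint.
#'
#' @param measurement a `fret_measurement` (or anything with
#'   `f_prebleach`/`f_postbleach` fields).
#' @return FRET efficiency (dimensionless), attribute `below_zero`.
#' @export
fret_efficiency <- function(measurement) {
  if (measurement$f_postbleach == 0) stop("f_postbleach is zero")
  e <- 1 - measurement$f_prebleach / measurement$f_postbleach
  attr(e, "below_zero") <- e <= 0
  e
}

#' Convert a FRET efficiency to a donor-acceptor distance
#'
#' R = R0 * (1/E - 1)^(1/6), the inverse of the sixth-power Forster
#' relation.  E = 1 maps to R = 0; efficiencies at or below zero have
#' no finite distance and raise an error.
#'
#' @param efficiency FRET efficiency in (0, 1].
#' @param forster_radius Forster distance R0 in Angstrom (59 for the
#'   AF488/Cy3NTA pair).
#' @return Distance in Angstrom.
#' @export
efficiency_to_distance <- function(efficiency, forster_radius = 59) {
  if (forster_radius <= 0) stop("forster_radius must be > 0")
  if (any(efficiency <= 0 | efficiency > 1))
    stop("efficiency must lie in (0, 1]")
  forster_radius * (1 / efficiency - 1)^(1 / 6)
}

#' Forster efficiency at a given donor-acceptor distance
#'
#' E = 1 / (1 + (R/R0)^6); exact inverse of [efficiency_to_distance()].
#'
#' @param distance donor-acceptor distance in Angstrom (>= 0).
#' @param forster_radius Forster distance R0 in Angstrom.
#' @return FRET efficiency in (0, 1].
#' @export
distance_to_efficiency <- function(distance, forster_radius = 59) {
  if (forster_radius <= 0) stop("forster_radius must be > 0")
  if (any(distance < 0)) stop("distance must be >= 0")
  1 / (1 + (distance / forster_radius)^6)
}

#' First-order distance uncertainty from an efficiency s.e.m.
#'
#' Propagates the standard error of a mean efficiency through the
#' Forster conversion: sigma_R = |dR/dE| * sem with
#' dR/dE = -(R0/6) * (1/E - 1)^(-5/6) / E^2.
#'
#' @param efficiency mean FRET efficiency, strictly inside (0, 1).
#' @param sem_efficiency standard error of the mean efficiency.
#' @param forster_radius Forster distance R0 in Angstrom.
#' @return Distance uncertainty in Angstrom (>= 0).
#' @export
propagate_distance_uncertainty <- function(efficiency, sem_efficiency,
                                           forster_radius = 59) {
  if (any(efficiency <= 0 | efficiency >= 1))
    stop("derivative unbounded: efficiency must be strictly inside (0, 1)")
  if (any(sem_efficiency < 0)) stop("sem must be >= 0")
  dRdE <- (forster_radius / 6) * (1 / efficiency - 1)^(-5 / 6) / efficiency^2
  abs(dRdE) * sem_efficiency
}

#' Convert a table of FRET measurements to distance constraints
#'
#' Per donor site the per-cell efficiencies are averaged first and the
#' mean is converted to a single distance; sites whose mean efficiency
#' is not strictly positive (no measurable transfer) yield a flagged
#' null constraint that is excluded from trilateration.
#'
#' @param measurements list of `fret_measurement` (possibly several per
#'   donor site, one per cell).
#' @param donor_coords named list or matrix of donor coordinates
#'   (Angstrom), names matching donor sites.
#' @param forster_radius Forster distance R0 in Angstrom.
#' @return List of `distance_constraint` (null sites dropped), with a
#'   `dropped_sites` attribute listing excluded donor sites.
#' @export
measurements_to_constraints <- function(measurements, donor_coords,
                                        forster_radius = 59) {
  sites <- vapply(measurements, function(m) m$donor_site, character(1))
  effs <- vapply(measurements, function(m) as.numeric(fret_efficiency(m)),
                 numeric(1))
  out <- list(); dropped <- character(0)
  for (s in unique(sites)) {
    e_cells <- effs[sites == s]
    e_bar <- mean(e_cells)
    if (e_bar <= 0 || e_bar > 1) { dropped <- c(dropped, s); next }
    sem <- if (length(e_cells) > 1L)
      stats::sd(e_cells) / sqrt(length(e_cells)) else 0
    r <- efficiency_to_distance(e_bar, forster_radius)
    u <- if (sem > 0 && e_bar < 1)
      propagate_distance_uncertainty(e_bar, sem, forster_radius) else 0
    dc <- if (is.matrix(donor_coords)) donor_coords[s, ] else donor_coords[[s]]
    out[[s]] <- distance_constraint(dc, r, u, donor_site = s)
  }
  attr(out, "dropped_sites") <- dropped
  out
}
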