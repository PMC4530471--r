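# fretdock

Integrative localisation of protein domains inside large
macromolecular assemblies, in R.

When a crystal structure of an isolated domain exists but its position
inside the parent assembly is uncertain, three independent lines of
quantitative evidence are commonly combined: (1) rigid-body docking of
the atomic model into a density map of the whole assembly, scored by
cross-correlation; (2) FRET-based trilateration, which localises a
fluorescent acceptor attached to the domain from its distances to
several donor fluorophores at known positions; and (3) biochemical
assays — thermal-shift melting and binding kinetics — that test the
structural hypothesis functionally.  `fretdock` implements all three
stages, the model-comparison metrics used to judge competing
placements, and seeded synthetic-data generators with known ground
truth for every input, so the whole pipeline can be validated end to
end.

## The core quantities

* **Docking score.** The probe structure is blurred to the map
  resolution (atomic Gaussians, FWHM = resolution, mass = atomic
  number) and scored against the map by the Pearson correlation
  coefficient over the grid; an exhaustive, deterministic search over
  all rotations (super-Fibonacci orientation grid) and translations
  (FFT scan) ranks poses by `cc`, reported alongside
  `normalized_cc = cc / cc_top`.  Optional Laplacian filtering of both
  maps adds penalties for mismatched surface features.
* **FRET.** Acceptor-photobleach efficiency
  `E = 1 − F_pre / F_post` converts to a donor–acceptor distance by
  the Förster relation `R = R0 (1/E − 1)^(1/6)` (default
  `R0 = 59 Å`, the AF488/Cy3NTA pair).  Each donor constrains the
  acceptor to a spherical shell; the acceptor locus is the voxelised
  intersection of all shells, with a weighted least-squares point
  estimate.
* **Model comparison.** Kabsch superposition, per-residue RMSD
  profiles, per-secondary-structure-element map correlation,
  Shrake–Rupley solvent-accessible areas, interface burial
  `(SASA_A + SASA_B − SASA_AB)/2` and van der Waals contact lists.
* **Assays.** Melting temperatures as maxima of the first derivative
  of normalised melt curves (multi-transition aware), hyperbolic
  saturation fits (`Kd`, `Bmax`), and single-exponential dissociation
  fits (`koff = 1/τ`).

## Worked example

Localise a synthetic acceptor from five noisy FRET measurements
(efficiency noise 0.05, 30 cells per donor):

```r
library(fretdock)

D   <- default_donor_sites()      # five donors, pairwise 31-59 A
acc <- default_acceptor_site()    # ground truth: (48, 44, 38)

fret <- simulate_fret_dataset(D, acc, forster_radius = 59,
                              noise_sd_efficiency = 0.05,
                              n_cells = 30, seed = 1)
cons <- measurements_to_constraints(fret, D, forster_radius = 59)
shell_locus(cons, grid_step = 2, tolerance_scale = 2)
#> locus_volume: 88 occupied voxels, volume 704.0 A^3
#>   centroid (48.28, 43.24, 37.87) A
point_estimate(cons)$coord
#> [1] 48.6 43.6 37.7        # 0.78 A from the true acceptor
```

Dock a three-helix toy structure back into its own 6 Å map (SNR 2)
from an unbiased 20° search with Laplacian filtering:

```r
st    <- make_toy_structure(3, c(24, 16, 10), seed = 7)
truth <- pose(quat_from_axis_angle(c(1, 1, 0), 25), c(2, -1, 1.5))
map   <- simulate_noisy_map(apply_pose(st, truth), resolution = 6,
                            voxel_size = 1.5, snr = 2, seed = 11)
hits  <- exhaustive_search(map, st, resolution = 6, angular_step = 20,
                           laplacian = TRUE)
hits
#> dock_result: 10 cluster(s) from 2676 orientations (step 20 deg, Laplacian)
#>   rank         cc normalized_cc cluster_size
#> 1    1 0.03086592     1.0000000            8
#> 2    2 0.02326345     0.7536939            5
refine_pose(map, st, dock_pose(hits, 1), resolution = 6)
#> refined pose: 0.8 deg / 0.06 A from the generative pose
```

The top cluster stands far above the rest (`normalized_cc` drops to
0.75 by rank 2) and refinement recovers the generative pose to well
under a degree and a tenth of an Angstrom.

Fit a two-transition melt and a binding pair:

```r
melting_temperatures(simulate_melt_curve(c(33.6, 39.6),
                                         amplitudes = c(1, 1)))
#> melt_result: 2 transition(s), Tm = 33.5, 39.5 degC

b <- simulate_binding(kd = 0.8, bmax = 120, koff = 0.15,
                      noise_sd = 0.05, seed = 7)
fit_saturation(b$saturation)$fitted[c("kd", "bmax")]
#> Kd = 0.93 +/- 0.09, Bmax = 120 +/- 3
fit_dissociation(b$dissociation)$fitted$koff
#> 0.139 min^-1
```

A thin command-line front end over the same functions lives at
`inst/cli/fretdock.R` (subcommands `simulate-map`, `dock`,
`fret-distances`, `trilaterate`, `compare-models`, `interface`,
`melt-tm`, `binding-fit`, `simulate-data`).

See `vignettes/methods.Rmd` for the models, parameter defaults, and
the package's numerical design decisions.

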