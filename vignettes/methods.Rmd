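---
title: "Methods: integrative domain localisation with fretdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative domain localisation with fretdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdock)
```

# Scope

`fretdock` implements the quantitative core of an integrative
localisation study: placing an atomic domain structure inside the
density map of a large assembly, independently confirming the placement
by FRET-based trilateration, comparing alternative atomic models, and
fitting the thermal-stability and binding assays that accompany such
work.  Every stage has a seeded synthetic-data generator with known
ground truth, so the whole pipeline is testable end to end without any
downloads.

This vignette records the models, the tunable parameters, and the
design decisions taken where several defensible choices existed.  It
states no empirical result that the test suite does not itself
recompute.

# Density simulation and scoring

## Gaussian blurring

`simulate_map()` places an isotropic 3D Gaussian on every heavy atom.
The width convention is **FWHM = stated resolution**, i.e.
$\sigma = \mathrm{res} / (2\sqrt{2\ln 2})$, a common real-space
convention for "blurring a model to a resolution"; it is isolated in
one internal helper so an alternative convention can be swapped in.
Each atom's Gaussian integrates to its atomic number (hydrogens are
excluded throughout, as are HETATM records by default).  Gaussians are
truncated at $4\sigma$: a $3\sigma$ cut, often used for speed, keeps
only 97.1% of a 3D Gaussian's mass and would visibly violate the
integral identity $\sum_v \rho_v \cdot a^3 \approx \sum_i Z_i$ that
the tests enforce to 1%; $4\sigma$ keeps 99.89%.

Parameters: `resolution` (Å, must be at least twice the voxel size),
`voxel_size` (Å, default 1.5), `padding` (Å, default twice the
resolution so that truncated tails stay on-grid).

## Laplacian filtering

`laplacian_filter()` applies the discrete 6-neighbour stencil (face
neighbours minus six times the centre, unit lattice spacing, zero
padding at the boundary).  Because the second derivative concentrates
weight at surfaces, correlating Laplacian-filtered maps penalises
shape mismatches that a plain density correlation tolerates.  In the
docking search the filter is applied to **both** the target map and
the probe density; filtering only one side would correlate unlike
quantities.  The full grid is always correlated — surface penalties
come from the filter, not from a mask.

## Correlation

`cross_correlation()` is a plain Pearson coefficient over a voxel set:
the `full` grid, or `model_support` — voxels where the model-simulated
map exceeds 10% of its maximum, the usual choice when a small model is
scored inside a much larger map.  Grid mismatches are resolved by
trilinear resampling onto the first map's grid.

# Exhaustive six-dimensional docking

`exhaustive_search()` enumerates a fixed, deterministic orientation
grid (a super-Fibonacci spiral on the quaternion 3-sphere; the number
of points is chosen so the empirical covering radius stays below the
requested `angular_step`).  For each rotation the probe atoms are
stamped onto the map grid as trilinear-weighted point masses and
blurred by multiplying with the Gaussian kernel's Fourier transform;
one FFT cross-correlation then scores **every** translation at once.
Because a circular shift changes neither the mean nor the variance of
the probe grid, the raw correlation sum converts exactly to a
full-grid Pearson coefficient per translation — the scores reported in
the hit list are true correlation coefficients, and scaling the map
leaves them unchanged.

Hits (best translation per rotation) are clustered greedily in score
order: a hit joins an existing cluster when it is within
`2 * angular_step` in rotation **and** 1.5 voxels in translation of
the representative; otherwise it founds a new cluster.  Ranking is by
correlation, ties broken by enumeration index, so results are
bit-reproducible.  `normalized_cc` divides by the top score, giving
the familiar "top hit = 1.0" presentation for judging how much a
candidate placement stands out from the noise floor.

`refine_pose()` polishes a pose by derivative-free pattern search over
the six parameters, scored by the exact Pearson correlation of the
exactly re-simulated probe map (not the delta-stamp approximation).
Steps start at 4° / 1 Å, halve on failure, and terminate below
0.25° / 0.1 Å; only improving moves are accepted, so the returned
correlation can never fall below the starting one.

`compare_placements()` refines each candidate placement and scores it
with `model_support` masking — the operation behind "which domain
does this density belong to" comparisons.

The spherical-harmonic rotational acceleration of the original search
tools is deliberately **not** reproduced: at the package's scale (maps
of ~$40^3$ voxels, probes of a few hundred atoms) the FFT translation
scan with a few thousand explicit rotations fulfils the same contract
— an unbiased, deterministic 6D search ranked by correlation.

# FRET efficiencies and Förster distances

Acceptor-photobleach FRET gives the efficiency directly from donor
intensities before and after destroying the acceptor:

$$E = 1 - F_\mathrm{prebleach} / F_\mathrm{postbleach},\qquad
  R = R_0\,(1/E - 1)^{1/6}.$$

These are the standard acceptor-photobleach and sixth-power Förster
forms consistent with the variable definitions of the experimental
protocol this package models; the default Förster radius is the
AF488/Cy3NTA pair value, $R_0 = 59$ Å.  Uncertainty is propagated to
first order, $\sigma_R = |dR/dE|\,\sigma_E$ with
$dR/dE = -(R_0/6)(1/E-1)^{-5/6}/E^2$.

**Averaging order.** Per-cell efficiencies are averaged first and the
mean is converted to a single distance per donor site (matching the
mean ± s.e.m. per-construct reporting convention of such experiments);
`measurements_to_constraints()` implements this and drops donor sites
whose mean efficiency is not strictly positive (no measurable
transfer) as flagged null constraints.

Note the conditioning of the conversion: $|dR/dE|$ is smallest near
$E \approx 0.5$ and diverges at both ends, so distances far from $R_0$
carry large uncertainties.  This drives the synthetic geometry choices
below.

# Trilateration

## Shell locus

Each constraint confines the acceptor to a spherical shell around its
donor; `shell_locus()` voxelises the intersection of all shells.  A
voxel is occupied when, for every constraint,

$$\bigl|\;\|x_c - d_i\| - r_i\;\bigr| \le
  \max(\mathrm{grid\_step},\; \mathrm{tolerance\_scale}\cdot u_i)
  + \tfrac{\sqrt3}{2}\,\mathrm{grid\_step},$$

with $x_c$ the voxel centre.  The half-diagonal term makes the
voxelised locus an **outer cover** of the continuous intersection:
with a pure centre test, a point that satisfies every shell can still
land in a voxel whose centre misses one shell by up to the
half-diagonal (1.73 Å at the default 2 Å grid), silently dropping
parts of the true locus at coarse grids.  The cover converges to the
true intersection from above as the grid is refined.  Defaults:
`grid_step` 2 Å, `tolerance_scale` 1.  An empty intersection is a
legitimate result (volume 0), not an error — mutually inconsistent
distances are exactly what a wrong structural hypothesis produces.
The locus can be exported as an MRC occupancy map
(`write_locus_mrc()`) for display as a volume in any viewer.

## Point estimate

`point_estimate()` minimises
$\sum_i w_i(\|x-d_i\| - r_i)^2$ with inverse-variance weights (unit
weights when uncertainties are absent), by BFGS with analytic gradient
from multiple starts: the linearised closed-form multilateration
solution, the donor centroid, and each donor.  When the donors are
coplanar every natural start lies on the symmetry plane of the
objective, where the out-of-plane gradient vanishes identically — two
additional starts offset along the plane normal break this trap.
With exactly three (non-collinear) donors both mirror solutions are
returned and `ambiguity_flag` is set; collinear donors are a
degenerate-geometry error.

## Probe placement

The dye-position protocol referenced by such studies (simulated
annealing of an explicitly modelled dye) is replaced by a documented
accessible-volume sampler, `place_probe()`: uniform rejection sampling
in the sphere of radius `linker_length` (default 20 Å) around the
attachment atom, rejecting samples within `clash_distance` (default
3 Å) of any protein heavy atom.  It fulfils the same contract — a
physically plausible mean fluorophore position with a positional
spread — at desk scale and deterministically per seed.

# Model comparison

* `kabsch_superpose()`: SVD-based least-squares superposition with
  determinant sign correction (never a reflection).  The test suite
  cross-checks it against an independently implemented closed-form
  quaternion (Horn) method.
* `per_residue_rmsd()`: one **global** superposition on all paired
  selected atoms, then per-residue RMSDs — the convention behind
  per-residue deviation plots.  Atom selection defaults to Cα-only
  (the usual choice for such plots; backbone and all-heavy are
  options).  Residues missing selected atoms are skipped and listed in
  the alignment note.  Cross-isoform comparisons take an explicit
  residue pairing; no automatic sequence alignment is attempted.
* `per_sse_map_cc()`: per-segment correlation between an experimental
  map and the full-model simulated map over voxels within
  `local_radius` (default 3 Å) of the segment's atoms — the
  per-secondary-structure-element quality profile used to judge
  flexible-fitting results.
* `sasa()`: Shrake–Rupley quadrature, probe 1.4 Å, 960 golden-spiral
  points per atom (~0.1% quadrature error on a sphere).  Because the
  point set is fixed in the laboratory frame, SASA is rigid-invariant
  only to quadrature accuracy — the tests assert 0.5%.
* `interface_report()`: buried area by the SASA-difference convention.
  Both the per-complex value $(S_A + S_B - S_{AB})/2$ and the total
  loss are reported, since published burial figures do not always
  state which convention they use; the per-complex value is the
  headline field.  Van der Waals contacts are residue pairs with any
  inter-atomic distance at or below the sum of VDW radii plus a 0.4 Å
  allowance (bundled radii: C 1.70, N 1.55, O 1.52, S 1.80, default
  1.70 Å).

# Assay fitting

## Thermal melts

`melting_temperatures()` min-max normalises the curve, smooths with a
Savitzky–Golay polynomial (window 7, order 2), differentiates by
central differences, and reports maxima of $+dF/dT$ — the convention
for hydrophobic-dye reporters, whose fluorescence rises on unfolding.
Peak search is restricted to temperatures before the global
fluorescence maximum, excluding the post-aggregation decay, and peaks
must have topographic prominence of at least `min_prominence`
(default 0.1) of the derivative range — enough to separate a genuine
second transition from shoulder noise.  Min-max normalisation makes
the result exactly invariant under affine transforms of the raw
fluorescence.  Tm resolution is limited by the temperature step
(0.5 °C on the standard 25–95 °C grid); no Boltzmann fit is attempted
because the derivative-peak definition is what the modelled protocol
states.  The defaults resolve clean curves; for noisy instrument data
the smoothing window and prominence threshold are the knobs to raise —
at ~1% amplitude noise the default prominence can still admit a
spurious shoulder peak near the fluorescence maximum.

## Binding

`fit_saturation()` fits $y = B_\mathrm{max} c/(K_d + c) + b$ and
`fit_dissociation()` fits $y = A e^{-t/\tau} + b$ with
$k_\mathrm{off} = 1/\tau$, both by Levenberg–Marquardt with
deterministic initialisation (half-rise concentration; log-linear
regression).  The baseline is fitted, not forced to zero — background
fluorescence exists in cell-based assays.  Fits are unweighted by
default (per-point inverse-variance weighting would require replicate
counts that summary tables rarely carry).  Curvature-free saturation
data produce an `ill_conditioned` warning with infinite standard
errors rather than a silent bad fit.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of their arguments including the
seed, restore the caller's RNG state, and attach their ground truth.

* `make_toy_structure()`: idealised poly-alanine α-helices (1.5 Å
  rise, 100°/residue, backbone + Cβ) on a hexagonal 10 Å grid with a
  small seeded jitter.  **Identical helix lengths make the bundle
  approximately symmetric at low resolution**, so docking tests use
  unequal lengths (24/16/10 residues) to make the generative pose
  unique; this is a property of the study structure, not of the
  search.
* `simulate_noisy_map()`: white Gaussian noise with variance set by
  the signal variance over model support divided by `snr`.  No CTF,
  projection artefacts, solvent flattening or B-factor falloff — the
  generator emulates a real-space blurred reconstruction, not image
  formation, so passing recovery tests says nothing about those
  effects.
* `simulate_fret_dataset()`: per-cell Gaussian efficiency noise
  (σ = 0.05, 30 cells per donor — the scale of the modelled
  experiments), clipped to [0, 1], expressed as pre-/post-bleach
  intensity pairs.  The default five donor sites
  (`default_donor_sites()`) have pairwise separations of 31–59 Å; the
  default ground-truth acceptor (`default_acceptor_site()`) lies 43–75
  Å away, so all five efficiencies fall in the well-conditioned 0.19–
  0.87 range — mirroring a real design where every labelling site
  produces measurable transfer.  Placing the acceptor closer than
  ~36 Å to a donor (E > 0.95) makes the clipped-noise mean biased and
  the conversion derivative explode; that regime is deliberately
  avoided in the defaults and is a documented limitation of
  photobleach FRET, not of the pipeline.
* `simulate_melt_curve()`: sums of logistic sigmoids (width 1.2 °C) on
  the 25–95 °C, 0.5 °C grid, plus a linear post-transition decay so
  the curve has the interior maximum real dye melts show.
* `simulate_binding()`: 8 log-spaced concentrations over
  $K_d/30 \ldots 30K_d$ and 12 time points over $0 \ldots 5/k_\mathrm{off}$,
  multiplicative Gaussian noise.

Noise is Gaussian throughout; heavier-tailed cell-to-cell variation
would widen the recovery bands.

# Problem sizes and numerical conventions

The bundled tests run at deliberately desk-sized conditions: maps of
roughly $40^3$ voxels at 1.5 Å, probes of 150–300 atoms, a 20°
orientation grid (~2700 rotations) for the full recovery check and
30–45° for unit tests, 100-seed replicate sets for the stochastic
recovery bands.  A production-scale search would use a 10° grid and
proportionally larger maps; nothing in the algorithms changes.

Conventions worth restating: coordinates are Å in a right-handed
frame; residue numbering is taken verbatim from input files; alt-locs
resolve to the highest-occupancy conformer (ties by alt-loc letter);
MRC output is mode-2 float, X-fastest, with the origin in the ORIGIN
header words; all correlations are Pearson; all seeds are plain R
integer seeds.

# Known limitations

* Docking assumes a rigid probe; flexible fitting is out of scope
  (only its assessment metrics — per-residue RMSD and per-segment
  correlation — are provided).
* The FFT translation scan uses circular convolution; probe density
  near the map boundary can wrap.  With the default padding (twice
  the resolution) the wrapped mass is negligible, but maps cropped
  tightly around the target should be padded before searching.
* The accessible-volume probe model ignores dye shape, linker
  statistics and orientation factors (κ² is fixed inside the supplied
  R0).
* Buried-area and contact values depend on the bundled VDW radii and
  the 0.4 Å contact allowance; radii tables differ between programs
  at the few-percent level.
* Tm is reported at the derivative-peak temperature: for strongly
  asymmetric transitions this differs from a thermodynamic midpoint
  fit.
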