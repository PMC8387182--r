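---
title: "Virtual 3D measurement of atrial septal defects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual 3D measurement of atrial septal defects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoasd)
```

# The problem

Sizing an atrial septal defect (ASD) — the long diameter, short diameter and
area of the hole in the interatrial septum — drives the choice of closure
device. 2D echo shows only cross-sections; a 3D "virtual measurement" system
sweeps the heart with a rotational 2D probe (or acquires four real-time 3D
wedges), reconstructs a Cartesian volume, despeckles and segments it, and
measures the defect in physical units on the reconstructed anatomy.

Real ex vivo specimens are not distributable, so this package couples the
measurement pipeline to a digital phantom with *known* defect geometry. Every
recovered measurement can therefore be compared with its exact ground truth,
and the original validation protocol (10 specimens, Pearson `r` between real
and virtual measurements with its significance value `L`) can be replicated
end to end on synthetic hearts.

# The phantom: a stated world

`phantom_spec()` describes two blood-filled chambers (a dark sphere) inside a
bright myocardial shell, split by a planar septum slab carrying an elliptical
through-hole:

* `chamber_radius = 12` mm, `wall_thickness = 3` mm — small-heart scale that
  fits a 60 x 60 x 32 mm field of view, matching the ex vivo setting.
* `septum_thickness = 2` mm — the fossa ovalis region of the atrial septum,
  where secundum ASDs sit, is a thin membrane of roughly 1-3 mm.
* `intensity_myocardium = 180`, `intensity_blood = 30` on a 0-255 scale —
  blood is nearly anechoic, myocardium strongly reflective.
* defect axes default to 10 x 7 mm; the replication study draws the long
  diameter uniformly from 6-14 mm and the short diameter as a uniform
  0.5-0.95 fraction of it, bracketing the published cohort (long diameters
  6.3-13.8 mm, short/long ratio near 0.7).

The phantom deliberately omits valve motion, chamber anatomy, attenuation and
the system point-spread function. A green test therefore establishes that the
*pipeline* recovers known geometry through realistic sampling and noise — not
that it would segment a pathological clinical image.

## Acquisition simulators

The rotational (TTO) simulator resamples a full-diameter plane every 1, 2 or
3 degrees about the central depth axis (180/90/60 slices), by trilinear
interpolation with out-of-volume reads of 0. Noise is applied in the
acquisition domain, in this order:

1. multiplicative speckle `pixel <- pixel * max(0, 1 + sigma * N(0, 1))` with
   `speckle_sigma = 0.2` — a mean-one multiplicative model is the standard
   ultrasound assumption, and 20 % is a moderate tissue speckle contrast;
2. salt-and-pepper impulses with `impulse_prob = 0.01`;
3. quantization to 256 integer gray levels.

The full-volume simulator masks the same volume to the four fixed 15-degree
azimuth wedges acquired on consecutive cardiac cycles, with independent noise
per wedge and an optional rigid `jitter` (voxels) emulating inter-cycle
misalignment; seam voxels shared by two wedges are averaged on assembly.

# Scan conversion

Reconstruction treats each output voxel's in-plane position as a polar pair
(signed radius `R`, argument `alpha`) about the rotation axis at
`(W - 1) / 2`. The two bracketing slice angles are found — wrapping at 180
degrees with the sign of `R` flipped, because the plane at 0 degrees is the
mirrored plane at 180 — and the value is bilinearly interpolated in
(angle, radius). Depth rows are shared by all slices and map index-exactly.
A stack of `W x D` slices yields a `W x W x D` volume (240 x 240 x 128 at the
default raster); voxels beyond the scanned disc are 0. Bilinear interpolation
is a convex combination, so reconstructed intensities never leave the input
range, and inputs constant along the angular coordinate reconstruct exactly.

# Despeckling

`median_aniso_diffuse()` iterates the explicit flux-form scheme

    u <- u + dt * [ div( c(|grad u|) grad u ) + gamma * (med(u) - u) ]

with the Perona-Malik conductance `c(s) = 1 / (1 + (s / kappa)^2)` and
Neumann boundaries. Defaults: `dt = 0.125` (the 3D explicit stability bound
is `dt <= 1/6`), `kappa = 15` gray levels (edges of interest are 10x
stronger), `gamma = 0.5`, 20 iterations, 3-voxel median window. The flux form
conserves the volume mean exactly when `gamma = 0`; the median term is
order-preserving, so the output range stays inside the input range.

`multiscale_filter()` realizes the two-resolution idea: speckle grains are
PSF-scale texture, so one factor-2 downsampling turns them into quasi-impulse
noise that the median term removes in a few passes. The coarse level runs
half the configured iterations; its re-expansion is fused with the fine level
*heterogeneously* — per voxel, the fusion weight is the Perona-Malik
conductance of the Gaussian-smoothed (sigma 3 voxels) fine-level gradient at
a quarter of `kappa`, so flat regions take the coarse-filtered value while
structural edges and a generous halo around them keep the full-resolution
data untouched. A fine-level pass of a quarter of the iterations cleans up.
The design was chosen against two checks it must satisfy simultaneously: on a
noiseless phantom at pipeline scale the mean absolute change stays below 2
gray levels, and on a speckled uniform phantom it beats single-scale
filtering at equal total iterations. The filtering quality metric is
`histogram_width()` — the sample standard deviation inside a homogeneous
region, which filtering must narrow.

# Segmentation

Intensity fuzzy c-means (`fcm()`, fuzzifier 2, two clusters: myocardium vs
cavity, the cavity being the darker cluster by default) supplies a
per-voxel membership `u`. Because the feature is scalar intensity, the
update runs on the value histogram and costs the same for any volume size.
Centroids initialize evenly over the intensity range; quantile placement
degenerates when one value dominates (an air background is most of an
ultrasound volume).

The membership field enters the level set twice:

* **Initialization** — `phi0 = -c0 (2u - 1)` puts the interface exactly on
  the fuzzy class boundary, which is why it converges in far fewer
  iterations than a generic box (a property the test suite checks by paired
  runs).
* **Stop / area control** — the stop function
  `S = g * (1 - 4u(1 - u))`, `g = 1 / (1 + |grad(G_sigma * I)|^2 / kappa_g^2)`
  vanishes at strong edges and at fuzzy boundaries and weights the length
  term; the area (balloon) term is weighted by the *signed* membership field
  `1 - 2u`.

The evolution is the variational without-reinitialization flow

    dphi/dt = mu [ lap phi - div(grad phi / |grad phi|) ]
            + lam delta_eps(phi) div( S grad phi / |grad phi| )
            + nu B delta_eps(phi)

with the compactly supported cosine-window Dirac `delta_eps` (width
`epsilon = 1.5`). Two numerical points mattered:

* The non-compact Cauchy-type Dirac feeds the image terms to every voxel and
  destabilizes the explicit scheme; the compact window confines them to the
  interface band, which is what makes the published parameter scale
  (`dt = 5`, `lam = 5`) usable.
* In 3D the distance-regularization weight must satisfy
  `mu * dt <= 1 / (2 * ndim) = 1/6`, sharper than the 2D rule
  `mu * dt < 0.25`; `evolve_levelset()` enforces the dimension-aware bound.
  Default `mu = 0.01` with `dt = 5`.

With a constant-sign area term (`B = S`, the classic shrink-from-outside
flow, still the default of `evolve_levelset()`) the interface has no stable
equilibrium: at a thin septum the edge indicator is small on *both* sides of
the boundary, the restoring force vanishes, and the contour drifts about 0.1
voxel per iteration through the defect rim — over the default 300 iterations
that is a 2 mm oversizing. `segment_volume()` therefore passes
`B = 1 - 2u`: the area functional is weighted by the signed membership, the
flow expands where `u > 0.5` and shrinks where `u < 0.5`, and the fuzzy
boundary is a stable fixed point. This is the literal reading of "membership
added to the area functional", with the edge-stop `S` retained in the length
term.

The mask is `phi < 0`. On phantoms this dark compartment is blood plus the
anechoic surround; rim extraction (below) isolates the defect from it, so no
connected-component postprocessing of the mask is needed.

# Surface extraction and defect metrology

`marching_cubes()` extracts the iso-surface by marching tetrahedra over the
Kuhn 6-tetrahedron cell decomposition. The decomposition shares face
diagonals between neighbouring cells, so the mesh is watertight by
construction and there are no ambiguous configurations to patch — the classic
defect of the table-based algorithm that "improved" variants address.
Binary masks are pre-smoothed with a 3 x 3 x 3 mean filter before
interpolation: raw binary iso-surfaces place every vertex at an edge
midpoint, which inflates a sphere's area by about 9 %; with the smoothing the
error is under 0.3 %. If smoothing erases a feature outright (a single
voxel), extraction falls back to the raw binary field so every non-empty
mask yields a surface.

`extract_rim()` resamples the cavity mask on the atrial face plane — the
septum mid-plane offset by half the septum thickness, pulled one voxel
*inside* the slab. Sampling closer than one voxel to the face reads the
partial-volume shell of the rim corner and oversizes the defect by about one
voxel per side (measured +10-15 % on the short diameter at 0.5 mm spacing).
Cavity components touching the window border are discarded (the anechoic
surround always reaches the border; a through-hole never does), and the
boundary of the largest remaining component is contoured on the *continuous*
trilinearly-resampled field at level 0.5, giving a sub-voxel, ordered, closed
rim polygon in 3D millimetre coordinates. An intact septum returns a
`found = FALSE` result rather than an error.

`defect_metrics()` projects the rim onto its least-squares plane (SVD) and
measures:

* **long diameter** — maximum Feret diameter (max pairwise distance over the
  convex hull);
* **short diameter** — minimum Feret width by rotating calipers (the paper
  never defines the two axes; max/min Feret matches the clinical long/short
  axis convention and is deterministic);
* **area** — shoelace area of the projected ordered contour (planar, not
  geodesic; the choice is recorded, the two coincide for a planar rim).

The "left and right atria" measurements of the validation tables are
realized as the two septum faces.

# Validation statistics and the replication study

`summarize_measurements()` reports n / min / max / mean / sample SD — the
summary-table shape of the original study. `validate_measurements()` computes
the Pearson correlation `r` between the real and virtual arms and `L`, read
as the two-sided p-value of the `t = r sqrt((n-2)/(1-r^2))` test of zero
correlation on `n - 2` degrees of freedom: the source pairs `L` with `R` and
applies the 0.05 convention but never defines it, so the correlation-test
p-value is the interpretation implemented (a paired alternative can be built
from the same pairs table). The printed tables of the original study give
only per-arm summaries, not the 10 raw pairs, so its exact `R` values cannot
be recomputed from the publication; the replication study instead re-runs
the whole protocol on phantoms where ground truth is exact.

`replication_study()` generates `n_models = 10` phantoms with randomized
defects, runs acquisition (1-degree step, default noise) through metrology on
each, and emits the summary and `r`/`L` tables per metric and face. At the
reduced desk scale (120 x 120 x 64 voxels, 0.5 mm) the study completes in
about a minute and yields `r > 0.99` for all six metric/face combinations
with `L` far below 0.05 — consistent with the published "R generally greater
than 0.9". Sub-voxel rim quantization bounds `r` slightly below 1 even with
noise switched off.

# Diagnosis component

`nb_fit()` / `nb_predict()` implement the categorical naive Bayes classifier
(priors times the product of per-feature conditionals, posteriors normalized
by the total-probability denominator) with Laplace smoothing, default 1 — the
source is silent on zero counts. `ga_select_features()` wraps it in a
genetic algorithm over binary feature masks: selection by the
largest-remainder rounding of expected copy numbers `N f_x / sum f`,
one-point crossover, per-bit mutation, elitism, empty masks repaired by
setting a random bit. Population 30 and 50 generations are standard choices;
the source names no operators beyond the fitness and selection formulas.

Two printed formulas required a decision, both flagged rather than silently
fixed:

* The fitness `f(a) = 1 / (1 + e^a)` is *decreasing* in `a`, so selecting by
  it would prefer the worst individuals. `fitness_sigmoid()` defaults to the
  printed form; `ga_select_features()` defaults to the conventional
  orientation `1 / (1 + e^-a)` (flag `orientation = "printed"` restores the
  literal formula, inverted selection pressure and all).
* The prose around the expected-copy formula swaps the meanings of its two
  symbols; the implementation is the standard expected-copy-number with the
  fitness sum in the denominator, rounded by largest remainder so counts sum
  to the population size.

`synth_records()` samples tables from a known naive Bayes model, so
conditional independence holds by construction and fitted parameters are
recoverable — the generator behind the parameter-recovery and
informative-feature tests.

# Numerical and design notes

* Noise is generated in R's RNG stream; every simulator takes a `seed` and
  restores the caller's RNG state, so fixed seeds give bit-identical outputs
  end to end.
* FCM initialization, tie-breaks and the rim component rule (largest
  non-border component) are deterministic; there is no stochastic step
  between acquisition noise and the final metrics.
* Degenerate inputs: constant volumes are rejected by FCM (degenerate
  distances); empty masks are rejected by surface extraction; an intact
  septum is a regular "no defect" result; rims with fewer than 3 distinct
  points are errors.
* Configs reject unknown keys; CLI exit codes are 0 (success), 2 (config),
  3 (data/format), 4 (numerical).
* The DICOM reader targets the generic explicit-VR little-endian multiframe
  layout with frames ordered depth-then-time ("height, width, depth, time"),
  enforcing ascending data-element tags; vendor-private extensions of the
  original scanner files are unspecified and out of scope.
* Pipeline and CLI configs are JSON (the environment provides no YAML
  parser for R); the schema is the constructors' argument lists.

# Known limitations

* The phantom's septum is planar and its chambers spherical; rim planarity
  and the two-face measurement convention lean on that simplification.
  General data require a user-supplied septum plane.
* The speckle model is white multiplicative noise; real speckle is
  PSF-correlated, which is emulated in the filtering tests by smoothed noise
  fields but not by the acquisition simulator itself.
* Segmentation assumes a bimodal intensity distribution; it will not
  separate structures of equal echogenicity.
* `L` is a correlation p-value on n = 10 pairs: it attests association, not
  agreement; systematic bias would need a paired test or agreement analysis,
  which the original tables do not report.
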