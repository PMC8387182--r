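# echoasd

Virtual 3D echocardiographic measurement of atrial septal defects (ASD), end
to end and fully synthetic: digital heart phantoms with a parameterized
septal defect, rotational-probe (TTO) and four-wedge full-volume acquisition
simulators, polar-to-Cartesian scan conversion, multiscale median-term
anisotropic diffusion despeckling, fuzzy-c-means-initialized level-set
segmentation without reinitialization, watertight surface extraction, and 3D
defect morphometry — plus the validation statistics that compare virtual
against ground-truth measurements, and a naive Bayes + genetic-algorithm
classifier for tabular diagnosis records.

## The science in brief

An ASD is a hole in the interatrial septum; its **long diameter**, **short
diameter** and **area** guide closure-device selection. A rotational 2D probe
sweeps 360° about its axis in steps of 1°/2°/3°, giving 180/90/60 sector
images of `W × D` pixels. Scan conversion maps each output voxel's polar
coordinates (signed radius *R*, argument *α*) back onto the two bracketing
slices by bilinear interpolation, producing a `W × W × D` Cartesian volume
(240 × 240 × 128 at the default raster). After despeckling with

    u ← u + dt·[ div( c(|∇u|) ∇u ) + γ·(med(u) − u) ],   c(s) = 1/(1+(s/κ)²)

the volume is split into myocardium and cardiac cavity: fuzzy c-means
memberships *u* initialize the level set (φ₀ = −c₀(2u−1)), gate its stop
function S = g·(1−4u(1−u)), and weight its area term, and φ evolves by the
distance-regularized flow

    ∂φ/∂t = μ[Δφ − div(∇φ/|∇φ|)] + λ δ_ε(φ) div(S ∇φ/|∇φ|) + ν (1−2u) δ_ε(φ)

so no signed-distance reinitialization is ever needed. The defect rim is the
boundary of the cavity through-hole on each atrial face of the septum; the
long/short diameters are its maximum Feret diameter and minimum Feret width
(rotating calipers) and the area is the shoelace area of the projected rim.
Agreement between virtual and true measurements is quantified by the Pearson
correlation *r* and its significance *L* (two-sided p-value of the
zero-correlation t-test on n−2 df).

Because the original ex vivo specimens are unavailable, a built-in phantom
generator supplies hearts with exactly known defect geometry, and
`replication_study()` re-runs the full 10-specimen validation protocol on
them.

## Worked example

```r
library(echoasd)

spec <- phantom_spec(defect_long = 10, defect_short = 7)   # 120×120×64 @ 0.5 mm
ph   <- generate_phantom(spec)
acq  <- acquisition_config(slice_width = 120, slice_depth = 64, seed = 42)

stack <- simulate_tto(ph$volume, acq)       # 180 slices at 1° steps
vol   <- scan_convert(stack)                # 120 × 120 × 64 Cartesian volume
filt  <- multiscale_filter(vol)
seg   <- segment_volume(filt, levelset_config(iterations = 150))

rim <- extract_rim(seg$mask, phantom_septum_plane(spec), "left_atrial",
                   spacing = spec$spacing)
defect_metrics(rim)
#> <defect_metrics> left_atrial: long 10.20 mm, short 7.00 mm, area 56.38 mm^2
```

Ground truth is 10 mm × 7 mm with area π·5·3.5 ≈ 54.98 mm², so the recovered
long diameter is 2 % high, the short diameter exact, and the area within
3 % — sub-voxel accuracy through speckle, impulses and the full
reconstruction chain.

The replication of the validation protocol:

```r
rep <- replication_study(n_models = 10, seed = 1)
rep$validation[, c("face", "metric", "n", "r", "L")]
#>          face         metric  n         r            L
#>   left_atrial  long_diameter 10 0.9988456 7.760185e-12
#>   left_atrial short_diameter 10 0.9933378 8.550007e-09
#>   left_atrial           area 10 0.9994737 3.354234e-13
#>  right_atrial  long_diameter 10 0.9984563 2.479968e-11
#>  right_atrial short_diameter 10 0.9960531 1.056679e-09
#>  right_atrial           area 10 0.9994807 3.179714e-13
```

Every virtual measurement correlates with its ground truth at r > 0.99 with
L far below the 0.05 significance convention.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "echoasd", package = "echoasd"))')
Rscript $CLI phantom     --config phantom.json --out phantom.nrrd
Rscript $CLI acquire     --in phantom.nrrd --out stack/ --step 1 --seed 7
Rscript $CLI reconstruct --stack stack/ --out vol.nrrd
Rscript $CLI filter      --in vol.nrrd --out vol_f.nrrd
Rscript $CLI segment     --in vol_f.nrrd --out mask.nrrd
Rscript $CLI measure     --mask mask.nrrd --septum plane.json --out metrics.csv
```

Volumes are NRRD/MetaImage, slice stacks PGM + JSON manifest, meshes
STL/PLY, DICOM multiframe files are read (one volume per time point). Exit
codes: 0 ok, 2 config error, 3 data/format error, 4 numerical failure.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch, 10 phantoms with long diameters drawn from
6–14 mm at 120 × 120 × 64 voxels (0.5 mm), runs the full
acquisition–reconstruction–filtering–segmentation–metrology pipeline on
each, and writes the Pearson correlation between true and recovered long
diameters (left atrial face) as JSON. Runtime ≈ 1 minute on one CPU.

## Package layout

| module | contents |
|---|---|
| `R/phantom.R` | phantom generator, TTO and full-volume simulators |
| `R/reconstruct.R` | scan conversion, wedge assembly |
| `R/filtering.R` | median-term anisotropic diffusion, multiscale filter, histogram width |
| `R/segmentation.R` | FCM, level-set init/stop/evolution, Dice |
| `R/measure.R` | marching tetrahedra, rim extraction, Feret metrics |
| `R/stats.R` | summaries, r/L validation, replication study |
| `R/diagnosis.R` | naive Bayes, GA feature selection, synthetic records |
| `R/io.R` | NRRD, MetaImage, PGM stacks, DICOM read, STL/PLY |
| `R/pipeline.R` | end-to-end orchestration with JSON config and logs |
| `src/` | Rcpp kernels (resampling, diffusion, level set, surfaces) |

The methods vignette (`vignettes/virtual-asd-measurement.Rmd`) documents the
models, parameter choices, numerical decisions and limitations.
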