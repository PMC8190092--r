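# thylaquant

Quantitative analysis of thylakoid membrane biogenesis in rod-shaped
cyanobacteria (*Synechococcus elongatus* and relatives), for microscopists
and molecular physiologists who need reproducible numbers from three kinds
of measurements:

1. **Periphery fluorescence profiles** — how GFP-tagged photosynthetic
   complexes (PSI, PSII, cytochrome *b₆f*, NDH-1, ATPase) are distributed
   along the cell outline: per-cell *patchiness*, longitudinal-side
   *asymmetry*, two-channel *colocalization*, and cross-cell mean profiles.
2. **Thylakoid layer counting and spacing** — number of membrane layers per
   longitudinal side and inter-layer distances (nm) from thin-section
   (TEM-like) images, with sub-pixel peak localisation and group
   comparisons.
3. **Abundance trajectories and photometry** — degree-4 polynomial fits
   with adjusted R² for protein abundances across a light regime
   (GL → HL → LL day 1–5), oligomer/monomer band ratios, chlorophyll
   formulas and 77 K spectrum normalisation.

A forward simulator generates two-channel fluorescence and TEM-like images
of spherocylindrical cells with complete ground truth (concentric thylakoid
shells, clustered/asymmetric protein point distributions, PSF blur, Poisson
and Gaussian noise), so every estimator in the package is validated against
known truth.

## The statistics at the core

The cell is a spherocylinder (length *L*, width *W*, perimeter
*P* = 2(*L*−*W*) + π*W*). Fluorescence is sampled at *n* = 360 equally
spaced positions of normalised arc length *t* ∈ [0,1), anchored at the
midpoint of longitudinal side L1 and traversed counterclockwise, then
partitioned into sides and poles (L1, P1, L2, P2).

* patchiness = σ(profile) / Σ(profile)  (population SD over total;
  0 for even signal, larger for clustered signal)
* side asymmetry = max(L-side maxima) / min(L-side maxima)  (≥ 1,
  brighter side reported)
* colocalization = Pearson *r* over in-mask pixels
* group comparison: pooled two-sample two-sided *t* test
* layer spacing: dark-line minima of the mid-cell transect with
  prominence filtering and 3-point parabolic refinement; percent change
  100·(mean − mean_ref)/mean_ref
* trajectory fit: least-squares polynomial, degree 4;
  adj R² = 1 − (1 − R²)(n − 1)/(n − 5)
* chlorophyll: 12.7 × OD₆₆₅ (methanol extract);
  A_Chl678 = 1.0162·A₆₇₈ − 0.0630·A₆₂₅, c = A_Chl678/(68·ℓ) mM

## Worked example

```r
library(thylaquant)

# one growth-light cell: 3 concentric shells, 2000 GFP-tagged complexes
scene <- make_scene(scene_params(preset = "GL"), seed = 42)
res   <- profile_scene(scene, channel = "gfp")   # render -> segment -> profile
patchiness(res$profile)$value
side_asymmetry(res$profile)$value

# spacing study: 10 TEM-like cells per condition
groups <- simulate_spacing_study(c(GL = 78.4, HL = 109.2), n_cells = 10, seed = 1)
spacing_summary(groups, reference = "GL")

chl_methanol(0.5)
chl_whole_cell(0.68, 0.2)$chl_mM
```

prints

```
patchiness = 0.00043 (n = 360)
side asymmetry = 1.031 (brighter side L2)

inter-layer spacing summary (reference: GL)
 group   mean_nm     sd_nm  n percent_change        t df             p
    GL  78.38121 0.4033271 40        0.00000       NA NA            NA
    HL 109.25484 0.4156348 40       39.38907 337.1475 78 3.670809e-125

chl_methanol(0.5) = 6.35
A_Chl678 = 0.678416, chl = 0.009977 mM
```

Read: this uniformly distributed, symmetric GL cell is neither patchy
(≈ 0.0004 at n = 360) nor asymmetric (ratio ≈ 1). The pipeline recovers the
two groups' shell spacings (truth 78.4 and 109.2 nm) to a fraction of a
nanometre and reports the ≈ 39% spacing increase of high-light cells with
an overwhelming pooled-*t* significance.

## Command line

```sh
Rscript inst/cli/thylaquant.R simulate --preset GL --n-cells 5 --seed 1 --out-dir scenes/
Rscript inst/cli/thylaquant.R segment  --image scenes/GL_cell001.tif --out-prefix c1
Rscript inst/cli/thylaquant.R profile  --image scenes/GL_cell001.tif \
    --contour c1_contour01.csv --geometry c1_geometry01.json --out prof1.csv
Rscript inst/cli/thylaquant.R tem-spacing --image tem.tif
Rscript inst/cli/thylaquant.R chl --mode methanol --od665 0.5
```

`simulate` writes 16-bit TIFFs (fluorescence: 2 pages, GFP and Chl) plus a
versioned ground-truth JSON sidecar per cell.

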