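---
title: "Methods: quantifying thylakoid membrane biogenesis in rod-shaped cyanobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying thylakoid membrane biogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thylaquant)
```

## Scope and model

`thylaquant` quantifies how photosynthetic complexes and thylakoid membranes
are spatially organised in rod-shaped cyanobacteria such as *Synechococcus
elongatus*. A cell's 2-D projection is modelled as a **spherocylinder**: a
rectangle of length $L - W$ capped by two semicircles of diameter $W$
(typical dimensions $L \approx 3\,\mu m$, $W \approx 1\,\mu m$). Thylakoid
membranes are concentric, inward-parallel copies of the plasma-membrane
outline; an inward offset $d$ of a spherocylinder outline is again a
spherocylinder outline with $L - 2d$, $W - 2d$, which is what makes the
layered architecture easy to state and to render.

All periphery analyses share one coordinate: **normalised arc length**
$t \in [0, 1)$ along the outline, anchored at the midpoint of longitudinal
side L1 and traversed counterclockwise. Which of the two sides is "L1" is a
pure convention; we fix it geometrically (the side with smaller cell-frame
$y$ after aligning the major axis with $x$), so that repeated runs anchor
identically. Every downstream side statistic is order-free
(brighter/dimmer), so this choice cannot change any reported value. From
the anchor, samples pass the second half of L1, pole P1, side L2, pole P2
and the first half of L1; the side and pole arc fractions are
$(L-W)/P$ and $(\pi W/2)/P$ with perimeter $P = 2(L-W) + \pi W$.

## The four periphery statistics

* **Periphery profile.** Intensity sampled at $n$ equally spaced arc
  positions ($n = 360$ by default), each value the mean of bilinear
  interpolations along the local normal over a band of half-width 1 px
  (configurable, 0 = single-pixel tracing). The fixed start point and
  direction substitute for curve registration when profiles are averaged
  across cells.
* **Patchiness** of a profile is its population standard deviation divided
  by its total, $\sigma(v)/\sum v$: low for evenly spread signal, high for
  clustered signal. Because $\sum v$ grows with $n$, the statistic is
  comparable only between profiles sampled at the same $n$ — the reason the
  package fixes $n = 360$ rather than adapting it to cell size. Whether the
  source method divides by the sum or the mean cannot be settled from the
  text we implement; the sum is the default (the literal reading of
  "normalised by the total fluorescence") and `normalizer = "mean"` gives
  the $n$-independent coefficient of variation instead.
* **Side asymmetry** is the ratio of the two longitudinal sides' maximum
  profile values, reported as brighter/dimmer (so $\ge 1$) plus which side
  was brighter. Maxima are taken over region-labelled profile samples, not
  raw pixels, mirroring how the ratio is read off a plotted profile.
* **Colocalization** is the Pearson correlation of two channels over
  in-mask pixels (no Costes thresholding; Manders $M_1/M_2$ with zero
  thresholds are available as companions).

Group comparisons use the classical pooled two-sample two-sided $t$ test
(`welch = TRUE` switches to the unequal-variance form). Degenerate
zero-variance input returns $t = 0, p = 1$ when the means agree and is an
error otherwise.

## Layer counting and spacing from thin-section images

TEM-like images are analysed along the **mid-cell transect**: the line
through the centroid perpendicular to the major axis, averaged over 20
parallel lines 1 px apart (membranes are locally parallel there, so this
suppresses noise without blurring layers). Membranes are stained dark, so
layers are local minima. A minimum is accepted if its topographic
prominence reaches 20% of the transect's dynamic range and minima closer
than 20 nm are merged (most prominent wins); both thresholds are exposed in
the configuration, and were fixed once at values that separate genuine
membranes (dips of roughly half the dynamic range) from shot noise.
Positions are refined by a three-point parabolic fit, giving sub-pixel
(sub-5 nm) localisation. The plasma membrane — the outermost peak on each
side, within 40 nm of $W/2$ — is removed before counting; inter-layer
distances are differences between adjacent remaining peaks on the same
side. The measurement line is a package choice: the underlying measurements
in micrographs are manual, and the mid-cell perpendicular transect is the
deterministic equivalent for concentric layers.

## Abundance trajectories and photometry

Protein abundances over the light regime (GL, HL, LL day 1–5, coded
$x = 0 \dots 6$) are first normalised per protein to the reference
condition's replicate mean (reference mean becomes exactly 1; proteins with
zero reference mean are dropped and reported). Trajectories are fitted with
ordinary least-squares polynomials of degree 4 and summarised by
$R^2 = 1 - SS_{res}/SS_{tot}$ and
$\bar R^2 = 1 - (1 - R^2)\frac{n-1}{n-p-1}$ with $p = 4$ parameters
(intercept excluded). By default the fit uses replicate means per condition
(7 points); `use_replicates = TRUE` fits all points, and `drop_reference`
removes the GL point — these two conventions are the main reasons a
published per-protein $\bar R^2$ list cannot be reproduced bit-for-bit
without the original supplementary table, which this package does not
bundle. Native-gel band tables yield oligomer/monomer ratios per replicate,
then mean ± SD; a zero denominator (e.g. no trimer band early in
biogenesis) marks the entry undefined rather than producing a number.

Photometry implements three fixed formulas: methanol-extract chlorophyll
$12.7 \times OD_{665}$; whole-cell chlorophyll via
$A_{Chl678} = 1.0162\,A_{678} - 0.0630\,A_{625}$ and
$c = A_{Chl678}/(68\,\mathrm{mM^{-1}cm^{-1}} \cdot \ell)$; and 77 K
emission-spectrum normalisation to the excitation-specific anchor peak
(PSI, search window 710–730 nm, for 435 nm excitation; phycocyanin,
645–665 nm, for 600 nm excitation) after background subtraction. The ±10 nm
windows are a package choice around the approximate peak positions; a
negative corrected absorbance is flagged instead of propagated.

## The synthetic-scene generator

The generator is the package's stand-in for the microscopes: it renders
two-channel fluorescence (GFP spots, Chl shells) and TEM-like images from a
fully recorded ground truth, so that every analysis step can be validated
against known truth.

**Shell presets.** GL cells carry 3 concentric layers at 78.4 nm spacing;
HL cells one continuous layer plus a membrane fragment close to the plasma
membrane on one longitudinal side, 109.2 nm apart; LL1 adds the first new
layer on the fragment side (spacing 110.6 nm, asymmetric), and LL2–LL5
relax towards the GL layout. The spacings are the published group means the
presets emulate; the fragment extents and LL intermediate layouts are
package choices consistent with the qualitative regrowth sequence.

**Protein points.** Arc positions are drawn from a density that is a
mixture of `n_clusters` von Mises components of concentration $\kappa$
($\kappa = 0$ is exactly uniform), multiplied by side weights: $a$
(`side_asymmetry`) on L1 and 1 on L2. Across each polar cap the weight
interpolates linearly between the adjoining side levels — density is
continuous around the outline — times `polar_enrichment`. The flat
alternative (a single intermediate cap level) makes the dim side's maximum
be dominated by pole bleed-through, so the recovered ratio would no longer
track the generator's ground truth; continuity removes that artefact and is
also the physically sensible choice. Sampling uses inverse-CDF on a
4096-bin grid from one seeded stream per scene; identical parameters and
seed give bitwise-identical scenes and images.

**Optics and noise.** Defaults: 30 nm/px and a 100 nm PSF sigma for
fluorescence (super-resolved confocal scale), 5 nm/px and a 10 nm PSF for
TEM-like images; rendering order is blur → background → Poisson → Gaussian
read noise (gains of 0 disable the stochastic terms). Blur conserves the
photon budget: with noise off the total GFP intensity equals the summed
point amplitudes to better than 1%.

**Default study conditions.** 2000 protein points of 500 counts each,
background 10 counts. These were set once, for realism: a cyanobacterial
cell carries on the order of $10^4$ photosystems, of which a GFP-tagged
subunit labels a substantial fraction, and tagged-complex images show
periphery signal well above camera background. The choice matters because
the max-based asymmetry statistic is biased towards 1 by the background
pedestal and by point-sampling fluctuations; with unrealistically few, dim
points that bias is a property of the statistic itself (visible in any
implementation), not of this pipeline.

**What the generator does not emulate:** optical sectioning and 3-D
structure, tubular membrane intermediates, cryo-ET density formation,
spectral bleed-through, uneven illumination, and cell division or crowding
(single, well-separated cells only). Passing the simulation studies
therefore validates the estimators under the stated forward model; it does
not certify performance on real micrographs with artefacts outside that
model.

## Numerical choices and degenerate inputs

* Segmentation: Otsu threshold after 1 px Gaussian smoothing, a 3 px
  opening (removes shot-noise speckles), disc closing (radius 5 px), hole
  filling, area filter (0.5 µm² minimum); border-touching cells are
  dropped by default and flagged when kept.
* Contours: marching squares at the 0.5 level of the smoothed mask
  (sub-pixel vertices); orientation enforced counterclockwise by signed
  area; non-simple outlines are an error naming the defect; anchoring is
  idempotent.
* Rod fitting: orientation from second-order moments; length from the
  major-axis extent plus one pixel; width from the area-preserving root of
  $(L - W)W + \pi(W/2)^2 = A$.
* Sphere limit $L = W$: no longitudinal sides exist; the partition warns
  and labels (almost) everything polar.
* Peak refinement falls back to the integer sample when the local
  curvature is not convex; transects require at least 5 samples.
* Seeds: every stochastic routine takes an explicit seed and uses a
  private RNG stream (`withr::with_seed`), never the global state.

## Problem sizes used in the bundled studies

The simulation studies shipped with the package use 50 cells per condition
for TEM spacing recovery and 30 cells per level for the asymmetry and
patchiness studies (500 points per cell for the patchiness ladder, noise
off, so that the ladder isolates the clustering effect). These sizes match
the scale of the emulated study (50 measured distances, 30 profiled cells
per panel) and keep a full run on a single CPU in the tens of seconds.

## Known limitations

* The patchiness value depends on the sampling density $n$; compare only
  profiles with equal $n$, or use the CV normaliser.
* Side asymmetry is undefined for spherical cells and degrades as
  $L \to W$ (few side samples).
* Layer counting assumes dark-membrane polarity and concentric geometry;
  heavily tilted sections or non-concentric membranes violate the
  mid-cell-transect assumption.
* The per-protein $\bar R^2$ values printed in the emulated study are
  documented reproduction recipes, not bundled tests: they require the
  study's supplementary abundance table and pin neither the means-vs-
  replicates convention nor the abscissa coding.
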