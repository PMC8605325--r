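---
title: "Quantifying nuclear-lamina organization and rupture of micronuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear-lamina organization and rupture of micronuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnlamina)
```

## Scope

Micronuclei (MN) are small nucleus-like compartments that form around
missegregated chromosomes. Their nuclear envelope is fragile: discontinuities
("gaps") in the lamin meshwork predispose an MN to membrane rupture, which is
scored photometrically by the loss of a chromatin-retained marker (H3K27ac).
`mnlamina` implements the quantitative machinery for this biology on
super-resolution fluorescence stacks:

* lamin meshwork segmentation by steerable ridge filters with non-maximum
  suppression (NMS);
* splitting an MN into hemispheres at its equatorial plane (Brenner best
  focus), 2D projection, and gap calling with an area cut-off of
  0.12 µm² and an intensity-ratio cut-off of 0.5;
* MN morphometry: projected area, volume as the mean of a minimum-volume
  enclosing ellipsoid and a convex hull of the lamin-positive voxels, and a
  sphere-equivalent surface area;
* rim-based lamin B1 quantification with background subtraction, rupture and
  FISH-positivity rules, chromosome counting from centromere foci, and
  nucleoporin focus density;
* lamina-associated domain (LAD) coverage per chromosome from BED interval
  files with blacklist subtraction;
* the statistical policy used throughout: a family test gating pairwise
  Barnard unconditional exact tests, the φ coefficient for binary
  association, Spearman rank correlation, and post-hoc chi-square power.

Because raw image data of this kind are rarely redistributable, the package
ships a synthetic MN generator with known ground truth; every stage is tested
against it end to end.

## The image model and its parameters

An MN is modelled as an oblate spheroid shell (default semi-axes
1.0 × 0.95 × 0.6 µm) carrying a meshwork texture, sampled at STED-like
spacing (20 nm lateral, 150 nm axial). Parameters of
`synthetic_mn_spec()` that matter most:

* `shell_thickness_um` (0.06 µm): radial extent of the lamin band.
* `mesh_spacing_um` (0.10 µm) and `mesh_line_fraction` (0.45): the meshwork
  texture is the near-zero level set of a smoothed random field, giving a
  network of line-like filaments; 0.10 µm face size matches electron- and
  super-resolution estimates of the lamin meshwork.
* `psf_sigma_nm` (25, 120): Gaussian PSF. The axial value models
  *deconvolved* stacks, since the reference workflow deconvolves before
  analysis.
* `poisson_scale` (150 photons at unit intensity) and `gaussian_sigma`
  (2 counts): shot and read noise.
* `gaps`: a list of `gap_spec(theta, phi, area_um2, residual_fraction)`.
  A gap retains diffuse residual lamin at `residual_fraction` of the mean
  shell brightness — deliberately structureless, because a lamina gap is
  not a dimmed intact meshwork.

Two rendering details are essential for realism. First, voxel intensity
scales with the shell surface area inside the voxel (∝ 1/cos of the surface
tilt, capped by the voxel aspect ratio), which produces the bright
equatorial rim that every real z-stack of a nuclear shell shows — and which
the Brenner focus measure relies on. Second, the radial band profile is
widened by the voxel footprint projected on the surface normal; without this
anti-aliasing, a 60 nm shell point-sampled on a 150 nm z-grid simply
vanishes wherever the surface falls between planes and the resulting dark
rings read as false gaps.

Calibration of the "normal" texture follows the published characterization
of gap-free lamina: holes in normal meshwork measure at most ≈ 0.12 µm² and
their interior-to-meshwork intensity ratio never falls below 0.5. The
inter-line veil (0.75 of line intensity) and the 0.10 µm mesh spacing were
chosen so that gap-free synthetic shells, measured through the package's own
pipeline, reproduce those two bounds. What passing tests on this generator
show is therefore that the detector recovers gaps *under the stated model of
normal lamina*; they cannot certify performance on real images whose
normal-texture statistics differ.

## Meshwork segmentation

`steerable_ridge_response()` computes, per z-plane, the even second-order
Gaussian-derivative line filter at scale 60 nm. Steerability means the
response at any orientation is a closed-form combination of three basis
convolutions (Ixx, Ixy, Iyy); the per-pixel maximum over 12 equally spaced
orientations and its argmax are kept (a 180-orientation brute force changes
responses by < 1%, which the tests check). `non_maximum_suppression()` then
keeps a pixel iff its response is at least both bilinear samples one pixel
away along the normal to its ridge orientation, yielding one-pixel
centerlines.

`segment_meshwork()` composes the two with:

* **local-contrast normalization** (`normalize_shell_contrast()`): each
  plane is divided by a heavily smoothed copy of itself plus a floor of 20%
  of the smoothed maximum *within the MN footprint*. The tangential rim is
  several-fold brighter than the face-on pole, and without flat-fielding a
  single response threshold cannot serve both. The floor is global across
  planes (a per-plane floor would re-amplify noise in shell-free planes)
  and footprint-restricted (so a bright neighbouring nucleus cannot shift
  the MN's normalization).
* a **response-quantile threshold** (default 0.5 of the positive NMS
  responses within the footprint), with the retained responses carried as
  segmentation weights;
* a **raw-signal gate** (2.5× the footprint's lower-quartile smoothed
  intensity, lateral smoothing only): flat-fielding would otherwise promote
  pure background noise in empty planes into centerlines. The gate is
  applied *after* the quantile is computed, so it does not shift the
  threshold's reference distribution.

## Gap calling

The equatorial plane maximizes the Brenner focus score
`Σ (I(x+2,y) − I(x,y))² + (I(x,y+2) − I(x,y))²` (ties break toward the
stack middle, then the lower index), evaluated on the raw channel where the
bright rim concentrates the score at the true equator. The equator belongs
to the bottom hemisphere exclusively, so equatorial holes are not counted
twice. Binary projections are any-voxel unions along z.

Before hole labelling the projected centerline net is cleaned: isolated
components under 8 px are dropped, sub-resolution breaks are sealed by a
5 × 5 closing (holes would otherwise leak into one another through 1–2 px
discontinuities), and the net is dilated by one pixel to restore the
physical filament half-width (holes bounded by 1 px centerlines would
otherwise be inflated by a centerline-to-edge margin ring).

Candidates are 4-connected components of (not meshwork) ∧ footprint that do
not touch the footprint boundary; meshwork connectivity is 8-connected (the
standard duality). Per candidate: area (pixel count × pixel area),
perimeter (8-connected boundary walk), eccentricity and solidity (second
moments, convex hull over pixel corners), and the intensity ratio between
the candidate and the footprint-minus-candidates reference. The ratio is
computed on the z-**max** projection of the flat-fielded channel: a z-mean
dilutes columns where the shell spans few hemisphere planes, so polar holes
would read dark regardless of lamin content — the max projection measures
shell-local intensity, depth independently. (A mild 0.8-plane axial
smoothing is applied first so a shell position that falls between z-samples
is not mistaken for lamin-free.)

Filtering is exactly the published rule, with strict inequalities: accepted
iff area > 0.12 µm² **and** ratio < 0.5. An MN "has a gap" if at least one
candidate survives; gap density is the accepted count per µm² of projected
MN area.

## Morphometry, intensity and classification rules

MN volume averages two estimators of the lamin-positive point cloud: the
minimum-volume enclosing ellipsoid (Khachiyan ascent; tolerance 10⁻⁶ by
default, 10⁻³ in the pipeline where the optimality gap is far below the
20 nm voxelization error) and the convex hull (incremental hull, exact
signed-tetrahedra volume; large voxel clouds are first reduced to per-slice
2D hull vertices, which is exact). Surface area is sphere-equivalent,
`π^(1/3) (6V)^(2/3)` — the minimal assumption given that only "derived from
the volume" is specified. Note these are *shell-enclosing* volumes: they
include the shell band and are used as a monotone size readout (the tests
check Spearman ρ ≥ 0.99 against projected area), not as an unbiased interior
volume.

Spot (NPC focus) detection is a scale-matched Laplacian-of-Gaussian with
lateral σ = diameter/(2√2) (0.2 µm nominal diameter) and the same physical
σ axially, 26-neighbour maxima above threshold, greedy radius suppression at
one diameter, and per-axis quadratic sub-voxel refinement. The detection
threshold is an explicit per-image parameter, as in the reference workflow;
`NA` applies 0.2× the maximum response and flags the result.

Rim lamin B1 intensity follows the published procedure: a 4-pixel inner
border band of the object mask, expanded ≥ 2× for the background estimate,
and background subtraction `F_N = F_I − (F_O − F_I)·(A_I/A_O)` (mode
`scaled`, the default). The printed formula divides instead of multiplying
by `A_I/A_O`, which yields negative intensities for typical inputs; it is
preserved verbatim as mode `printed`, and the exact annulus correction
(`F_N = F_I − A_I (F_O − F_I)/(A_O − A_I)`, identically 0 on uniform
images) is available as mode `annulus`.

Rupture: `ruptured` iff the MN/nucleus H3K27ac mean ratio is strictly
below 0.4 (a > 60% decrease); exactly 0.40 is intact; the call is invariant
under rescaling both means. FISH positivity: peak ≥ 2× local background
(inclusive) and centromere co-localization. Chromosome number = centromere
foci inside the MN mask. Cells with > 3 FISH foci are excluded; zero foci
are included but flagged.

## Statistics

For three or more groups, a family test runs first — Pearson chi-square for
counts, one-way ANOVA or Kruskal–Wallis for continuous data, chosen by
per-group Shapiro–Wilk normality — and pairwise comparisons are emitted only
when the family test rejects. Pairwise categorical comparisons use Barnard's
unconditional exact test: the pooled-variance score statistic orders
tables, and the p-value maximizes the null probability of the extreme set
over the nuisance success probability on a 1001-point grid with
golden-section refinement (grid error < 10⁻⁶ at the sample sizes involved;
tests require exact agreement with full enumeration for row totals ≤ 7 and
a realized type-I error ≤ 0.055 at nominal 0.05).
`barnard_pvalue_table()` computes all `(n1+1)(n2+1)` p-values at fixed row
totals in one pass for simulation studies. The φ coefficient is computed
with rows as the predictor (positive level first); callers orient tables,
which reproduces the signed published values (+0.87, −0.85) from the
reconstructed marker-validation tables. Post-hoc power uses the standard
noncentral chi-square formulation with Cohen's *w*; the originally reported
power value for the gap-proportion experiment is not reproducible from the
printed information (a standard computation at the stated effect size and
sample sizes gives power ≈ 1), so no attempt is made to match it.

## LAD coverage

Interval arithmetic is BED-convention (0-based half-open; adjacent
intervals merge) on `GRanges`. Blacklist regions are subtracted from both
the LAD intervals and the chromosome lengths, then
`LAD% = 100 · |LAD \ blacklist| / (length − |blacklist|)` per chromosome.
Tests pin this to hand arithmetic and to an exact base-pair boolean-array
oracle on random toy fixtures.

## Numerical choices and degenerate inputs

* Strict inequalities at every published cut-off (0.12 µm², 0.5, 0.4); the
  inclusive reading only for "twice the background".
* Brenner offset fixed at 2 px, both axes summed; at least 3 samples along
  a scored axis.
* Border policy for filtering: reflective padding (folded periodically for
  kernels larger than the plane); results within one filter support of the
  border are flagged via `border_px`.
* Hemisphere with zero planes (equator at the last plane): flagged, the
  other hemisphere is analyzed.
* Erosion emptying the rim selection (object thinner than 2× rim width):
  the whole mask is used and flagged.
* Degenerate geometry (coplanar or collinear points) raises errors rather
  than returning silently wrong volumes.
* Truncated derivative kernels are zero-meaned so constant images give an
  exactly zero ridge response; sub-1e-9 FFT ripple is clipped.
* Unknown configuration keys are errors, never ignored.

## Problem sizes used in the tests

The bundled test-suite and acceptance analyses run on synthetic MN of
≈ 165 × 125 × 13 voxels: a 50-MN panel with 0–3 inserted gaps
(0.15–0.5 µm², residual ≤ 0.2, default noise) for recovery metrics, a
20-seed equator sweep, 10⁴ null simulations for Barnard calibration, and
exhaustive Barnard enumeration for row totals ≤ 7. These sizes make the
whole analysis reproducible on a laptop while keeping every estimate's
sampling error well inside the tolerances being tested.

## Known limitations

* The synthetic meshwork is a random-field texture, not a mechanically
  realistic lamin network; gap positions are restricted to the well-sampled
  polar zones in the recovery analyses because mid-latitude structure in a
  hemisphere projection is dominated by viewing geometry (a limitation the
  projection-based method itself shares).
* The rendered nucleus is a rectangular slab used as a photometric
  reference; its wall brightness is calibrated so that an MN rendered at a
  given relative brightness measures that ratio (the calibration holds at
  the default MN geometry; strongly differing shell sizes shift the rim
  band's sampling and with it the measured ratio).
* Volumes are shell-enclosing, not interior volumes.
* Orientation estimation is in-plane only; the 3D character of the analysis
  enters through hemisphere splitting, as in the reference workflow.
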