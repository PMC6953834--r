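---
title: "Quantifying the air-gap effect in IOERT dose distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the air-gap effect in IOERT dose distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioertdose)
```

## The problem

In intraoperative electron radiation therapy (IOERT) a rigid PMMA
applicator collimates a single high-energy electron beam (4--20 MeV) onto a
surgically exposed tumour bed. The beam energy is chosen under the
*conventional assumption*: a flat irradiation surface with water-equivalent
tissue starting at the applicator's exit face. Two features of the real
surgical field break that assumption:

* the **air gap** between the exit face (cut by a bevel of 0--45 degrees)
  and the irregular post-resection surface, which displaces and deforms the
  depth-dose curve, and
* **tissue heterogeneity** (bone near the treatment volume, fluid pools,
  low-density regions).

This package rebuilds the classic five-scenario comparison that isolates
the two factors. From a paired preoperative/intraoperative CT of the same
patient it constructs, on one 1.5 mm isotropic grid:

| scenario | heterogeneity | air gap |
|---|---|---|
| `intraCT` (gold standard) | yes (actual) | yes (actual) |
| `preCT_water` | no (all water) | no |
| `preCT` | yes (preop) | no |
| `preCT_water_air` | no | yes (segmented) |
| `preCT_air` | yes (preop) | yes (segmented) |

Each scenario's 3D electron dose is computed and gamma-compared (3%/3 mm)
against `intraCT`. If the gap-aware scenarios agree with the gold standard
while the gap-blind ones do not, the air gap -- not heterogeneity -- is the
driver of dose error.

## Pipeline stages and their models

### Grid and image model

All volumes are HU-valued 3D grids (`CTVolume`) with spacing, origin and
direction cosines; world coordinates are LPS millimetres and the origin is
the centre of the first voxel. After `resampleIsotropic()` (trilinear for
HU, nearest for masks; 1.5 mm default, matching the dose-grid resolution)
every volume is axis-aligned, which the voxel engines assume.

### Registration

`rigidRegister()` aligns the preoperative to the intraoperative CT by
maximising normalised mutual information (Studholme's
\((H_A + H_B)/H_{AB}\), 32 bins, HU clamped to \([-1000, 2000]\)) evaluated
only at bone voxels -- the only structures rigid between the two
acquisitions. Choices the method leaves open, fixed here:

* the metric domain is the *intraoperative* bone mask dilated by 2 voxels,
  sampling the moving image trilinearly through the candidate transform;
* multi-resolution by Gaussian smoothing of both volumes at 4, 2 and 1 mm,
  Nelder-Mead at each level, preceded by a coarse translation sweep
  (\(\pm\)12 mm, 4 mm steps) at the coarsest level so marginal initial bone
  overlap cannot strand the optimiser in a flat region;
* an initialisation whose mapped bone overlap is below 10% is rejected with
  an error rather than fitted silently, and non-convergence is an error --
  there are no silent fallbacks.

Registration quality is scored on phantoms as mean target registration
error (TRE) over bone voxels; the suite requires TRE below one analysis
voxel (1.5 mm) for motions up to 10 mm / 10 degrees, and typically achieves
~0.1 mm.

### Segmentation

All masks come from seeded region growing in HU windows (6-connected by
default), the reproducible replacement for the interactive "manual
boundaries" of clinical practice; constraint masks can be supplied wherever
a manual delineation would have been. Windows, all configurable:

* bone: \([200, \infty)\) HU plus a 1-voxel morphological closing;
* air gap: \((-\infty, -500]\) HU, seeded just distal to the bevel centre
  and constrained to the distal extension of the applicator's inner
  cylinder -- an empty result is a *valid* zero gap, not an error;
* applicator wall: \([60, 200]\) HU (PMMA reads close to soft tissue)
  within a generous tube neighbourhood of an approximate axis;
* body: threshold at \(-300\) HU, largest connected component, hole
  filling, minus the wall.

The \(-500\) HU gap limit is the one segmentation constant inherited from
the clinical protocol; the others are this package's defaults.

### Applicator pose

`estimatePose()` recovers the 6-DOF pose plus bevel roll from the wall
mask alone: principal-component axis initialisation (or a caller-supplied
approximate axis when the visible stub is shorter than ~2.5 diameters),
refined by a line fit through centroids of *complete* wall rings -- slabs
cut by the bevel plane or the volume boundary are partial rings whose
centroids are off-axis and are excluded, with a residual-trimmed best-pass
selection. The distal rim (most-distal voxel in each of 72 angular bins of
5 degrees) is fitted with a trimmed least-squares plane, giving the bevel
angle, the bevel centre and the roll from the direction of steepest rim
descent (the "shorter edge"); a manually clicked shorter-edge point can
override the roll, mirroring the semiautomatic clinical procedure. Roll is
flagged undefined when the fitted bevel angle is below 5 degrees, since a
flat applicator is rotationally symmetric. A 1-voxel morphological opening
strips noise speckle from the wall before fitting. The axis sign (distal =
into tissue) is disambiguated by comparing the tissue fraction around the
two tube ends; the end facing the tumour bed is surrounded by tissue, the
proximal end by ambient air.

### Scenario construction

HU edits on the common grid: the applicator interior is blanked to air
(the standard planning-system edit), the segmented gap is set to
\(-1000\) HU, body voxels are set to 0 HU for the water scenarios, and the
gap edit is applied after waterising so gap voxels always end as air. For
`preCT_water` the water region is the full half-space distal to the bevel
plane: every ray then accumulates water-equivalent depth from its
bevel-plane crossing, the exact geometry of the flat-phantom calibration
that the conventional assumption encodes. An alternative plane through the
distal-most rim point is available (`water_plane = "distal_rim"`) for
sensitivity checks.

### Dose engine

`computeDose()` is a deterministic divergent pencil-beam engine -- a
desk-scale stand-in for a Monte Carlo code, kept behind a pluggable
interface (`dose_engine` argument of `runCase()`) so a true MC engine can
replace it without touching the pipeline. Per voxel distal to the bevel
plane:

\[ D = \mathrm{PDD}(z_\mathrm{we}) \times L(r; z) \times
   \left(\frac{\mathrm{SSD}}{d}\right)^2 \]

* \(z_\mathrm{we}\): radiological depth, the trilinear line integral of
  physical density (from the shipped piecewise-linear HU calibration
  anchored at air 0.00121 and water 1.000 g/cm^3) along the ray from a
  virtual point source 1000 mm proximal of the bevel centre, starting at
  the ray's bevel-plane crossing; midpoint rule with steps of half the
  smallest voxel.
* \(\mathrm{PDD}\): a monotone piecewise-cubic (Fritsch-Carlson) curve
  through the per-energy anchors surface fraction, (R100, 1.0), (R90, 0.9),
  (R50, 0.5) and the bremsstrahlung tail beyond the practical range;
  defaults follow the standard electron rules of thumb
  (R90 \(\approx E/3.2\) cm, R50 \(\approx E/2.33\) cm,
  Rp \(\approx E/2\) cm) and ship as editable YAML.
* \(L\): an error-function aperture edge, 0.5 exactly at the divergently
  projected aperture radius, with
  \(\sigma = \sigma_0 + k_\mathrm{we} z_\mathrm{we} + k_\mathrm{geo}
  z_\mathrm{geo}\). The geometric term is deliberate: across an air gap
  almost no water-equivalent depth accumulates, yet the physical penumbra
  widens with distance, and a purely water-equivalent \(\sigma\) could not
  reproduce that.

Doses are expressed as percent of each distribution's own maximum;
`absoluteScale()` maps percent to Gy through the prescription at the 90%
isodose. This engine class reproduces the depth shift, penumbra broadening
and curved-isodose behaviour that drive the air-gap effect; it does not
model lateral scatter hot spots from sharp surface irregularities, output
factors, or tissue bulging into the applicator.

### Gamma analysis

`gammaMap()` implements the 3D gamma index with 3% / 3 mm defaults, global
normalisation to the reference maximum (the published protocol does not
state its normalisation dose; an explicit value can be supplied), reference
dose thresholds of 10% or 70%, and exclusion of non-tissue voxels of the
gold standard. The evaluated distribution is sampled on a sub-voxel lattice
(one third of a voxel) with trilinear interpolation inside a search sphere
of radius 3 x DTA; sample points outside the grid are skipped, and a voxel
whose entire search sphere is outside fails with \(\gamma = \infty\). The
production path prunes the search by visiting offsets in increasing
distance and stopping once the distance term alone exceeds the current
minimum -- an exact optimisation. `gammaBruteForce()` is a separate,
exhaustive, unpruned code path kept as the verification oracle; the suite
demands agreement to \(10^{-6}\) on seeded random field pairs. Gamma is
asymmetric; `intraCT` is always the reference.

## The synthetic phantom family

No patient CT pairs are available for validation, so it rests on
`generatePhantom()`: an ellipsoidal soft-tissue body
(40 HU) with rod-shaped bones (900 HU) flanking the treatment volume, an
optional low-density region, a tumour-bed cavity carved from a
spherical-cap base with a seeded sum of rim-windowed 2D Gaussian bumps
(closed-form floor function, hence an exact max-depth oracle), an optional
fluid pool (10 HU) flat-filling the cavity bottom, a posed PMMA applicator
(120 HU walls) stood off the floor so the maximum bevel-to-floor distance
along the axis exactly equals the target gap, a known rigid
inter-acquisition motion, and seeded Gaussian HU noise (15 HU default).
Both volumes are rendered analytically -- the preoperative scan evaluates
the intact anatomy at motion-mapped coordinates -- so every truth element
(pose, motion, masks, gap) is exact, not resampled.

The reference family mirrors the clinically observed range: maximum air
gaps of 8.5, 14.5 and 30.5 mm with energies 8, 6 and 9 MeV and bevels 30,
15 and 30 degrees, on a \(96 \times 96 \times 128\) voxel, 1.5 mm grid tall
enough to contain a usable length of applicator tube. What the phantoms do
*not* emulate: CT physics (beam hardening, scatter, streak artefacts --
metal-artefact handling, the main obstacle to intraoperative CT dosimetry
with shielding discs or retractors in place, is out of scope), anatomical
realism beyond "bones
near a cavity in a torso-like body", and tissue bulging into the
applicator. Passing the suite therefore demonstrates correctness of the
*computational chain* under known ground truth, not clinical accuracy on
real anatomy.

## What the pipeline reports

`runCase()` produces the classic per-case table -- four scenario
comparisons x two thresholds, with per-comparison averages -- plus the RMS
HU difference between the registered preoperative and intraoperative image
(over tissue voxels inside the bounding box of the reference dose) and the
maximum air-gap distance. On the reference family the water-only agreement
falls steeply as the gap grows while both gap-aware scenarios stay at or
near 100%, reproducing the finding that motivates the method: the air gap,
not tissue heterogeneity, dominates the dose error, so it is the air gap
that must enter the calculation.

```{r family, eval = FALSE}
cfg <- phantomConfig(seed = 1L, target_gap_mm = 14.5,
                     spec = applicatorSpec(5, 15))
ph <- generatePhantom(cfg)
rep <- runCase(caseConfig(ph@preop, ph@intraop,
                          beamSpec(6, cfg@spec, ph@truth$pose)))
rep
```

## Numerical choices and degenerate inputs

* Determinism everywhere: phantoms are pure functions of their config,
  the dose engine has no stochastic component, and RNG use is confined to
  seeded helpers that restore the caller's RNG state.
* Resampling clamps the sub-voxel boundary overhang onto edge voxels (the
  output grid covers the input extent by construction); transform
  resampling marks genuinely out-of-field voxels as air.
* Two constant images give a degenerate joint histogram; NMI is defined as
  2 (perfect dependence) with a warning.
* An empty air-gap segmentation is a valid zero-gap result;
  `maxAirGapDistance()` of an empty mask is 0.
* A bevel angle fitted below 5 degrees reports roll as undefined rather
  than a meaningless number.
* Pass rates are exact ratios of analysed voxels; the analysis set is
  recomputed per threshold from the reference dose.

## Problem sizes

The suite validates on 96-mm unit-test phantoms (64^3 at 1.5 mm) and the
full 144 x 144 x 192 mm reference family; gamma oracle equivalence uses
twenty 40^3 random smooth field pairs at 3 mm spacing, and registration
recovery uses ten phantoms with random motions up to ~10 mm / 10 degrees.
`scripts/acceptance.R` reruns the family end to end (three full cases:
registration, segmentation, pose, five doses, eight gamma maps each) with
five registration phantoms and five oracle pairs.

## Known limitations

* The pencil-beam engine is a stand-in: absolute dose accuracy in
  heterogeneous media is far below Monte Carlo; only the relative
  scenario-to-scenario behaviour it exists to expose is validated.
* The HU-to-density table is a generic two-segment calibration, not a
  scanner calibration.
* Local gamma normalisation scales each voxel's tolerance by its own
  reference dose; it is provided as a config switch but the published
  protocol -- and every number this package reports -- is global.
* Pose recovery needs a wall stub of roughly 1.5 tube diameters beyond the
  bevel transition; clinical scans that truncate the applicator harder
  than the phantoms do would need the manual shorter-edge override.
* Metal artefacts, deformable anatomy and in vivo dosimetry are out of
  scope.
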