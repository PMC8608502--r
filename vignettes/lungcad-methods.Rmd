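---
title: "Pulmonary nodule CAD: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulmonary nodule CAD: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lungcad` implements a classical computer-aided-detection (CAD) chain for
pulmonary nodules on chest CT: segment the lung fields, repair their
contour, enhance compact bright shadows with a variable-radius ring
filter, extract per-candidate shape and intensity features, and screen
candidates into nodule / non-nodule. Because the patient scans such
systems are usually tuned on are not distributable, the package ships a
synthetic thoracic phantom generator with exact ground truth; every
stage is validated against that truth or against independent brute-force
oracles. This vignette records the models behind each stage, the
parameters that matter, and the design decisions that were genuinely
open, so that a maintainer can see why the code is the way it is.

## Volume model and conventions

A CT volume is a 3D array of Hounsfield units (HU) in index order
`(slice, row, column)` = `(z, y, x)`, with per-axis physical spacing in
mm and a world origin; the world position of voxel `(k, i, j)` is
`origin + (k-1, i-1, j-1) * spacing`. Indices are 1-based throughout,
including exported CSV files — the natural convention in R; the CSV
header documents it. HU values are clamped to the 12-bit CT range
[-1024, 3071] on load. Slices of a DICOM series are ordered by spatial
position, never by file name, and the slice spacing is the median
inter-slice gap (gaps deviating more than 10% from that median trigger a
warning). Per-volume anisotropic spacing is carried through every stage;
in particular all in-plane operations convert mm parameters to pixels
through the volume's own spacing, so nothing assumes 1 mm pixels.

## Lung segmentation

**Optimal threshold.** The classical iterative isodata scheme: starting
from the volume mid-range, `T <- (mean(v < T) + mean(v >= T)) / 2` until
the update is at most `threshold.tolerance_hu` (default 0.5 HU, within
`threshold.max_iter = 100` iterations). On a bimodal chest histogram
(air/lung vs soft tissue) this converges in a handful of iterations to a
fixed point strictly between the two class means. The test suite checks
it against an exhaustive scan over every integer HU for the fixed-point
condition.

**Region connectivity.** Voxels below the threshold are air. Air
connected to the in-plane image border (6-connectivity in 3D) is ambient
air and is removed; the slice axis is deliberately excluded from the
border test because clinical acquisitions are routinely cropped so that
the lung reaches the first or last slice. An optional flag
(`lung.remove_airway`) also removes components connected to top-face air,
i.e. a trachea entering from above; it is off by default because the
phantoms have no airway. Of the remaining components the largest
`lung.keep_components` (default 2) with volume above `lung.min_volume_ml`
are kept. The clinical default is 400 ml; `phantom_config()` lowers it to
50 ml because the desk-scale phantom lungs hold about 150 ml each — this
is a scale parameter of the data, not of the method.

**Cavity filling.** Dense structures inside the lung (vessels, solid
nodules) are excluded by the air threshold and must be put back.
Per slice, background components under 4-connectivity that do not touch
the slice border become foreground. The operation is extensive and
idempotent.

**Contour repair.** A juxtapleural nodule is soft-tissue dense and
merges with the chest wall under thresholding, leaving a notch in the
lung boundary. Each slice's components are closed independently with a
disk structuring element on a zero-padded canvas. Two points were
genuinely open and deserve their rationale:

* *Structuring radius.* A disk of radius `R` rolling on the outside of
  the contour dips about `a^2 / (2R)` into a hemispherical notch of
  radius `a`, so plain closing with `R = a` only flattens the notch, it
  does not fill it. The element radius is therefore derived from the
  rolling-ball sag formula as `R ≈ 1.4 a^2` pixels, where
  `a = repair.ball_radius_mm` (default 5 mm) is the largest indentation
  radius that must be bridged; the residual dip is then under half a
  pixel. Closing is the identity on convex shapes regardless of `R`, so
  a larger element does not distort the pleural boundary.
* *Component independence and fixpoint.* Closing the whole slice with
  such an element would bridge the 12 mm mediastinal gap between the two
  lungs; closing per connected component cannot. Because closing one
  component can bring it into contact with another, the per-slice pass
  iterates to a fixpoint (the pass is monotone increasing and bounded, so
  it terminates; in practice one extra confirming pass). This makes the
  operation idempotent by construction.

Repair runs per slice rather than in 3D so that strongly anisotropic
slice spacing needs no resampling. The per-slice convention for the whole
back half of the pipeline follows the same reasoning.

## Ring-filter detection

The detector is a variable-scale annulus-contrast operator. For each
slice, each in-mask voxel and each radius `r` in `detect.radii_mm`
(default {2, 3, 4, 6, 8, 10} mm, covering roughly 4–20 mm nodule
diameters), the response is

> mean HU over the disk of radius `r` − mean HU over the annulus with
> inner radius `r` and outer radius `detect.annulus_factor * r`
> (default 1.6),

maximized over the radius set and floored at 0; the maximizing radius is
the candidate's scale (smallest radius wins ties, keeping output
deterministic). The operator is purely contrast-based — adding a constant
HU to the volume changes nothing, and the response is linear in
nodule/background contrast on clean disks — both are tested.

Two boundary rules matter in practice:

* Both means are drawn from the lung mask **eroded by one voxel**
  (6-connectivity). Mask-border voxels carry partial-volume blends of
  lung (≈ −850 HU) and chest wall (≈ +40 HU); including them fires the
  filter all along the pleural rim — on a clean phantom this produced
  over 150 rim candidates before the rule and zero after. Responses are
  still *assigned* at every mask voxel, so juxtapleural candidates are
  not lost.
* A voxel whose disk or annulus has less than 25% of its pixels in the
  eroded mask gets response 0 rather than an unreliable mean.

**Candidate extraction.** Candidates are local maxima of the response
map above `detect.response_threshold` (default 100 HU contrast): a voxel
whose response equals the maximum over a box of half-width
`detect.min_separation_mm` (default 4 mm) per axis. Surviving seeds are
merged by non-maximum suppression at the same separation, strongest
first, and refined to the response-weighted centroid of supra-threshold
voxels within the seed's scale radius. An earlier design that emitted one
candidate per connected supra-threshold cluster was abandoned: with high
contrast structures, the response halos of a nodule and a nearby vessel
tree merge into one sprawling cluster whose centroid lies in empty
parenchyma — large nodules were mislocalized by 10–20 mm. Local maxima
with NMS are the standard blob-detection answer and bring localization
under 2 mm. Lowering the threshold only adds seed locations, preserving
the monotone-detection property.

Filtering is 2D per slice with 3D non-maximum suppression across slices,
again to tolerate anisotropic slice spacing without resampling.

## Features and screening

A candidate region is delineated by region growing from the centroid
voxel: 26-connected voxels with HU at least `centroid HU −
features.growth_delta_hu` (default 150 HU), inside the lung mask, capped
at a bounding box of half-width twice the candidate's scale radius.
Regions under 3 voxels are flagged (`feature_error`) and classified
negative rather than aborting the batch. Features:

* `volume_mm3`, `equivalent_diameter_mm` — physical size.
* `circularity` — `4π·area / perimeter²` on the largest-area slice, with
  the perimeter from the Vossepoel–Smeulders chain-code estimate (plain
  boundary-pixel counting underestimates circularity of a digital disk by
  ~40%).
* `elongation` — major/minor principal-axis ratio from **3D** second
  moments in mm. The 2D version was rejected deliberately: a vessel
  running perpendicular to the slice plane has a circular cross-section
  and looks compact in 2D, while in 3D it is a tube; this single feature
  separates most vascular false positives.
* `mean_hu`, `max_hu`, `contrast_hu` (region mean minus a 2-voxel
  surrounding shell, preferring in-mask shell voxels), and
  `boundary_gradient_hu_per_mm` (mean central-difference gradient
  magnitude on the region border).

Contrast and gradient features are invariant to a global HU offset;
mean/max shift with it (tested).

**Screening.** The shipped false-positive reducer is a transparent rule
set — a candidate is a nodule only if it passes all of:
`equivalent_diameter_mm ≥ 3` (the usual clinical reporting floor, and
safely below any 4 mm nodule's measured diameter given ±0.5 mm
discretization), `circularity ≥ 0.5`, `elongation ≤ 2.5`,
`contrast_hu ≥ 150`. The score is the fraction of rules passed. The
circularity, elongation and contrast cut-offs were fixed once by
inspecting feature distributions on a development phantom (seed 99,
disjoint from every seed used elsewhere in validation): true-nodule
candidates sit at elongation 1.0–1.2 with circularity near 1, while
vessel fragments spread over elongation 2.1–5.4. The elongation cut of
2.5 is placed well above the nodule population, leaving headroom for
juxtavascular nodules whose grown region swallows a vessel stub; the
price is that the straightest vessel fragments (elongation just above 2)
occasionally pass, which is the residual false-positive source seen in
validation (0–4 per phantom). Circularity and contrast barely
discriminate on the phantom's tissue palette — vessels are as bright and
as round in cross-section as nodules — so those rules sit at permissive
values and matter mainly for real-data artifacts (pleural-edge slivers,
noise specks).

An optional trained alternative is a Fisher linear discriminant on
z-scored features (pooled covariance, ridge-regularized if singular),
persisted as plain JSON. Standardization constants live in the model, so
the decision is invariant to consistently rescaling any feature. Tests
compare it with an independent LDA implementation and with the
closed-form Bayes rate on known Gaussians. The benign/malignant question
is out of scope: candidate screening (nodule vs non-nodule) is what the
detection metrics measure, and the class names are configurable.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a 64 × 128 × 128 grid at 2 × 1 × 1 mm —
desk-scale, but anisotropic like clinical CT. It contains an ellipsoidal
soft-tissue body (+40 HU) on an air background (−1000 HU), two ellipsoid
lung fields (−850 HU, semi-axes 42 × 36 × 24 mm, ≈ 150 ml each),
random-walk vessel tubes (+50 HU, radii 1–2.5 mm), spherical nodules of
configurable placement (isolated, juxtapleural — sunk 0.75 r below the
pleural surface so the nodule indents the lung rather than sitting half
in the chest wall — and juxtavascular, which get a dedicated abutting
vessel), partial-volume shading at every tissue interface, and additive
Gaussian noise (default sd 20 HU). Vessels keep a 3 mm clearance from
isolated and juxtapleural nodules so the placement labels stay truthful.
Vessel and noise draws come from separate substreams of the seed, so
adding vessels does not change the noise field, and a nodule-free
re-generation at the same seed is an exact paired control — several tests
use this to ask "which voxels would the segmentation cover if the nodule
were absent?".

The lung semi-axes leave at least 6.5 mm of body wall between the lung
caps and the body surface. With 2 mm slices and the isodata threshold
sitting exactly at the lung/body blend midpoint, a thinner wall becomes
porous to partial-volume voxels and ambient air leaks into the lung
field; the geometry is chosen so the phantom is a valid specimen of the
scene it claims to model.

What the phantom does **not** model: airways and fissures, scanner
physics (beam hardening, reconstruction kernels, streak artifacts),
ground-glass or part-solid nodules, and textured parenchyma. Passing the
phantom suite therefore demonstrates the pipeline's geometric and
statistical correctness — segmentation accuracy, filter response,
localization, screening logic — not clinical performance on patient
scans, where contrast is lower and the false-positive sources richer.

## Numerical choices

* Connected components use a run-based union-find written for exactly the
  connectivities the pipeline specifies (6-connectivity in 3D,
  4-connectivity in 2D); off-the-shelf 2D labeling is 8-connected, which
  leaks through diagonal contacts at the mediastinum.
* Ring-filter convolutions are FFT-based; responses below 1e-6 HU are
  clamped to zero so flat regions are exactly 0 despite float noise, and
  translation-equivariance tests assert < 1e-6 rather than bit equality.
* Ties in the scale search go to the smallest radius; NMS ties go to the
  first voxel in linear order — all outputs are deterministic, and a
  fixed config plus fixed input yields byte-identical candidate CSVs.
* The evaluation matcher is greedy by ascending candidate-truth distance
  (ties by descending response), one-to-one; a truth nodule is hit if a
  candidate centroid lies within `max(hit_distance_mm, truth radius)`
  (default 5 mm). Sensitivity is monotone in the hit distance.
* Degenerate inputs fail loudly and early: constant volumes for the
  threshold, all-air volumes for segmentation, sub-pixel repair radii
  (warning + identity), non-finite candidate responses on export.

## Problem sizes used in validation

The test and acceptance workloads run on the default 64 × 128 × 128
phantom grid: five-seed end-to-end detection runs with ten isolated
nodules each (diameters 6–16 mm, ≈ 850 HU contrast, noise sd 20),
five-seed segmentation Dice checks including the 30 HU noise ceiling,
ten-seed threshold-oracle comparisons on 10^5-sample Gaussian mixtures,
and fifty random masks for the extensivity/idempotence properties. These
sizes exercise every code path at full grid resolution while keeping a
complete validation run in a few minutes on one core.

## Known limitations

* The ring filter is a mean-contrast operator; a max-based (Quoit-style)
  variant would be more specific for very irregular nodules and is noted
  as an extension, not implemented.
* Screening rules are tuned to the phantom's tissue palette; on clinical
  data the contrast cut in particular would need recalibration, and the
  linear discriminant would need a labeled candidate set.
* DICOM support covers uncompressed single-frame little-endian CT with
  axial identity orientation — what desktop CT exports produce; gantry
  tilt and oblique orientations are not resampled.
* No lobe segmentation, airway-tree extraction, FROC curve plotting, or
  malignancy modeling.
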