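---
title: "Quantifying hippocampal sclerosis from binary segmentations: methods and design"
author: "hippasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hippocampal sclerosis from binary segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippasym)
```

## The problem

Hippocampal sclerosis (HS) — neuronal loss and gliosis of the hippocampus —
is the most common pathology in mesial temporal lobe epilepsy. On T1-weighted
MRI it manifests as volume loss and, more subtly, as altered shape: a
degenerating hippocampus frays at the surface and develops fluid-filled
cavities, so its surface area falls less (or even rises) while its volume
shrinks. `hippasym` implements a complete quantitative pipeline from binary
hippocampus segmentations (produced by any engine: FreeSurfer,
FSL-FIRST, deep-learning tools) to a per-scan decision:

1. **Shape features** — 14 mesh-based 3D descriptors per structure, from
   marching cubes on the binary mask.
2. **Asymmetry index (AI)** — for a paired measure,
   $\mathrm{AI}(lh, rh) = (lh - rh)/(lh + rh)$: zero for symmetry, bounded
   in $[-1, 1]$, scale-invariant. AI is computed on *uncorrected* measures:
   the contralateral side is each scan's internal reference.
3. **Normative modelling** — hippocampal volumes corrected for head size
   (eTIV) and age by a linear model fitted on healthy controls (HC);
   AI limits at mean $\pm$ 2 and $\pm$ 3 HC standard deviations.
4. **Classification and discrimination** — scans outside the limits are
   flagged left- or right-abnormal; sensitivity, specificity, F1 and the
   rank-based AUC of the absolute AI quantify discrimination of unilateral
   HS from other epilepsies.
5. **Feature ranking** — a repeated, patient-stratified, cross-validated
   linear SVM ranks the 14 feature AIs; the surface-to-volume ratio is the
   expected winner and the pipeline's headline biomarker.
6. **Robustness** — test–retest reproducibility over re-scan sessions:
   session-wise MAPE and ICC(2,1).

Because clinical MRI cannot be redistributed, the package ships a
synthetic-data module that generates both measurement-level cohorts and
voxel-level hippocampus phantoms; every stage of the pipeline is exercised
end-to-end on data generated in code.

## Geometry: marching cubes on binary masks

Meshes are extracted at iso-level 0.5 of the binary field, with voxels
outside the array treated as background, so every mask yields a closed
surface. Rather than the classical 256-entry case tables, `maskToMesh()`
uses a face-tracing formulation specialised to binary fields: on each cell
face the iso-contour segments are directed so the foreground stays on a
fixed side, ambiguous faces (diagonal foreground pairs) are always resolved
with the foreground connected, and the directed segments are chained into
closed polygons inside each cell. Because the ambiguity rule depends only
on the shared face pattern, adjacent cells always agree and the mesh is
watertight by construction — `TriMesh` validity checks that every directed
edge occurs exactly once with its reverse present. Polygons with more than
three vertices are fan-triangulated around their centroid, a canonical
choice that makes the mesh exactly symmetric under grid mirrors and
90-degree rotations. An isolated voxel meshes to the exact octahedron
(6 vertices, 8 faces, volume $1/6\,\mathrm{mm^3}$, area
$\sqrt{3}\,\mathrm{mm^2}$ at 1 mm spacing).

**Staircase bias and smoothing.** Any marching-cubes surface of a *binary*
volume carries staircase facets: for digital balls the mesh volume is
accurate to a fraction of a percent, but the surface area is overestimated
by 8–9% regardless of implementation. Since the surface-to-volume ratio is
the pipeline's headline measure, `computeShapeFeatures()` measures all
mesh-derived features on a Taubin $\lambda|\mu$-smoothed surface
($\lambda = 0.5$, $\mu = -0.53$, 20 iterations, `smoothMesh()`): the
alternating shrink/inflate passes remove the staircase while changing the
enclosed volume by well under 1%. Our oracle runs on voxelized balls with
radii 5–20 mm at 1 mm spacing give area errors $\le 1.2\%$, volume errors
$\le 2\%$, sphericity $\ge 0.988$ and maximum-diameter errors $\le 3\%$.
Raw meshes remain available (`smooth_iterations = 0`).

**Frozen feature definitions.** The 14 features are: mesh volume, voxel
volume (count $\times$ voxel volume), surface area, surface-to-volume
ratio (area / *mesh* volume, the radiomics convention), sphericity
$(36\pi V^2)^{1/3}/A$, maximum 3D diameter, three in-plane 2D diameters
(vertices binned to planes by rounding the orthogonal coordinate to the
voxel grid: axial = slice, coronal = column, sagittal = row), and
principal-axis metrics from the *population* covariance of foreground
voxel centres (axis length $4\sqrt{\lambda}$, elongation
$\sqrt{\lambda_2/\lambda_1}$, flatness $\sqrt{\lambda_3/\lambda_1}$, ties
broken by stable descending sort). Radiomics tools drift slightly across
versions in the 2D-diameter details; these definitions are frozen here and
validated against closed forms (ellipsoid moments, sphere limits) in the
test suite.

## Normative model and asymmetry limits

The volume model is OLS of a side-specific volume on z-scored eTIV and age,
fitted on HC rows only; the z-scoring constants also come from the HC rows
(the model is a property of the norm population) and are stored so the
correction applies to all subjects. Sex is deliberately not a covariate.
The correction removes the covariate effect but keeps the intercept, so
corrected values stay interpretable in mm³; effect sizes are unchanged by
this location convention.

Asymmetry limits are centred on the *HC mean* AI, not on zero: healthy
controls show a small negative mean volume AI (slightly larger right
hippocampus, about $-0.007$ with deep-learning segmentation), and
zero-centred limits would bias side-specific flags. All HC scans
(including repeats) enter the limits; the sample SD ($n-1$) is used
throughout. Classification direction is metric-dependent: HS *lowers*
volume (AI below the lower limit flags the left side) but *raises* the
surface-to-volume ratio (AI above the upper limit flags the left side).
Sensitivity/specificity/F1 are evaluated on the unilateral-HS vs
all-other-epilepsies contrast only; bilateral HS scans are excluded there
and from the AUC contrast (with the emulated cohort: 37 unilateral HS vs
86 other-epilepsy scans).

The rank-based AUC equals the Mann–Whitney statistic normalised by
$n_+ n_-$ with ties counted 0.5; it is checked exhaustively against brute
force pair counting and against an independent ROC implementation.

## Feature ranking

A linear soft-margin SVM (cost $C = 1$, the conventional default, no class
weighting) is trained on the AI of each of the 14 shape features, in
5-fold cross-validation repeated 20 times. Folds are stratified by
patient: all scans of a subject stay in one fold (asserted by a property
test). Features are standardized with training-fold constants only, so
importances are invariant to affine rescaling of any input and carry no
test leakage. Each run's importance is the normalised absolute primal
weight vector; the final importance is the mean over the 100 runs and the
ranking is deterministic given the seed. The classifier is only a ranking
device, never the diagnostic.

## Robustness

Re-scan sessions group a subject's scans: same calendar day for patients,
greedy chronological chaining within 365 days of the anchor scan for
controls (a documented choice; the session window rule for chains spanning
more than a year is ambiguous, and greedy anchoring at the earliest
unassigned scan is the simplest deterministic resolution). Session-wise
MAPE averages, with equal session weight, each session's mean absolute
deviation from its own mean, as a percentage. ICC(2,1) — two-way random
effects, absolute agreement, single measure — uses the first two scans per
session (earliest by date, ties by scan ID):
$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$
The estimator is verified against an independent `aov()`-based
mean-squares oracle to $10^{-10}$ and by planted variance-component
simulations. Method comparisons use two-sided paired t-tests on the
session-level deviations (the inner MAPE term), the natural session-level
statistic; with zero-variance differences the p-value is 1 (all-zero) or 0
by convention.

## The synthetic-data module

Two fidelity levels keep the statistical stages testable at large n while
the geometry stages see realistic masks.

**Measurement-level cohorts** (`generateMeasurementCohort()`) emulate the
study conditions: 406 HC MRIs from 354 subjects and 126 patient MRIs from
105 subjects (18 HS-left / 19 HS-right / 3 HS-bilateral / 86 other), with
41 re-scan sessions (20 patient same-day pairs — one bilateral subject
contributes a triple — and 21 HC sessions of 3–4 scans within a year).
Defaults plant: HC volume-AI mean $-0.007$ with total SD 0.02; group
volume-AI shifts of $-4.165$ / $+4.203$ total SDs (the deep-learning
effect sizes); an S/V-AI shift of $\pm 2.088$ SDs, the value at which the
population AUC of the absolute AI under the folded-Gaussian model equals
0.87; volumes linear in eTIV and age (slopes 200 and $-150$ mm³ per
covariate SD, residual SD 250 mm³, eTIV $\sim N(1.5\cdot10^6, (1.5\cdot10^5)^2)$ mm³,
age $\sim N(33, 12^2)$ years truncated to [7, 90]); and multiplicative
per-side measurement noise of 2% (volume) and 0.7% (S/V). Session scans
share a subject's latent values; the subject-level AI spread is shrunk so
the *total* per-scan AI SD equals the configured SD, which keeps planted
standardized effects exact at the scan level. What this generator does
*not* emulate: heavy-tailed outliers, segmentation failures, scanner/site
effects, or the correlation structure of real shape features — so passing
tests demonstrate correctness of the machinery at the planted conditions,
not clinical performance. In particular the generator reproduces the
printed effect sizes and AUC, but its Gaussian tails give a different
3-SD F1 trade-off than heavy-tailed clinical data.

**Voxel-level phantoms** (`generateHippocampusMask()`) voxelize a bent
ellipsoid (default semi-axes 19 × 7.5 × 6 mm, parabolic bend): atrophy
scales the cross-section semi-axes by $\sqrt{v}$ so volume scales by
$\approx v$; "fraying" adds a band-limited random field (12 random cosine
harmonics around the configured spatial frequency, unit variance) to the
implicit function, which raises the surface-to-volume ratio strictly and
monotonically; optional spheres carve cavities on the lateral body;
rescan jitter rigidly translates the sampling grid. All generators are
pure functions of their config (seed included).

## Numerical choices and degenerate inputs

* Voxel indices are 0-based; physical coordinates are voxel-centre ×
  spacing. Volumes are canonicalized to RAS on load (when the NIfTI
  carries an xform); left/right is decided by label ID, never by image
  side.
* Empty masks, single-voxel masks (for axis metrics), constant covariates,
  zero AI spread, single-class AUC inputs, zero within-session means and
  zero-variance paired differences all raise explicit errors or documented
  conventions (F1 = 0 with no positive predictions; p = 1/0 for degenerate
  paired tests).
* Maximum-diameter searches are exact brute force over unique vertices
  (meshes at structure scale have a few thousand vertices, so the
  quadratic cost is negligible); a convex-hull prefilter was considered
  and dropped as unnecessary at these sizes.
* Report limit bands are drawn as constant-AI loci — rays through the
  origin with slope $(1-a)/(1+a)$ — because the AI is a ratio; parallel
  offsets would misrepresent the decision rule at small structure sizes.

## Problem sizes used in validation

The shipped validation uses voxelized balls of radius 5–20 mm, phantom
grids of roughly $50^3$ voxels, cohorts of 532 scans, 200-seed
effect-size/calibration recoveries, 500-replicate AUC recovery, and a
70-subject phantom study (20 normative + 50 pathological), sizes at which
every stage's sampling error is far below the tested tolerances.

## Known limitations

* No DICOM input, no intensity radiomics, no hippocampal subfields, no
  site harmonisation, nonlinear age effects or per-protocol covariates.
* No bilateral-HS detector: bilateral disease moves both sides together
  and is nearly invisible to asymmetry; it is visible in the report as
  displacement along the diagonal.
* The pipeline consumes whichever binary segmentation it is given; the
  segmentation engine itself (and its failure modes) is out of scope.
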