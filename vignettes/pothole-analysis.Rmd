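---
title: "Normative FA deviation mapping: models, parameters and design"
author: "potholeFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative FA deviation mapping: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potholeFA)
```

## The problem

Diffuse white-matter injury — as after traumatic brain injury (TBI) — is
spatially heterogeneous: different patients carry damage in different
places, so group-level voxel-wise comparisons of fractional anisotropy (FA)
average away exactly the signal of interest, especially in mild TBI.
Deviation mapping ("pothole" analysis) sidesteps this by scoring each
subject *individually* against a normative control population and counting,
per subject, the contiguous clusters of white-matter voxels whose FA is
abnormally low. The per-subject pothole count is then an ordinary scalar
outcome that standard group statistics can handle.

`potholeFA` implements that pipeline end to end on co-registered volumes:

1. **Normative template** — per-voxel sample mean \(\mu_v\) and sample SD
   \(\sigma_v\) of FA over a control cohort, restricted to the white matter
   common to all controls (`buildTemplate()`).
2. **z-map** — for each subject, \(z_v = (x_v - \mu_v)/\sigma_v\) on the
   intersection of the template's valid voxels with the subject's own
   white-matter mask (`computeZMap()`).
3. **Potholes** — connected components of \(\{v : z_v < -3\}\) under
   26-connectivity, kept when they span at least 10 voxels
   (`detectPotholes()`); per-subject counts and volumes
   (`summarizePotholes()`), group prevalence maps over an atlas
   (`prevalenceMap()`).
4. **Region tables and statistics** — atlas-ROI mean FA (`roiMeanFA()`),
   proportional head-size scaling (`tivScale()`), and the group statistics
   used around such analyses: one-way ANOVA with \(\eta^2\) and Bonferroni
   post hocs — from raw data (`anovaOneway()`) or from published group
   summaries (`anovaFromSummary()`) — pooled t with Cohen's d
   (`ttestPooled()`), Pearson \(\chi^2\) (`chiSquare()`), Mann–Whitney U
   (`mannWhitney()`), Spearman \(\rho\) (`spearmanCor()`), and Bonferroni
   adjustment (`bonferroniAdjust()`).

Registration, brain extraction, tissue segmentation and tensor fitting are
upstream of this package: all volumes are assumed co-registered to one grid,
and the package refuses to mix grids (shape, voxel size within 1e-6 mm, and
orientation tag must match).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `zThreshold` | −3 | SD | Deviations beyond 3 control SDs; strict `<`, so voxels at exactly −3 are excluded. |
| `minSize` | 10 | voxels | Cluster-extent filter. A 10 mm³ filter is also supported (`sizeUnits = "mm3"`), but at a typical DTI voxel of 2 × 2 × 3 mm ≈ 12 mm³ a 10 mm³ threshold is sub-voxel and therefore inert; the 10-voxel form is the operative default. |
| `connectivity` | 26 | — | Faces + edges + corners, the common default of volumetric clustering tools; 6 and 18 are available since conventions differ. |
| `sdFloor` | 1e-6 | FA | Voxels with sample SD below this are dropped from the valid mask, preventing division blow-ups at (near-)constant voxels. |
| `looControls` | `TRUE` | — | Controls are scored leave-one-out by default; see below. |

Sample SD uses denominator \(n-1\): control cohorts in this setting are
small (the reference cohort has 21), where the unbiased form matters.

### Scoring controls: leave-one-out and its null distribution

A control included in its own reference template deflates its own z-scores.
By default each control is therefore scored against a template built from
the *other* controls (`buildTemplateLoo()`); patients are scored against the
full control template. Both modes are available.

This choice has a quantifiable consequence. For Gaussian noise, a z computed
with the *true* mean and SD is sub-threshold with probability
\(\Phi(-3) \approx 0.00135\). But a z computed with mean and SD *estimated*
from \(m\) controls satisfies

\[
\frac{x - \bar\mu_m}{\hat\sigma_m \sqrt{1 + 1/m}} \sim t_{m-1},
\qquad\text{so}\qquad
P(z < -3) = P\!\left(t_{m-1} < \frac{-3}{\sqrt{1+1/m}}\right),
\]

which at \(m = 20\) (leave-one-out from 21 controls) is ≈ 0.0043 — about
3.2× the Gaussian tail. This inflation is not a bug of the pipeline but a
property of small-sample normative z-scoring; the calibration tests
therefore compare the empirical sub-threshold rate against this exact
finite-sample reference (within Monte-Carlo error, computed at the
voxel-block level because leave-one-out scores at one voxel share control
data across subjects), and separately confirm it is of the same order as
the Gaussian tail. Isolated sub-threshold voxels rarely reach the 10-voxel
extent filter, so healthy-control pothole *counts* remain near zero either
way.

## What the synthetic cohort emulates — and what it does not

Because no imaging data ship with the package, a first-class generator
(`generateControlCohort()`, `generateTbiSubject()`, `generateMetadata()`)
produces the study conditions every test runs under:

* a 32 × 32 × 32 grid at 2 × 2 × 3 mm (typical DTI resolution; the toy grid
  is the smallest on which multi-lesion placement with separation margins is
  comfortable), with an ellipsoidal white-matter mask of ≈ 9000 voxels split
  into 8 octant regions standing in for a 48-region white-matter atlas;
* a smooth base FA field, constant per region with values in [0.25, 0.55],
  plus voxel-wise i.i.d. Gaussian noise (SD 0.05), clipped to [0, 1] —
  clipping rather than rejection, negligible at these parameters;
* group sizes 21 / 52 / 17 (control / mild TBI / moderate-severe TBI) and
  metadata tables drawn from the reference cohort's published group means
  and SDs for age, education and symptom scores (clipped to age ≥ 18,
  scores ≥ 0);
* planted lesions: connected blobs (or cuboids) of 20–40 voxels whose FA is
  set to mean − 6 SD (clipped at 0), placed with a 2-voxel Chebyshev margin
  so planted lesions stay disjoint under 26-connectivity. Lesion depth is
  defined against the *true* generating mean/SD, not the estimated
  template, so recovery error isolates the pipeline's estimation noise.
  Five lesions per patient is the desk-scale stand-in for the ~10–12
  potholes reported on full-size brains, whose white matter has an order of
  magnitude more voxels.

The generator deliberately omits spatially correlated noise, Rician noise,
registration error, partial-volume effects and subject-specific anatomy.
Passing tests therefore demonstrate that the *pipeline machinery* is
correct and calibrated under its stated model — not that the method's
sensitivity or specificity transfers to real DTI, where noise is spatially
structured and registration is imperfect.

The gaussian form of the FA noise is this package's modeling choice; the
field does not prescribe a distributional form for registered FA residuals.

## Numerical and design choices

* **Determinism.** Every generator and the pipeline are deterministic
  functions of their seed; cluster output order is fully specified
  (descending voxel count, ties by ascending lexicographic peak index), so
  repeated runs write byte-identical reports.
* **Missing data.** FA outside a subject's mask is `NA`; `NA` voxels can
  never join a cluster. An atlas region with no in-mask voxels yields a
  missing mean (never 0) and is dropped listwise from that region's test,
  with the Bonferroni family sized by the number of regions actually
  tested.
* **Summary-statistics entry points.** `anovaFromSummary()` reconstructs
  SSB = \(\sum n_i(\bar x_i - \bar x)^2\) and SSW = \(\sum (n_i-1) s_i^2\)
  exactly, so published tables of (n, mean, SD) can be re-analyzed;
  agreement with published statistics is limited to ~0.5% relative by the
  rounding of printed summaries. Reconstruction from the reference cohort's
  tables confirms the pooled (not Welch) t and classical (not partial)
  \(\eta^2\) conventions.
* **Rank tests.** Average ranks for ties throughout; Mann–Whitney p by
  normal approximation with tie-corrected variance and no continuity
  correction; Spearman p by the t approximation on \(n-2\) df; Pearson
  \(\chi^2\) without continuity correction.
* **TIV scaling** is proportional (`value × cohortMeanTIV / TIV`), the
  simplest reading of "scaled by intracranial volume"; residual-regression
  scaling is out of scope.
* **Degenerate inputs** are defined, not errors, where a convention exists:
  SST = 0 gives F = 0, \(\eta^2\) = 0, p = 1; equal means with zero pooled
  variance give t = 0, d = 0; zero detections give precision 1 in recovery
  metrics.

## Problem sizes used by the test suite

The suite validates component labeling against a flood-fill oracle on 200
random grids up to 12³ across all three connectivities; lesion recovery on
50 synthetic patients against a 21-control template (voxel recall ≥ 0.95,
exact count recovery in ≥ 90% of subjects); null calibration over 21
leave-one-out controls (~200k voxel scores); ANOVA type-I error over 5000
null replicates; and byte-identical repetition of a 40-subject end-to-end
demo. These sizes give tight Monte-Carlo bounds while keeping a full run in
a couple of minutes on one CPU.

## Known limitations

* Only hypo-FA (one-sided) anomalies are detected; high-FA deviations are
  out of scope.
* No covariate-adjusted normative modeling (age/sex regression per voxel)
  and no robust (median/MAD) template variant.
* Cluster-extent filtering is a fixed threshold; no permutation-based
  extent inference or threshold-free cluster enhancement.
* The statistics module covers the tests listed above; ANCOVA-style
  covariate control is not implemented.
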