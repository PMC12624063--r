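---
title: "Methods: separating and grading white matter hyperintensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating and grading white matter hyperintensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhgrade)
```

## The problem

White matter hyperintensities (WMH) are bright lesions of the cerebral white
matter on FLAIR MRI, graded in clinical practice on the Fazekas scale (0-3)
or the 5-grade Brain Dock scale used in Japanese brain screening, separately
for periventricular hyperintensities (PVH, adjacent to the lateral
ventricles) and deep/subcortical hyperintensities (DWMH). Visual grading is
subjective and shows substantial inter-rater variability. Given segmented
binary masks — brain, lateral ventricles, WMH — this package automates the
downstream part of grading: the anatomical split of WMH into PVH and DWMH,
volume normalization, threshold learning, grade prediction, and agreement
evaluation. Segmentation itself is out of scope; any segmentation tool that
produces co-registered masks can feed the pipeline.

## The periventricular/deep partition

PVH is defined by the widely used 10 mm distance rule: white matter within
10 mm of the ventricular surface is periventricular. The PV shell is built by
morphological dilation of the ventricle mask with a single anisotropic
ellipsoidal structuring element containing every integer voxel offset
$(i,j,k)$ with

$$ (i\,s_x)^2 + (j\,s_y)^2 + (k\,s_z)^2 \le (10\,\mathrm{mm})^2, $$

where $(s_x, s_y, s_z)$ is the voxel spacing, followed by subtraction of the
original ventricle voxels. This is exactly equivalent to thresholding the
anisotropic Euclidean distance transform at 10 mm (distances measured between
voxel centers; no sub-voxel surface model), and the element's central plane
is the 10 mm in-plane disk, so the construction also contains the union of
separate 2D and 3D expansions. The test suite keeps a brute-force distance
transform as an independent oracle and checks voxel-identity on random
anatomy.

Clinical FLAIR in this setting has 0.4-1 mm in-plane resolution but 5-6 mm
slices, and no axial resampling is performed; with 6 mm slices the element
spans only one slice up and down, which is the intended, spacing-aware
behavior. The axial axis defaults to the axis of maximum spacing and can be
overridden.

WMH components are then labeled per axial slice (8-connectivity in plane by
default; components are never merged across slices) and classified against
the shell:

* entirely inside the shell: PVH;
* entirely outside: DWMH;
* boundary-spanning: wholly PVH when **strictly more than 60%** of its voxels
  lie in the shell, otherwise split voxelwise.

The 60% cut is the default of a tunable `pv_fraction` parameter (the usual
ablation range is 0.5-0.9). The strict inequality means a component at
exactly 60% is split; overlap is computed in voxel counts, which equals an
area fraction within one slice because in-plane spacing is uniform. Split
components are recorded once with `assigned = "split"`; the voxelwise masks
carry the partition. By construction PVH and DWMH masks are disjoint and
their union is the input WMH mask — an invariant the suite checks on random
masks.

## Volume ratios and grading

Lesion volumes are voxel counts times voxel volume, normalized by total brain
volume into dimensionless *volume ratios* to remove head-size effects. Grade
prediction applies ordered boundary thresholds to the ratio; a ratio equal to
a threshold takes the higher grade (the ROC positive-call convention; the
choice of side is a convention, and ties have measure zero for continuous
ratios). The shipped defaults are the published Fazekas Youden-neighbor
thresholds (PVH 0.00017/0.00402/0.00977, DWMH 0.00013/0.00179/0.00743), so
the tool grades without local training data.

Three threshold learners are provided:

* **density** — per-grade Gaussian KDE of the ratios; the boundary threshold
  is the arithmetic midpoint of adjacent grade peaks. Bandwidth is
  Silverman's rule with a floor of $10^{-6}$ (so constant samples still
  yield a sharply peaked density); peaks are located by argmax on a
  2048-point grid over $[0, 1.05\max r]$. Kernel, bandwidth rule, raw-scale
  ratios, and grid are our numerical choices; the grid step bounds the peak
  quantization error at about $2.6\times10^{-6}$ in ratio units.
* **Youden-all** — each boundary $g|g{+}1$ is a binary ROC problem with all
  grades $\le g$ negative and $\ge g{+}1$ positive; the cutoff maximizes
  Youden's $J = \text{sens} + \text{spec} - 1$.
* **Youden-neighbor** — the same, restricted to the two adjacent grades.

ROC candidates are the midpoints of consecutive distinct pooled ratios plus a
sentinel below the minimum, which enumerates every achievable confusion
table, so the scan is exact and reproducible; ties in $J$ break toward higher
sensitivity, then the smaller cutoff. Non-monotone fitted thresholds (possible
with heavily overlapping grades) are sorted with a warning rather than
rejected, since prediction needs a monotone set. Brain Dock predictions merge
grades 3 and 4 onto Fazekas grade 3 for cross-scale validation; merging after
prediction is identical to predicting with the 3|4 boundary dropped.

## Evaluation

The evaluation mirrors standard grading studies: binary accuracy and F1 at
every grade boundary (0 vs 1/2/3, 0/1 vs 2/3, 0/1/2 vs 3 for Fazekas, plus
0/1/2/3 vs 4 for Brain Dock; positive class is the upper-grade group, F1
defined 0 when precision + recall is 0), multi-class accuracy, macro F1
(unweighted mean over grades present in ground truth or prediction; absent
grades are excluded rather than scored 0), and MAE on integer grades of the
scale in use. Agreement uses unweighted Cohen's kappa between two raters and
Fleiss' kappa over a fixed panel; a panel that uses a single category
everywhere has chance agreement 1 and kappa is reported as NaN with a
warning. All metrics are validated to 1e-12 against naive loop-based
implementations.

## The phantom and cohort simulators

`make_phantom()` builds a geometric subject: an ellipsoidal brain, two
ellipsoidal ventricle bodies, and spherical lesions rasterized in mm space at
requested distances from the ventricular surface. Each lesion's actual
relation to the 10 mm shell is verified on the exact distance map at
generation time, so the phantom carries exact PVH/DWMH ground truth; lesions
may not overlap anything, keeping the component-truth mapping unambiguous.
The default geometry (96 x 96 x 16 voxels at 0.9 x 0.9 x 6 mm) reproduces the
thick-slice regime.

`sample_cohort()` draws grade-conditional volume ratios from log-normal
distributions moment-matched to per-grade mean/SD lesion volumes in mL. The
defaults are calibrated to a 137-subject graded training cohort (e.g. Brain
Dock PVH means 0.451, 1.535, 8.456, 13.503, 18.632 mL for grades 0-4, with
SDs comparable to the means — hence the right-skewed log-normal model), and
converted to ratios with a nominal 1400 mL adult brain, since the source
statistics are absolute volumes. Fazekas defaults pool the two highest Brain
Dock grades weighted by their subject counts. What the simulators do *not*
emulate: FLAIR intensities, segmentation errors, irregular confluent lesion
shapes, posterior-horn ambiguity, or rater-dependent label noise — so green
tests certify the downstream machinery, not segmentation robustness on real
data.

For validating threshold learning against an optimal-decision oracle, the
suite uses common-variance log-normal grades (sdlog 0.35, meanlog spaced 0.8
apart): with a shared sdlog the likelihood ratio between adjacent grades is
monotone, the Bayes decision rule is itself a set of ratio thresholds, and a
threshold learner can meaningfully be compared to a density-ratio oracle.
Youden-neighbor is Bayes-consistent in that design (equal-sized adjacent
grades put the Youden cutoff at the density crossing). Youden-all is not:
with one grade against three, maximizing sensitivity + specificity weights
the sides equally regardless of their sizes and converges to a different
cutoff than the accuracy-optimal one — in our design its asymptotic held-out
accuracy is about 4 points below the Bayes rate. That deficit is a property
of the index, not an implementation defect, and matches the strategy's
relatively weaker multi-class performance in practice.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `pv_distance_mm` | 10 | mm | periventricular shell radius |
| `pv_fraction` | 0.6 | fraction | strict `>`; ablation range 0.5-0.9 |
| `connectivity` | 8 | — | in-plane component connectivity (4 or 8) |
| binarization threshold | 0.5 | intensity | strict `>`, for probabilistic masks |
| KDE bandwidth | Silverman, floor 1e-6 | ratio | density method only |
| nominal brain volume | 1400 | mL | cohort simulator mL-to-ratio conversion |

## Problem sizes and determinism

All randomness flows through explicit integer seeds (phantom, cohort, CLI),
and the pipeline is byte-deterministic for a fixed seed. The suite exercises
random grids up to 48 x 48 x 12 voxels against the brute-force distance
oracle and cohorts of 100 subjects per grade, sizes at which the oracle
remains exact and cheap while covering the clinically relevant spacing
regime. One caveat on NIfTI round trips: the format stores spacing as 32-bit
floats, so volumes recomputed after a write/read agree to about seven
significant digits, not exactly.

## Known limitations

* The partition assumes correct upstream segmentation; no morphological
  cleanup of the input masks is attempted.
* Distance is center-to-center; with 6 mm slices the shell boundary is
  quantized at slice resolution, as in any voxel-space implementation
  without resampling.
* The learned thresholds are only as transferable as the training cohort's
  acquisition and grading conventions; the shipped defaults come from one
  multicenter cohort.
* Only a fixed-mm distance rule is implemented; ventricle-size-normalized
  distance rules and 3D component analysis are out of scope.
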