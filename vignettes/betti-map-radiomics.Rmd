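---
title: "Betti-number map radiomics: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Betti-number map radiomics: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bettimap)
```

## The method in one paragraph

Solid lung tumors that carry actionable genotypes (the motivating case is
EGFR-mutant non-small-cell lung cancer) tend to show hazy, ground-glass-like
low-attenuation regions inside the solid lesion on CT. When the image is
binarized at an intensity threshold, such regions appear as *holes* —
enclosed background components — in the foreground. `bettimap` quantifies
this topology directly: a re-quantized axial tumor slice is thresholded at
every gray level, a small window slides over each binary image, and every
window is summarized by its Betti numbers — `b0`, the number of 8-connected
foreground components, and `b1`, the number of enclosed holes (4-connected
background components not touching the window border). This yields, per
q-bit slice, `2^q × 3` maps (`b0`, `b1`, `b1/b0`), which are then treated
like ordinary radiomic images: 54 histogram and texture features per map,
a Mann–Whitney screen, a robustness-index-driven search for a 1–4 feature
signature, and an SVM classifier. Because Betti numbers are topological
invariants, the maps are insensitive to smooth deformations of the lesion
and, empirically, more stable across scanners than plain intensity texture.

## Pipeline stages and their parameters

### Preprocessing (`resample_isotropic`, `select_max_area_slice`, `requantize`)

* **Isotropic voxel, 0.77 mm.** CT voxels are anisotropic; all geometry
  below assumes square pixels. Intensities are resampled with Keys cubic
  convolution; the target grid has `round(dim × spacing / iso_mm)` voxels
  per axis. Masks are resampled *shape-based*: the signed Euclidean
  distance field of the mask (negative inside) is interpolated cubically
  and re-thresholded at zero, which preserves the object's shape and
  topology where a naive nearest-neighbour mask resample would staircase
  or fragment it.
* **Analysis slice.** The axial slice with the maximal ROI area, chosen
  *after* resampling (the pre-resampling slice grid no longer exists on
  the isotropic grid); ties break to the lowest index. The analysis is
  deliberately 2-D.
* **Re-quantization.** HU are clipped to a window and mapped linearly to
  `2^q` levels, `g = floor((v − lo)/(hi − lo)·2^q)` with the top edge
  assigned `2^q − 1`. Presets: full (−1000, 1500), lung (−1350, 150),
  mediastinal (−150, 250) HU; bit depths 5–8. The package default is the
  mediastinal window, which places soft tissue mid-scale and clips both
  air and ground-glass attenuation to the bottom levels — the regime in
  which holes are crisp.

### Betti-number maps (`bn_maps`)

* **Connectivity.** Foreground 8, background 4 — the standard pairing on
  the square lattice; with any other pairing a diagonal line would both
  connect and separate, and counts become inconsistent.
* **Binarization.** Foreground is `pixel ≥ t`, `t = 0 … 2^q − 1`, so the
  `t = 0` map is all-foreground and the threshold ladder is monotone.
* **Windows.** Square kernels 5–11 px, strides 1–5 px; only fully
  contained windows are evaluated. Padding would create artificial
  components and border-touching pseudo-holes, so partial windows are
  skipped rather than padded; the map grid is
  `floor((dim − k)/s) + 1` per axis.
* **Ratio map.** `b1/b0` with the convention `0` when `b0 = 0` (an empty
  window has no components and no holes).
* **ROI transfer.** A map cell belongs to the ROI iff its window's center
  pixel does.

### Features (`extract_bn_features`, `extract_oi_features`, `extract_wd_features`)

Each map restricted to the ROI yields 54 features: 14 histogram features
(mean, population variance, skewness, kurtosis, energy, entropy, min, P10,
median, P90, max, range, IQR, uniformity) and 40 texture features — 9 GLCM,
13 GLRLM, 13 GLSZM, 5 NGTDM, with the standard formulas of the Vallières
radiomics feature family. Totals: `2^q × 3 × 54` BN features (41,472 at
8 bits, 5,184 at 5 bits), 54 original-image features, and 216
wavelet-decomposition features (4 subbands × 54).

Discretization for the texture matrices distinguishes two cases. Integer
non-negative maps (Betti counts, re-quantized images) keep their values as
gray levels — `G = max + 1`, preserving count semantics — capped at 64
levels with linear re-binning. Real-valued maps (`b1/b0`, wavelet subbands)
are equal-width binned into 32 levels over the ROI range. Texture formulas
index levels from 1, so level-weighted features (LGRE, HGZE, …) are always
defined. Zero-denominator conventions: GLCM correlation is 0 at zero
variance; NGTDM busyness and strength are 0, and coarseness is capped at
10^6, when their denominators vanish. GLCM matrices are symmetric,
distance 1, normalized per direction and averaged over 0/45/90/135;
run-length matrices are summed over the four directions before features.

The wavelet comparator uses a single-level *stationary* (undecimated)
Coiflet-1 transform with symmetric boundary extension, so the four
subbands keep the slice's shape and the ROI applies pixel-for-pixel. A
decimated transform would halve the grid and force ROI resampling; the
undecimated variant avoids that at no modeling cost. With periodic
extension the transform is exactly invertible, which the tests use.

### Signature search (`mann_whitney_filter`, `search_signature`)

Features pass a two-sided Mann–Whitney U screen (p < 0.05, exact null
distribution when both groups have ≤ 8 cases, tie-corrected normal
approximation otherwise; no multiplicity correction — the screen is a
filter, not an inference). Candidates are ranked by the robustness index
of a stratified five-fold cross-validated SVM (Gaussian kernel, C = 1,
gamma = 1/N, features z-scored with training-fold statistics):

RI = (AUC_train + AUC_valid) / (1 + |AUC_train − AUC_valid|),

which rewards a high total AUC and a small train/validation gap; it is
symmetric, increasing in each argument, and peaks at 2. The top 25
candidates stay in play; starting from the best single feature the set
grows greedily to at most 4 features, and the globally RI-maximal set is
the signature. Exhaustive search over tens of thousands of features is
infeasible; the greedy scheme with a ranked pool is the bounded
adaptation, and it is deterministic given the fold seed (ties break to
the earlier-ranked candidate).

### Modeling and evaluation (`grid_search_svm`, `evaluate`, `delong_test`, `icc_robustness`)

The final SVM is optionally tuned over linear/Gaussian/sigmoid kernels
with C (and gamma) on 0.1–10 in steps of 0.3 — 34 values, hence
34 + 34² + 34² = 2,346 configurations — again by maximizing the RI.
Evaluation reports AUC with a 2,000-replicate case-resampled percentile
bootstrap CI, plus accuracy, sensitivity and specificity at the frozen
decision-score threshold 0 (positives = mutants; the package does not
refit the operating point on evaluation data). AUC pairs are compared
with the DeLong structural-components test (p = 1 by convention at zero
variance). Feature stability across re-segmentations is graded by
ICC(2,1) — two-way random effects, absolute agreement, single
measurement, the form matching the poor/moderate/good/excellent
cut-points at 0.5/0.75/0.9; a feature constant across all cells has an
undefined ICC and is excluded from the signature mean.

### Reported validation AUC is a holdout estimate

The signature search *selects* by cross-validated AUC, so the search's own
`AUC_valid` is optimistic: with thousands of candidate features the
selected signature's CV AUC sits far above chance even on label-free
noise. `run_train_eval()` therefore sets aside a stratified holdout
(default one third of the training cases) before any filtering or
searching, and reports its validation AUC on that untouched partition.
The search keeps its internal CV contract; only the *reported* estimate is
shielded. With this design a cohort with no class signal reports
validation AUCs centred on 0.5, while the search-internal CV AUC would
centre near 0.75 — the gap is pure selection bias, worth remembering when
reading radiomics signature papers.

## The phantom: what it emulates, and what it does not

`phantom_spec()` renders a bright solid ellipsoidal lesion (default
9 × 9 × 12 mm at 40 HU) in a dark lung background (−800 HU) on a
deliberately anisotropic grid (0.7 × 0.7 × 2.0 mm) so the resampling front
end is always exercised. Heterogeneity comes from smooth Gaussian blobs
(±50 HU); the class signal comes from a Poisson number of small spherical
holes depressed by 550 HU — the hazy low-attenuation structures the
method is built to count. Holes are drawn with radii 0.8–1.6 mm, kept
fully interior to the tumor, separated by at least 1 mm of tissue, and
placed within a ±2 mm axial slab around the equator. The size and
separation constraints matter: each hole must survive thresholding as a
*distinct enclosed* background component at the analysis resolution —
overlapping or oversized holes would merge into cavities that register as
suppressed `b0` rather than as `b1`, changing the character of the planted
signal. The slab keeps the holes visible to the single analysis slice.
Cohorts add label-independent nuisance variation (per-case pixel size
0.6–0.8 mm, slice thickness 1.5–2.5 mm, noise 10–20 HU) mimicking scanner
diversity, and `perturb_mask()` emulates multi-rater segmentation by
adding smooth random fields to the mask's signed distance function.

The phantom does *not* model CT physics (no beam hardening,
reconstruction kernels, partial-volume blur beyond interpolation) nor
realistic tumor morphology; a passing planted-signal test shows the
pipeline recovers a topological class difference under nuisance
variation, not that it reproduces clinical discrimination on real CT.

## Reference desk-scale conditions

The package's default run configuration is the mediastinal window at
5 bits, kernel 7, stride 2 on 120-case cohorts (60/60). Kernel 7 is the
canonical window size of the method's geometry search; 5 bits and stride 2
scale the threshold ladder and window grid to sizes a laptop handles in
seconds per case while leaving the hole geometry resolvable (window
centers every ~1.5 mm against hole diameters of 1.6–3.2 mm). The
end-to-end acceptance checks run the planted cohort once and ten null
cohorts at these conditions; the null battery is summarized by its mean
holdout AUC, the natural calibration summary for a seed battery.

## Numerical conventions collected in one place

* Resampled grid dimension: `round(extent/iso)`; sampling positions
  `j × iso` from the first voxel center; border handling by clamping.
* Mask re-threshold after distance-field interpolation: inside iff
  signed distance < 0.
* Slice-selection and all search ties: lowest index / earliest candidate.
* `b1/b0 := 0` where `b0 = 0`; binarization uses `≥ t`.
* Quantization top edge maps to `2^q − 1`; values outside the window clip.
* Histogram skewness/kurtosis of a constant sample: 0.
* Stratified five-fold CV needs ≥ 5 cases per class; the holdout draw is
  stratified and seeded separately from the folds.
* Bootstrap replicates that draw a single class are redrawn.

## Known limitations

* The analysis is single-slice 2-D; no `b2` (3-D cavity) counting.
* Betti counting is per-threshold; no persistence across the ladder.
* The greedy signature search is not exhaustive and can miss interacting
  feature pairs whose singles rank below the pool cut.
* NRRD support covers plain raw/gzip attached-header files; DICOM series
  are not read — convert to NIfTI upstream.
* Texture matrices are 2-D by construction.
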