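# bettimap

Topological radiomics for CT: classify tumor phenotype (the motivating
application is EGFR mutation status in non-small-cell lung cancer) from
**Betti-number maps** — images of the topology of a lesion rather than its
texture.

Hazy, ground-glass-like regions inside a solid tumor become *holes* when
the image is thresholded. `bettimap` measures them directly: a re-quantized
axial tumor slice is binarized at every gray level `t = 0 … 2^q − 1`, a
`k × k` window slides across each binary image, and every window is
summarized by its Betti numbers

* `b0` — number of 8-connected foreground components,
* `b1` — number of enclosed holes (4-connected background components not
  touching the window border),

giving `2^q × 3` maps (`b0`, `b1`, `b1/b0`) per slice. Because Betti
numbers are topological invariants, these maps are robust to smooth
deformations and scanner-dependent appearance. The maps are then treated
as radiomic images: 54 histogram/texture features each (histogram, GLCM,
GLRLM, GLSZM, NGTDM — `2^q × 3 × 54` features per case, 41,472 at 8 bits),
screened by Mann–Whitney tests, and compressed into a 1–4 feature
signature that maximizes the **robustness index**

```
RI = (AUC_train + AUC_valid) / (1 + |AUC_train − AUC_valid|)
```

under stratified five-fold cross-validated SVM evaluation (Gaussian
kernel, C = 1, gamma = 1/N). Final models can be grid-tuned over
linear/Gaussian/sigmoid kernels with C, gamma ∈ {0.1, 0.4, …, 10}
(2,346 configurations) and are reported with bootstrap AUC confidence
intervals, DeLong AUC comparisons, and ICC-based robustness grades of the
signature across repeated segmentations. Original-image (54 features) and
stationary Coiflet-1 wavelet (216 features) comparator pipelines are
included, as is a synthetic lung-tumor phantom generator so the whole
pipeline runs end to end without clinical data.

## Worked example

Generate a 24-case synthetic cohort in which mutants carry about nine
low-intensity holes and wildtypes about one, extract Betti-map and
original-image features, and run selection + evaluation:

```r
library(bettimap)

cohort <- generate_cohort(cohort_spec(
  n_mutant = 12, n_wildtype = 12,
  lambda_mutant = 9, lambda_wildtype = 1, seed = 33))

cfg    <- run_config(approaches = c("bn", "oi"), boot_b = 100,
                     holdout_frac = 0.25, seed = 33)
tables <- run_extract(cohort, cfg)
report <- run_train_eval(tables, cfg)
report
```

```
<pipeline_report> approaches: bn, oi 
  bn: RI 1.7, signature [b1_Histogram_Mean_1]
  oi: RI 1.077, signature [Histogram_P10]
  winner by RI: bn 
```

Reading the output: for each feature approach the pipeline reports the
selected signature and its robustness index. Here the Betti-map approach
wins (RI 1.7 vs 1.08) with a one-feature signature built on the mean of
the `b1` (hole-count) map at threshold 1 — exactly the planted
topological signal — while the original-image comparator falls back on an
intensity percentile and generalizes worse. The reported validation AUC
(`report$approaches$bn$auc_valid`, here 0.89) is computed on a stratified
holdout that took no part in feature screening or the signature search,
so it is not inflated by selection.

Lower-level entry points mirror the pipeline stages: `preprocess_case()`
(isotropic resampling, max-area slice, re-quantization), `bn_maps()` /
`betti_numbers()`, `extract_bn_features()` / `extract_oi_features()` /
`extract_wd_features()`, `mann_whitney_filter()`, `search_signature()`,
`grid_search_svm()`, `evaluate()`, `delong_test()`, `icc_robustness()`.
Results carry `tidy()`/`glance()` methods and `autoplot()` for BN map
stacks, search traces and ROC curves. A thin command-line wrapper lives at
`inst/cli/bettimap.R` (`phantom`, `extract`, `train` subcommands).

See the vignette (`vignettes/betti-map-radiomics.Rmd`) for the model,
every numerical convention, and the phantom's design and limits.

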