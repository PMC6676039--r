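# sfdihist

Predicting histological tissue composition of breast specimens from
wide-field light-scattering maps.

## The problem

Breast-conserving surgery needs fast intraoperative triage of resected
tissue, but gold-standard histopathology takes days. Spatial frequency
domain imaging (SFDI) measures, label-free and per pixel, three scattering
parameters of fresh tissue: the reduced scattering coefficient μs′ (mm⁻¹),
the phase-function parameter γ, and the scatter power B in
μs′(λ) = A·(λ/800 nm)^−B. These parameters carry morphological information,
because collagenous **stroma**, cellular **epithelium** (elevated in
invasive cancer), and **adipose** scatter light differently.

`sfdihist` implements the full computation connecting the two modalities,
for imaging scientists and computational pathology researchers:

* **Histology quantitation** — white balance, Ruifrok–Johnston-style
  optical-density stain unmixing, HSV-saturation stain labelling
  (hematoxylin / eosin / no-stain, with the 1/10-maximum white-space rule),
  and epithelium/stroma/adipose volume fractions over 200 μm voxels.
* **Scattering–fraction models** — for each of μs′, γ, B: a two-parameter
  logistic `1/(1 + exp((x−c)/w))` for the monotone stroma and adipose
  responses and a three-parameter Gaussian `a·exp(−(x−c)²/2w²)` for the
  peaked epithelium response, fitted by bounded multi-start nonlinear least
  squares, with rmse, adjusted R², and delta-method 95% prediction
  intervals.
* **LOO-CV prediction** — each specimen's fractions predicted as the mean of
  the three per-property model outputs (clipped to [0,1]), with all nine
  models refitted without the held-out specimen.
* **Classification** — adipose > 0.5 → fat; else epithelium:stroma
  ratio > 1 → malignant, else benign; plus soft classification maps whose
  color saturation encodes distance to the thresholds, and photograph
  overlays.
* **Performance statistics** — confusion matrices, one-vs-rest
  sensitivity/specificity/accuracy with exact Clopper–Pearson binomial CIs,
  Pearson correlations, pooled two-sample t-tests.
* **Synthetic data** — a generator emulating a 31-specimen cohort
  (10 invasive / 16 fibroglandular / 5 fat) and H&E-like slide images with
  known ground truth, so every stage is testable end to end without any
  download.

See `vignettes/scattering-to-histology.Rmd` for the model details and design
rationale.

## Worked example

Simulate a cohort with moderate observation noise, run leave-one-out
cross-validation, and report performance:

```r
library(sfdihist)

gen  <- generate_cohort(cohort_config(fraction_noise_sd = 0.10, seed = 42))
pred <- loo_cv(gen$cohort)

sapply(c("stroma", "epithelium", "adipose"), function(fr)
  round(pearson_correlation(pred[[fr]], gen$cohort[[paste0(fr, "_mean")]])$r, 3))
#>     stroma epithelium    adipose
#>      0.970      0.980      0.981

performance_report(pathology_to_class(gen$cohort$class), pred$predicted_class)
#> performance_report (0.95 level, unit = specimen, n = 31)
#>            predicted
#> true        malignant benign fat
#>   malignant         9      1   0
#>   benign            0     16   0
#>   fat               1      0   4
#> overall accuracy 0.94 (0.79-0.99)
#>   malignant    sensitivity  0.90 (0.55-1.00)
#>   malignant    specificity  0.95 (0.76-1.00)
#>   ...
```

The correlations say how well scattering-predicted volume fractions track
the (synthetic) histology ground truth across specimens; the confusion
matrix and one-vs-rest metrics summarize the threshold classifier, each with
an exact 95% binomial interval. One fitted curve looks like:

```r
fit_all_models(gen$cohort)$stroma$gamma
#> scatter_model logistic2: stroma ~ gamma
#>   params: c = 1.575, w = 0.0243
#>   rmse = 0.101, adj R^2 = 0.9369, n = 31
```

i.e. the stroma fraction falls off logistically around γ ≈ 1.57 with width
0.024 (γ decreases with stromal content in the simulated world, hence the
positive `w`).

### Command line

```sh
Rscript inst/cli/sfdihist simulate --out fixtures --seed 7
Rscript inst/cli/sfdihist segment --slide fixtures/slide_heterogeneous.ppm \
        --resolution 500 --out seg_out
Rscript inst/cli/sfdihist run-all --cohort fixtures/cohort.csv --out study_out
```

Images travel as ASCII PPM/PGM and maps as CSV (plain-text, diff-friendly;
no image codecs required). Exit codes: 0 success, 1 usage, 2 data error,
3 computation failure. Every run writes a `manifest.json`; repeating a run
with the same config and seed reproduces its outputs byte-for-byte.

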