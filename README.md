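# polcropsar

Crop classification from co-registered quad-polarimetric SAR and
multispectral optical imagery, by feature-level integration.

Polarimetric SAR (PolSAR) sensors measure the full scattering matrix per
pixel and, after multi-looking, deliver a 3×3 Hermitian covariance matrix
C₃ — a data structure that cannot be stacked next to optical reflectance
bands for a conventional per-pixel classifier. This package solves that by
transforming C₃ into a nine-channel intensity vector on different
polarization bases (linear h/v, ±45° linear, left/right circular), which has
the same "multi-band raster" structure as optical data, and then integrating
reduced SAR and optical feature sets for supervised classification. It is
aimed at agricultural remote-sensing work where radar structure information
and optical spectral information are complementary.

## Method

For the lexicographic scattering vector k = (S_HH, √2 S_HV, S_VV) and
covariance C₃ = ⟨k kᴴ⟩, each channel intensity is the backscattered power

    DN_pq = ⟨|qᵀ S p|²⟩,

for transmit/receive Jones vectors p, q drawn from {h, v, ±45°, l, r}.
Expanding the quadratic form gives a real, invertible 9×9 linear map M from
the nine real parameters of C₃ to the nine intensities P⃗; the package
constructs M analytically from the Jones vectors and carries its exact
inverse B. Intensities are converted to dB, σ⃗ = 10 log₁₀ P⃗, and reduced by
PCA (components `sigma_pca1`, `sigma_pca2`, … up to 98% cumulative
variance).

The SAR side further extracts:

* the Yamaguchi four-component powers Ps, Pd, Pv, Pc (surface,
  double-bounce, volume, helix), with three-branch volume-model selection on
  the 10 log₁₀(⟨|S_VV|²⟩/⟨|S_HH|²⟩) ratio at ±2 dB, helix power capped at
  2⟨|S_HV|²⟩, and exact conservation Ps+Pd+Pv+Pc = Span;
* the radar vegetation index RVI = 8⟨|S_HV|²⟩ / Span ∈ [0, 4].

The optical side extracts band-PCA components (`Opband_pca1`, …, 99%
variance), NDVI = (NIR−R)/(NIR+R), and a sliding-window Shannon entropy
texture H on the red band. All features are min–max normalized to [0, 1] and
stacked in one of five integration modes (`full` = 7 SAR + 4 optical layers,
two reduced 9-layer modes, and the two single-source modes). Classification
is by an RBF-kernel SVM with cross-validated hyperparameters, or by the
complex-Wishart maximum-likelihood rule d_m(C) = ln det Σ_m + tr(Σ_m⁻¹ C)
operating on C₃ directly. Accuracy assessment produces the confusion matrix
(rows = classified, columns = reference), overall accuracy, kappa,
user's/producer's accuracies and one-vs-rest TP/FN/TN/FP rates.

A seeded simulator generates labeled scenes — multi-look complex-Wishart
speckle around class covariances on a rectangular field mosaic, plus
truncated-Gaussian optical reflectances — so the whole chain is testable
without satellite data.

## Worked example

```r
library(polcropsar)

sc     <- generateScene(simConfig(seed = 42))   # 128x128, 4 classes, L = 4
sarFs  <- buildSarFeatures(sc$c3)
optFs  <- buildOpticalFeatures(sc$optical)
stack  <- assembleFeatures("full", sarFs, optFs)
handle <- svmTrain(stack, sc$train, seed = 42)
map    <- svmPredict(stack, handle)
report <- accuracyMetrics(confusionCounts(map, sc$test))
report
```

prints

```
RBF-SVM handle: 11 layers, cost = 100, gamma = 0.1, CV accuracy = 0.885
Overall accuracy: 89.2415%   kappa: 0.8566
       UA (%) PA (%)
crop_a  85.91  80.01
crop_b  92.83  95.61
veg_c   90.80  88.96
veg_d   87.24  92.38
```

89.2% of the held-out field pixels are labeled correctly; kappa 0.86 is the
chance-corrected agreement. The four simulated classes are built so that
`crop_a`/`crop_b` differ only polarimetrically and `veg_c`/`veg_d` only
spectrally, so the `sar_only` and `optical_only` modes each top out near
60–65% on this scene while the integrated stack resolves all four classes —
the core claim of the integration approach, reproduced as a property of the
method rather than of any particular satellite acquisition.

The same run is available end to end from a config file
(`inst/extdata/example_config.yaml`) via `runPipeline()`, which writes the
feature stack, class map, confusion CSV, accuracy report and a run log
(config hash, seed, PCA variance fractions, chosen SVM hyperparameters).
A thin CLI over the same functions lives at `inst/scripts/polcropsar`
(subcommands `simulate`, `features-sar`, `features-optical`, `integrate`,
`train`, `classify`, `assess`, `run`).

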