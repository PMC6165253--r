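---
title: "Integrated PolSAR + optical crop classification: models and design choices"
author: "polcropsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated PolSAR + optical crop classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcropsar)
```

# The problem

Quad-polarimetric SAR delivers, per pixel, a 3×3 Hermitian covariance matrix
$C_3 = \langle k k^H \rangle$ of the lexicographic scattering vector
$k = (S_{HH}, \sqrt{2} S_{HV}, S_{VV})$. Optical sensors deliver reflectance
bands. The two are complementary for crop mapping — radar responds to
canopy structure, orientation and moisture through scattering mechanisms,
optical to leaf chemistry through spectra — but a covariance matrix cannot
be stacked next to reflectance bands in a per-pixel feature classifier.
This package integrates them at the feature level: the covariance matrix is
transformed losslessly into nine backscatter intensities on different
polarization bases, which have the same multi-band structure as optical
data, and reduced feature sets from both sensors are stacked for a
supervised classifier.

# The polarization-basis intensity transform

Each channel is the power received in a transmit/receive polarization state
pair $(p, q)$ drawn from horizontal, vertical, ±45° linear and left/right
circular states:
$$DN_{pq} = \langle |q^T S p|^2 \rangle .$$
Since $q^T S p$ is linear in $k$, every $DN_{pq}$ is a real linear form in
the nine real parameters of $C_3$ (three diagonal intensities, real and
imaginary parts of the three off-diagonal correlations). Stacking the nine
forms gives an invertible 9×9 matrix $M$; the package constructs it
analytically from the Jones vectors
$h=(1,0)$, $v=(0,1)$, $\pm45 = (1,\pm1)/\sqrt2$, $l=(1,i)/\sqrt2$,
$r=(1,-i)/\sqrt2$ (backscatter alignment convention) rather than typing in a
printed matrix, and validates $M B = I$ to $10^{-10}$ at construction time.
Any self-consistent Jones convention yields an equivalent invertible
transform; fixing this one makes every downstream number deterministic.
The physical radiometric prefactor of the transform is kept as a single
global scale constant (default 1): it cancels in dB differences, PCA,
min–max normalization and both classifiers, so no downstream result depends
on it.

The channel order is fixed and documented (`polChannels()`): hh, vv,
+45+45, −45−45, ll, rr, h+45, hl, +45l. For positive semidefinite input all
intensities are non-negative; round-off below $-10^{-9}\cdot$span is counted
and clipped to zero. Intensities convert to dB as
$\sigma = 10\log_{10} P$, with a floor (default −50 dB) substituted where
$P \le 0$ so normalization always sees finite values.

# Yamaguchi four-component decomposition

The decomposition splits span $= \langle|S_{HH}|^2\rangle +
2\langle|S_{HV}|^2\rangle + \langle|S_{VV}|^2\rangle$ into surface ($P_s$),
double-bounce ($P_d$), volume ($P_v$) and helix ($P_c$) powers:

* helix power $P_c = 2\,|\mathrm{Im}(\langle S_{HH}S_{HV}^*\rangle +
  \langle S_{HV}S_{VV}^*\rangle)|$, capped at the total cross-polarized
  power $2\langle|S_{HV}|^2\rangle$;
* the volume covariance model is chosen among three canonical shapes by the
  ratio $10\log_{10}(\langle|S_{VV}|^2\rangle/\langle|S_{HH}|^2\rangle)$
  with ±2 dB branch thresholds, and its contribution is scaled to the
  helix-corrected cross-pol power;
* the residual co-polarized power is split into surface and double-bounce
  through the $f_s, f_d, \alpha, \beta$ system: the sign of the residual
  HH–VV correlation decides the dominant mechanism
  ($\alpha=-1$ when surface dominates, $\beta=1$ when double-bounce
  dominates), and the remaining two unknowns follow in closed form.

Negative component powers are clipped to zero and the deficit reassigned to
the other co-polarized component, so $P_s+P_d+P_v+P_c = \mathrm{span}$
holds *exactly* on every valid pixel — conservation is enforced
structurally, not approximately. Pixels whose matrix is not positive
semidefinite (checked through leading principal minors with a relative
tolerance of $10^{-9}$) are masked out and counted instead of producing
negative powers. The vectorized implementation is cross-checked in the test
suite against an independent scalar reference written straight from the
published branching.

# Optical features

* NDVI $=(NIR-R)/(NIR+R)$, with zero-denominator pixels masked.
* Entropy texture: per pixel, the Shannon entropy (bits) of the gray-level
  histogram inside a centered square window. Defaults: 7×7 window, 32
  equal-width bins over the band's global valid range, red band, symmetric
  reflection padding. These parameters are not dictated by any reference —
  they are common texture-analysis defaults — and all are exposed in the
  configuration; the absolute entropy values therefore carry no claim of
  matching any particular published raster.
* Band PCA over valid pixels of the mean-centered bands, keeping the
  smallest leading set reaching 99% cumulative explained variance. Bands
  share reflectance units, so they are centered but not rescaled by default
  (a standardization flag exists). Component signs are fixed so the
  largest-magnitude loading is positive, making outputs reproducible across
  eigensolvers.

# Feature integration

The nine dB channels are PCA-reduced with a 98% variance target, the
optical bands with 99%; in both cases the number of kept components is
data-driven, not hard-coded to two. On heavily speckled simulated scenes
the dB-channel PCA keeps more than two components — speckle decorrelates
the channels — whereas spatially filtered real acquisitions concentrate
variance much faster; the integration modes by construction consume only
the first two components of each reduction.

Order of operations: dB conversion → PCA → min–max normalization →
stacking. PCA runs on dB values (configurable to linear intensities), and
normalization is the last step before stacking so that every stacked layer
lies in [0, 1]. Min–max normalization is per layer over valid pixels; a
robust variant uses the 1st/99th percentiles and clips. The constants are
recorded in the stack and can be reapplied to a prediction scene, avoiding
train/test leakage of normalization statistics. Masks are conservative: a
pixel invalid in any contributing layer is invalid in the stack.

Five integration modes are provided: `full` (sigma_pca1, sigma_pca2, RVI,
Ps, Pd, Ph, Pv + Opband_pca1, Opband_pca2, NDVI, H — 11 layers), the
reduced `sar7_opt2` and `sar5_opt4` (9 layers each), and the single-source
`sar_only` / `optical_only` comparison modes.

# Classifiers

**SVM.** RBF-kernel SVM (libsvm through e1071) on the normalized stack.
Hyperparameters are chosen by 5-fold cross-validated accuracy over the log
grid $C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{0.01, 0.1, 1, 10\}$, with
fold assignment drawn from the configured seed, so a refit with the same
seed and config is bit-identical. Training is per-pixel; field (plot) ids
are kept in the training set to allow grouped validation. Prediction
aligns layers to the training layers by name, so layer order is
immaterial.

**Complex Wishart.** The class model is the arithmetic mean covariance of
each class's training pixels (at least 9 per class); each pixel is assigned
to $\arg\min_m d_m(C)$ with the Wishart maximum-likelihood distance
$$d_m(C) = \ln\det\Sigma_m + \mathrm{tr}(\Sigma_m^{-1} C).$$
Ties break to the lowest class id; non-finite distances become nodata and
are counted. A diagonal loading $\varepsilon = 10^{-9}\cdot$mean(span) is
added only when a class mean is singular (e.g. a rank-1 point-target
class). The distance is invariant to a global radiometric scale applied to
both data and model, up to a constant common to all classes, so
classification commutes with rescaling — a tested property.

# Accuracy assessment

Confusion-matrix rows are the classified class and columns the reference
class (conventions vary; this one makes user's accuracy a row statistic and
producer's accuracy a column statistic). Overall accuracy is trace/total;
kappa uses the marginal chance agreement; per class, the one-vs-rest rates
are TP rate = PA, FN rate = 1−PA, FP rate = (row sum − diagonal)/(total −
column sum), TN rate = 1−FP rate, so TP+FN = 1 and TN+FP = 1 per class. A
class with an empty row or column gets an NA statistic and an explicit
flag instead of a propagated NaN. Percentages are printed to two decimals;
internal values keep full precision.

A published eight-class reference confusion matrix ships as a plain-CSV
fixture and is used to verify the statistics end to end (overall accuracy
85.2745%, kappa 0.8306 recompute exactly from the counts). Its column sums
match the published per-class testing-pixel counts for six of eight
classes; the source tables themselves disagree by 6 and 4 pixels for the
remaining two, and the fixture follows the matrix as printed, since only
those counts reproduce the published statistics.

# The scene simulator

`generateScene()` draws each pixel's covariance from its class's multi-look
complex Wishart model, $C = \frac1L \sum_{k=1}^L z_k z_k^H$ with $z_k \sim
\mathcal{CN}(0, \Sigma)$, so $E[C]=\Sigma$ and the per-channel intensity
coefficient of variation is $1/\sqrt L$ — the multilook speckle law, which
the tests verify. Optical reflectances are truncated Gaussians in [0, 1].
Labels form a rectangular field mosaic (exact area control, unambiguous
ground truth); training and testing pixels are disjoint *by field*, not
just by pixel, and SAR and optical draws are independent, reflecting the
independence of the two sensing mechanisms.

The default four-class configuration encodes the study's central structure:
classes A and B share identical optical statistics and identical
RVI/decomposition signatures, differing only in co-/cross-polarization
correlations that the nine-channel intensities resolve; classes C and D
share one volume-like covariance and differ only in green/blue reflectance
(their NDVI is identical by construction). Consequently SAR alone cannot
separate C/D, optical alone cannot separate A/B, the `sar7_opt2` mode
(no optical PCA layers) cannot separate C/D, and the `sar5_opt4` mode
(no dB-PCA layers) cannot separate A/B — so the full integration must
dominate every other mode, which is the testable form of the integration
claim. Defaults: 128×128 pixels, 8×8 fields, L = 4 looks, 25% of each
class's fields for training capped at 400 pixels per class, reflectance
noise sd 0.03.

What the simulator does **not** emulate: spatial speckle correlation (real
multilook pixels are correlated; filtered data even more so), texture
differences between classes (all classes share the optical noise level, so
the entropy layer is uninformative on simulated scenes — deliberately: it
must not help by accident), mixed pixels and field-boundary effects,
SAR–optical correlation, topography and incidence-angle trends. Passing
tests therefore demonstrate correctness of the algorithms and the claimed
statistical properties, not absolute accuracy figures on any satellite
scene — those depend on the acquisitions themselves.

# Numerical choices

* Hermitian validity tolerance $10^{-9}$ relative; diagonal round-off above
  $-10^{-12}$ clipped to zero at construction.
* Basis transform inverse validated to $10^{-10}$; round trips hold to
  $10^{-10}$ relative in tests.
* Power conservation enforced exactly; verified to $10^{-6}$ relative on
  every pixel of a 256×256 scene.
* dB floor −50 dB; PSD minor tests at $10^{-9}$ relative.
* PCA sign fixed by the largest-magnitude loading; zero-variance variables
  dropped with a warning.
* Wishart determinants and inverses computed per class on 3×3 complex
  matrices (a dedicated cofactor determinant, since base R's `det` is
  real-only); the per-pixel trace term is evaluated as a real linear form
  in the nine parameter planes, which vectorizes the classifier over the
  whole scene.
* Rasters are stored as band-sequential little-endian flat binary with a
  JSON header sidecar — bit-exact round trips for float64 and int32, plain
  text metadata.

# Problem sizes

The shipped tests and the acceptance script run on sizes chosen to give
stable statistics at interactive cost: 64×64 to 256×256 simulated scenes,
1000 random matrices for transform round trips, n = 2000 (L = 4) for
class-mean recovery, n = 10000 for the speckle-law and two-class Wishart
checks, and the 128×128 default scene for the five-mode integration
comparison. Monte-Carlo thresholds (5% recovery error, 0.95 toy accuracy,
10% speckle-law tolerance) sit several standard errors away from the
expected values at these sizes.

# Known limitations

* The entropy texture defaults are conventional, not calibrated; absolute
  entropy rasters are configuration-dependent.
* The Wishart classifier assumes the multilook complex Wishart
  distribution; strongly filtered data violate the nominal look count, and
  the equivalent number of looks should then be estimated upstream.
* No speckle filtering, calibration or co-registration is performed —
  inputs are assumed calibrated, filtered and on one grid, with the
  geometry recorded as metadata only.
* Per-pixel SVM training ignores within-field correlation; plot ids are
  carried so grouped cross-validation can be added without changing the
  data model.
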