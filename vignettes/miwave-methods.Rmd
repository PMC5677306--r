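---
title: "Methods: wavelet feature fusion and GMM-supervector reduction for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet feature fusion and GMM-supervector reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miwave)
```

## The signal model

Imagined hand movement suppresses the mu (~10 Hz) and beta (~20 Hz)
sensorimotor rhythms contralateral to the imagined hand — event-related
desynchronization (ERD). A two-class motor-imagery BCI therefore looks
for a left/right asymmetry of band-limited power on electrodes C3
(left hemisphere) and C4 (right hemisphere) in the seconds after the
task cue. The dominant ERD frequencies are subject-specific, so the
pipeline extracts power over a broad 6–30 Hz range rather than a
narrow subject-tuned band; frequencies below 6 Hz are excluded because
ocular and movement artifacts concentrate there.

## Preprocessing

Trials are stored as a `trials x channels x samples` array with a
cue-relative time axis (sample *i* at `t0 + (i-1)/fs` seconds).
Preprocessing is: channel selection (C3/C4 by default), a 4th-order
Butterworth band-pass 0.5–30 Hz applied forward–backward
(`signal::filtfilt`), and a crop to the half-open cue-relative window
[0.5, 6) s. Zero-phase filtering matters because a causal filter's
group delay would shift oscillatory energy across the crop boundary;
the half-open window convention makes sample counts unambiguous
(5.5 s at 128 Hz is always 704 samples). The crop window is
configuration, not algorithm: responsive imagery periods vary across
subjects, and no automatic window selection is attempted.

## CWT features (micro structure)

The continuous wavelet transform with an analytic Morlet mother
wavelet, ψ(t) = π^{-1/4} e^{iω₀t} e^{-t²/2}, is evaluated at one scale
per 1 Hz bin, at the bin centers 6.5, 7.5, …, 29.5 Hz (the simplest
faithful reading of "1 Hz bins over 6–30 Hz"; averaging several scales
per bin would add unstated complexity). The feature for channel *c*
and bin *k* is the natural log of the time-averaged power,
`log(mean_t |CWT|² + floor)`. Choices that the method description
leaves open, fixed here:

* **Morlet parameter** ω₀ ≈ 8.33, chosen so the wavelet's half-power
  bandwidth at 10 Hz is 2 Hz — neighbouring 1 Hz bins remain
  distinguishable while mu-band energy does not smear into the beta
  band. The empirical consequence, asserted by a test, is that a tone
  leaks less than 5 % of its power gain into bins ≥ 3 Hz away.
* **Log floor**: 10⁻¹² of the mean trial power (absolute 10⁻¹² for a
  silent trial), preventing −∞ on zero-power channels while being far
  below any physiological power.
* **Edge handling**: zero padding, wavelet support truncated at ±6
  envelope standard deviations (truncation error ~10⁻⁸ relative,
  verified against direct quadrature of the defining integral); the
  power average runs over all samples, since the 5.5 s crop is long
  relative to the wavelet support.

With 2 channels × 24 bins this block is 48-dimensional.

## DWT features (macro structure)

Each channel is decomposed with an orthogonal db4 discrete wavelet
transform using periodic extension — chosen because it keeps the
transform exactly orthogonal, so the energy-conservation identity
Σ sub-band energies = signal energy holds to machine precision and is
used as a test oracle. Detail level *j* nominally covers
(fs/2^{j+1}, fs/2^j] Hz; the level rule is 4 levels with
{D2 = beta, D3 = mu, D4 = theta} for fs ≤ 160 Hz and 5 levels with
{D3, D4, D5} above, which places ~8–16 Hz in the mu band for the
common 125/128 and 250 Hz EEG rates. Odd-length signals at any level
are edge-padded by one sample.

Eight statistics summarize each rhythm band: mean |c|, average power,
sample SD (n−1), the ratio of the band's mean |c| to the next-coarser
band's (approximation band for theta; denominator safeguarded by
+10⁻¹²), energy, Shannon entropy in bits of the normalized coefficient
energies (0·log 0 := 0), skewness m₃/m₂^{3/2}, and non-excess kurtosis
m₄/m₂². Entropy base, kurtosis convention, and the ratio's orientation
are not dictated by the method description; they are fixed as above and
degenerate inputs (all-zero bands) return 0 rather than erroring.
2 channels × 3 bands × 8 statistics = 48 features.

## Fusion and PCA

The combined vector is the CWT block followed by the DWT block
(96 features). Before PCA each feature is z-scored: log-powers and,
say, raw band energies live on incommensurate scales, and an
unstandardized PCA would be dominated by whichever statistic happens
to have the largest variance. (The projection is written S = FW
without centering in the original formulation; standardization is a
deliberate deviation-by-necessity.) K is the smallest component count
whose cumulative explained variance reaches 98 %. Determinism is
enforced by a fixed eigenvector sign convention (largest-magnitude
loading positive) and stable eigenvalue ordering. PCA is always fitted
on training rows only; the evaluation plumbing asserts this with a
canary test that perturbs held-out rows and checks the fitted models
are bit-identical.

## GMM-supervector training-set reduction

To reduce an N-row training set to a fraction `rate`, each class's
projected rows are modeled by a diagonal-covariance Gaussian mixture
with `m = max(1, round(rate × n_class))` components, fitted by EM, and
only the component mean vectors are kept as the new training rows
("supervectors"), stacked class 1 first. The reduction rate is applied
per class — proportional allocation — since the alternative (pooled)
reading is ambiguous. Mixture weights and variances are retained for
diagnostics but never passed to the classifier.

EM details (all unstated in the method description, fixed here):
seeded k-means initialization, 10 restarts keeping the best final
log-likelihood, relative log-likelihood tolerance 10⁻⁶, at most 300
iterations, and a variance floor of 10⁻⁶ × the per-feature data
variance applied after every M-step. The floor also makes the
degenerate rate-1-per-point fit well defined. Monotonicity of the
log-likelihood trace, weight normalization, and the stationarity
identity Σωᵢμᵢ = sample mean are asserted on every fixture; a
two-component recovery test and a cross-check against an independent
mixture implementation (mclust, model "VVI") guard the estimator
itself. Because the fit is stochastic, every fitting function takes an
explicit seed.

Why means-only reduction helps: component means are local averages, so
gross outliers — which an SVM would otherwise pick up as support
vectors — are absorbed rather than propagated. The package verifies
this property statistically: on two-Gaussian training sets with 5 %
gross outliers, supervector-trained SVMs are at least as accurate as
SVMs trained on same-size random subsamples, averaged over 20 seeds.

## RBF-SVM

The kernel is K(x, y) = exp(−‖x−y‖²/(2σ)) — σ enters the denominator
*linearly*, exactly as the method prints it; whether σ² was intended is
unknowable, so the printed form is implemented and the grid absorbs
the difference in scale. The dual problem is solved by libsvm through
`e1071::svm` with the documented mapping γ = 1/(2σ), termination
tolerance 10⁻⁶; kernel equality and the dual constraint Σαᵢyᵢ = 0 are
asserted bit-for-bit and the KKT margin conditions are checked on the
XOR fixture. Prediction uses the package's own kernel expansion over
the stored support vectors (f(x) = Σαᵢyᵢ K(sᵢ, x) + b, ties to
class 1), which also makes serialized models exactly reproducible.

Hyperparameter search is an exhaustive grid over C = 2⁻⁵, 2⁻³, …, 2¹⁵
and σ = 2⁻¹⁵, 2⁻¹³, …, 2³ (exponent step 2 — the conventional coarse
grid; the printed ranges give only the endpoints), scored by seeded
stratified 10-fold cross-validation; ties prefer the smallest C, then
the largest σ (the smoother model). The grid search is optional inside
the evaluation pipeline (`use_grid_search`); the default instead
trains at fixed C = 1 and the dimension heuristic σ = K/2 (equivalent
to libsvm's default γ = 1/K), because nesting a 110-point grid inside
every fold of a repeated cross-validation multiplies cost by three
orders of magnitude while the synthetic fixtures are insensitive to
the choice.

## Evaluation

Accuracy, Cohen's κ = (p₀ − p_e)/(1 − p_e) (κ := 0 when p_e = 1), and
mutual information MI = ½ log₂(1 + SNR) in bits, with
SNR = ((μ₁−μ₂)/2)² / ((σ₁²+σ₂²)/2) computed from the class-conditional
moments (unbiased variances) of the per-trial SVM decision values —
the BCI-competition style criterion applied to a single decision per
trial, since this pipeline produces no time-resolved output; a
"maximum over time" variant is therefore out of scope. Perfectly
separated decision values (zero within-class variance, nonzero gap)
return an `Inf` sentinel.

`repeated_cv` runs seeded stratified k-fold cross-validation
`repeats` times; PCA, mixture reduction, optional grid search and SVM
training all happen strictly inside each training fold. Accuracy is
aggregated over repeats × folds; κ and MI are computed per repeat on
the pooled held-out predictions (a single fold's 2×2 table is too
sparse for stable κ). `reduction_sweep` repeats the evaluation at each
reduction rate, with rate 1.0 as the no-reduction baseline (training
rows passed straight to the SVM).

## The synthetic generator

`simulate_trials` emulates exactly the features the pipeline measures:
per trial and channel, 1/f ("pink") background noise (spectrally
shaped white Gaussian noise, unit variance, scaled by `noise_sigma`)
plus mu (10 Hz) and beta (20 Hz) sinusoids with independent uniform
random phases per trial. For class 1 (left hand) the C4 amplitudes,
and for class 2 (right hand) the C3 amplitudes, are multiplied by the
attenuation factor ρ (`erd_factor`) — the contralateral ERD
convention. ρ = 1 makes the class distributions identical (null
data); smaller ρ strengthens the effect. ERD is sustained over the
whole trial rather than time-locked to an envelope, because every
extracted feature averages power over the crop; temporal ERD structure
would be invisible to the pipeline and is deliberately not modeled.

Default amplitudes (mu 6 µV, beta 3 µV over noise sd 2 µV at 128 Hz,
5.5 s trials starting 0.5 s post-cue) give mu/beta SNRs in the range
typical of sensorimotor recordings. What the generator does *not*
emulate — ocular/muscle artifacts, inter-trial nonstationarity,
volume-conduction correlations between channels, time-locked ERD
envelopes — bounds what passing tests show: they validate the
machinery and its statistical calibration, not performance on real
recordings.

## Study conditions used by the tests and the acceptance script

Chosen once as realistic desk-scale conditions and not revisited:

* **Null calibration**: ρ = 1, noise sd 2, 100 trials/class,
  10×10-fold CV. The check is |accuracy − 0.5| < 3 standard errors
  with the *binomial* SE over distinct trials (√(0.25/200) ≈ 0.035):
  repeats reuse the same trials, so the empirical SE over the 100
  correlated fold accuracies would understate the sampling variability
  of the estimate against the generative truth.
* **Effect detection**: ρ = 0.3, noise sd 1, 100 trials/class,
  10-fold CV, accuracy ≥ 0.90 expected (observed: at ceiling).
* **Reduction behaviour**: same strong-effect set, rates {0.3, 1.0},
  10 repeats — accuracy at 30 % within 3 percentage points of the
  baseline; and the outlier-cluster comparison at a 5 % rate over 20
  seeds described above.
* **Monotone effect**: mean CV accuracy non-increasing in
  ρ ∈ {0.2, 0.5, 0.8, 1.0} (5 seeds per ρ, one inversion within
  simulation noise allowed).

The acceptance script (`scripts/acceptance.R`) recomputes feature
widths, the 98 %-rule PCA dimensionality, full and 30 %-reduced CV
accuracy/κ/MI, null-data accuracy, and the supervector-vs-random
comparison from scratch at these sizes, deriving all randomness from
its `--seed` flag.

## Numerical and degenerate-input conventions

* Columnar trial/feature/model files print doubles with `%.17g`, so
  write → read round trips are bit-exact; EDF round trips are exact up
  to the 16-bit quantization of the stored physical range.
* All-zero DWT bands: entropy/skewness/kurtosis 0, safeguarded ratio.
* Constant features: an all-constant matrix is an error for PCA;
  individually constant features get unit scale (they carry no
  variance and project to 0).
* Dead mixture components (responsibility mass < 10⁻¹⁰) are frozen
  rather than renormalized away.
* Decision-value ties classify as class 1.
* k-means initialization failures on duplicate-heavy data fall back to
  seeded random row selection.

## Known limitations

EDF support is minimal (16-bit EDF, one record per trial, labels in a
plain-text sidecar since EDF has no per-trial label field); GDF files
are not read. The MI and κ reported here are per-trial criteria, not
the time-resolved competition variants. The pipeline is strictly
two-class; multi-class extension, CSP-style spatial filtering, and
supervised dimensionality reduction are out of scope.
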