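---
title: "Decoding individual finger movements from fNIRS hemodynamics: models and methods"
author: "HemoDecode authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding individual finger movements from fNIRS hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

HemoDecode implements an end-to-end pipeline for multi-class decoding of
individual finger-tapping from functional near-infrared spectroscopy
(fNIRS) recordings: a block-design simulator with ground truth, a
hemodynamic preprocessing chain, stimulus-locked event-average features,
and a ten-model classifier suite whose flagship is an inception-style
1-D convolutional network ("Hemo-Net"). This vignette records the
models, the assumptions behind them, the tunable parameters, and the
design decisions taken where the methodology was genuinely open.

# The measurement model

A continuous-wave fNIRS channel detects light intensity at two
wavelengths (760 and 850 nm here). Neural activity changes the local
concentrations of oxygenated and deoxygenated hemoglobin
($\Delta HbO$, $\Delta HbR$, in $\mu M$), which modulate absorption.
The optical density change is
$\Delta OD_\lambda(t) = -\log_{10} I_\lambda(t)/I_{ref}$, and the
modified Beer-Lambert law links it linearly to the concentration
changes:

$$\Delta OD_\lambda = d \cdot DPF_\lambda \left(
  \varepsilon_{\lambda,HbO}\,\Delta HbO +
  \varepsilon_{\lambda,HbR}\,\Delta HbR \right),$$

with $d$ the source-detector distance (3 cm default), $DPF_\lambda$ the
differential pathlength factor (6.0 at both wavelengths; a standard
adult-head value, since no subject-specific calibration is available)
and $\varepsilon$ the extinction coefficients (Gratzer/Cope compiled
spectra, `extinctionDefaults()`). With two wavelengths the 2x2 system
is solved exactly per sample (`mbll()`); total hemoglobin is
$\Delta HbT = \Delta HbO + \Delta HbR$. The forward map
(`mbllForward()`) is used by the simulator and by roundtrip tests,
which require inversion to better than $10^{-8}$ relative error.

When OD is referenced to the channel's temporal mean (the default for
real continuous-wave data, which has no absolute baseline), recovered
concentrations are likewise relative to the recording mean; the
simulator's tests reference OD to the known DC intensity instead, which
makes the roundtrip exact.

# The synthetic study

No real recordings ship with the package, so the simulator *defines*
the study conditions and every downstream claim is relative to them.

**Paradigm.** `buildParadigm()` reproduces the block design: a 30 s
baseline rest, then three sessions over the five fingers of the right
hand (thumb to little, fixed order by default, optionally shuffled per
seed), each trial 10 s rest followed by 10 s tapping, and a terminal
rest. The published total of 350 s does not decompose exactly into the
stated parts (30 + 3*5*20 = 330 s); the package adopts a 20 s terminal
rest so that the default paradigm reproduces the stated total. Sampling
is at 3.9063 Hz.

**Hemodynamics.** Each task block contributes a boxcar convolved with a
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
dispersions 1, undershoot ratio 1/6 - the standard convention, since
the protocol specifies none), scaled so its peak equals the
class-specific amplitude. $\Delta HbR$ is $-1/3$ of $\Delta HbO$, a
typical empirical ratio. Two sources of class information are injected,
both physiologically motivated:

* an *amplitude code*: per-finger peak amplitudes rising from 0.6 to
  1.4 $\mu M$ (thumb to little), multiplied by a shared channel
  sensitivity profile (0.5-1, strongest centrally). Keeping the spatial
  factor common to all fingers reflects optode-coupling heterogeneity
  while leaving the finger amplitude *ratios* identical in every
  channel - necessary because each training example is a single
  channel's time course with no channel identity attached;
* a *latency code*: per-finger shifts of the HRF peak delay, -0.5 s to
  +0.5 s around 6 s.

Trial-to-trial variability is a log-normal per-event gain
(sdlog 0.15 by default) and Gaussian onset-latency jitter (0.3 s).
Because trials are 20 s apart and a 10 s response lasts ~40 s,
consecutive responses overlap; with the fixed condition order this
produces a systematic, class-dependent distortion of the event
averages - deliberately retained, as the acquisition it emulates has
the same property. A consequence worth stating plainly: under the
fixed order, *block position* is a class-correlated signal in its own
right, strong enough that classifiers decode well above chance even
when the generator assigns identical responses to every finger. The
zero-effect control therefore randomizes the condition order within
each session (`shuffleConditions` in `runExperiment()`), which is
exactly the counterbalancing argument for randomized designs. Even
then, pooled splits leak: the HbO and HbR rows of the same run,
channel and condition are near mirror images, and a tree ensemble
recognizes a test row's mirror from training. The package's
chance-level check therefore additionally permutes labels
(`permuteLabels()`), the canonical control that destroys every
label-feature dependence; the structural confounds themselves are a
finding worth knowing about when interpreting pooled-split accuracies
(including published ones).

**Noise and artifacts.** Intensities are the forward Beer-Lambert
composition around a unit DC level, plus cardiac (1.1 Hz), respiratory
(0.3 Hz) and Mayer-wave (0.1 Hz) sinusoids with seeded random phases
per channel, and white noise. The cardiac component lies above the
Nyquist frequency (1.95 Hz) and aliases, as it does in the real
acquisition. `injectArtifacts()` adds seeded single-sample spikes and
sustained baseline shifts at configurable per-minute rates.

**Presets.** `syntheticPreset()` fixes four regimes used throughout:
`"high-snr"` (strong responses, quarter-scale physiological noise, low
trial variability - the parameter-recovery regime), `"mid-snr"`
(x0.6 amplitudes, full noise, higher variability - the model-ranking
regime), `"null"` (identical amplitude and latency for every finger:
labels carry no information) and `"artifacts"`. These were fixed when
the generator was designed, from signal-to-noise reasoning, and are not
tuned per experiment.

**What the simulator does not model:** photon transport and partial
volume effects, scalp/systemic physiology distinct from the cortical
signal, subject anatomy, serial correlations in the noise,
inter-session breaks. Passing tests therefore demonstrate that the
pipeline recovers what this generative model puts in - not performance
on real data, whose variability is richer.

# Preprocessing

`preprocessRecording()` applies, in fixed order: truncation to the
stimulus window (5 s pad, preserving the pre-stimulus epoch margin),
spike interpolation, coefficient-of-variation channel rejection,
optical density, Beer-Lambert inversion, band-pass filtering,
temporal-derivative distribution repair (TDDR), and normalization. The
order is part of the method; permuting it is an error.

Decisions worth recording:

* **Spike interpolation.** The rule is a robust z-score on amplitude
  ($|x-\tilde x| / (1.4826\,MAD) > 5$) with linear interpolation across
  flagged samples; the protocol names the operation but not the rule,
  so a conservative threshold was chosen and calibrated against seeded
  artifacts.
* **Channel rejection.** CV = 100 * sd/|mean| (population sd) on raw
  intensity per wavelength; a channel is rejected when CV strictly
  exceeds 7.5 % at either wavelength, so the boundary case is
  deterministic (retained).
* **Band-pass.** The filter specification names a low-pass of 0.01 Hz
  and a high-pass of 0.5 Hz, which is physically a *pass band* of
  0.01-0.5 Hz (drift removal below, cardiac removal above); it is
  implemented as an order-4 Butterworth high-pass cascaded with an
  order-4 low-pass, each applied forward-backward (zero phase, so event
  timing is preserved). The zero-phase plumbing uses odd-reflection
  padding with steady-state initial conditions so that a constant input
  yields numerically zero output; off-the-shelf `filtfilt` in the
  `signal` package leaves O(1) edge transients, which would violate
  that contract. Note the respiratory (0.3 Hz) and Mayer (0.1 Hz)
  components lie inside the pass band and survive - a realistic
  nuisance for the classifiers.
* **TDDR** follows the published algorithm exactly (verified to
  ~1e-15 against the author's reference implementation as distributed
  with MNE-Python): split at 0.5 Hz, Tukey-biweight iteratively
  reweighted robust mean of the temporal derivative (tuning 4.685,
  machine-precision convergence, at most 50 iterations), integration of
  the reweighted centered derivative, high-frequency part re-added.
  Because the robust *mean* of the derivative is subtracted, a global
  linear trend does not survive TDDR, and because the recording mean is
  re-added, a repaired baseline shift leaves the (unidentifiable) DC
  level contaminated - both properties of the published method, which
  is why artifact-energy claims are evaluated mean-free and TDDR runs
  after the band-pass. A further inherent property: the Tukey biweight
  assigns weights below one to *every* centered derivative, so the
  repair mildly shrinks whatever dominates the low-frequency
  derivative distribution. For an oscillation-dominated series
  (bounded, arcsine-like derivative distribution) the shrinkage is
  2-4 %; for Gaussian-noise- or sparse-response-dominated derivatives
  the expected weight drops to ~0.9 and the distortion grows
  correspondingly. The package's minimal-distortion checks therefore
  use oscillation-dominated artifact-free fixtures, the regime the
  method is intended for.
* **Normalization.** Each channel's chromophore series is z-scored and
  shifted to a baseline mean of 10 ("baseline-zero adjustment" with
  value 10 read as an additive offset - the only reading that leaves
  unit-variance features). The identity $\Delta HbT = \Delta HbO +
  \Delta HbR$ is enforced up to this point; z-scoring each series
  destroys the common scale (unit-variance $\Delta HbO$ and
  $\Delta HbR$ are near mirror images whose sum cancels), so
  $\Delta HbT$ is formed on the concentration scale *before*
  normalization and then z-scored independently, and the recording is
  flagged `normalized`.

# Features

Epochs run from 5 s before stimulus onset to 15 s after (task plus
post-task); at 3.9063 Hz this window contains 78.1 samples, and the
feature length is fixed at the published dimensionality of 77 samples,
starting at index $\lceil -5 f_s \rceil$ relative to onset
(`extractEpochs()`, `nPoints` overridable). Event averages are the
elementwise trial means per (channel, chromophore, condition); each
average is one training example $X_i \in R^{1\times 77}$ labeled with
its finger, per the single-channel classification framing
$P(Y = y_i | X = x_i) = f(x_i, w)$. The experiment driver uses the HbO and HbR
averages as feature rows (the feature set the study names; HbT is
computed and can be included via an argument); rest is not a class by
default (the output layers are five-way), but the label set admits it.

Standard scaling is column-wise with statistics learned on the training
split only. The default split is pooled and stratified 80/20, seeded;
a by-run strategy (whole simulated runs held out) is available to probe
leakage, since the published split protocol is unstated.

# Classifiers

All ten models share a fit/predict contract (`fitDecoder()`,
`predict()`, `predictProb()`); probabilities are nonnegative and sum
to one per sample in every family.

**LDA** builds the within- and between-class scatter matrices
$S_W = \sum_k \sum_{x \in k} (x-\mu_k)(x-\mu_k)^T$ and
$S_B = \sum_k n_k (\mu_k-\mu)(\mu_k-\mu)^T$ and solves
$S_W^{-1} S_B v = \lambda v$ for the discriminant projections;
classification uses pooled-covariance Gaussian scores. Solvers `svd`,
`lsqr`, `eigen` differ only in numerics; shrinkage `auto` is
Ledoit-Wolf. **QDA** fits one Gaussian per class with covariance
regularized as $(1-r)\Sigma_k + rI$, $r \in \{0, 0.1, 0.5, 1\}$, and
applies Bayes' rule. **MNLR** uses the reference-class softmax with
$K-1$ weight vectors exactly as the defining equation (not the
symmetric parameterization), penalized L2 (L-BFGS) or L1 (FISTA),
intercept unpenalized, C the inverse regularization strength.
**RF** and **XGBoost** delegate to `ranger` and `xgboost` with the
published grids; 5-fold stratified, seeded, exhaustive grid search with
first-in-grid tie breaking is available for every classical family
(`gridSearchCV()`, grids in `decoderGrids()`).

**Deep models** are built on the package's own reverse-mode engine
(dense, 1-D convolution with same padding, batch normalization,
max-pooling, LSTM/bidirectional LSTM, parallel concatenation, residual
connections; convolution and pooling kernels in C++). Gradients are
hand-derived and finite-difference checked in the test suite. The five
architectures follow their published layer plans: a dense baseline
(1024/512/128/64 with batch norm and ReLU), a two-layer LSTM(50) stack,
a three-layer bidirectional LSTM (50/50/20), a CNN+LSTM hybrid with two
parallel heads, and Hemo-Net: three inception blocks (bottleneck 32,
kernel lengths 10/20/40, max-pool path, 4x32 channels out, batch norm +
ReLU), a residual projection from the input onto the block-stack
output, global average pooling, and a five-way softmax. Kernel lengths
printed as two-dimensional in the source description are read as 1-D
lengths 10/20/40, consistent with the inception-time design the
architecture cites; bottleneck and filter widths of 32 are that
design's defaults, as the description is silent.

The published LSTM equations wrap the cell-state update and the output
in extra sigmoids; that differs from the canonical LSTM and is almost
surely a typographical artifact. `lstmStep()` implements the canonical
cell by default and the literal printed form behind `form = "literal"`;
the stacked networks use the canonical cell.

**Training** (`trainDeep()`): batch size 32, Adam, L2 weight penalty
(1e-4) on weight matrices only, cyclic triangular learning rate in
[1e-5, 1e-2] (half-cycle two epochs) for the dense baseline and
Hemo-Net, fixed 1e-4 for the recurrent and hybrid models, early
stopping on validation loss with best-weight restoration. Optimizer
identity, epoch budget and cycle period are unstated in the protocol;
Adam with these settings is the field's default. Training is
deterministic under the plan seed (R's RNG drives initialization and
shuffling; batch-norm statistics are exact).

# Evaluation

`confusionCounts()` and `evaluationReport()` implement accuracy as the
indicator mean, per-class precision $T_p/(T_p+F_p)$ and recall
$T_p/(T_p+F_n)$ from the confusion matrix, F1 as their harmonic mean,
macro and support-weighted averages. Division by zero (a class never
predicted) yields 0 with an explicit flag - a convention needed for
degenerate runs. `reportTable()` mirrors the per-class /
accuracy / macro / weighted report layout. `runExperiment()` wires the
whole chain end to end, fully seeded, and writes features, reports and
confusion matrices as CSV.

# Problem sizes and what the checks show

The package's acceptance-style tests run on scaled-down instances
chosen for convergence-per-compute rather than maximal realism: the
chance-level control uses 7 simulated runs x 24 channels (2,520
examples, >= 500 held out; every model must stay within [0.14, 0.26]);
parameter recovery uses the high-SNR preset with 2 runs x 12 channels
and requires Hemo-Net and RF to exceed 0.9 held-out accuracy; the
qualitative ranking (inception net >= random forest >= multinomial
regression, the ordering reported on real data) is the median over
five seeds of the mid-SNR preset at 3 runs x 16 channels with a
12-epoch budget. Deep-model epoch budgets in these checks are small
because the synthetic classes are far easier than real data; the
defaults (`defaultPlan()`) allow up to 500 epochs with patience 20.

Known limitations: the decoding results quantify recovery of the
generator's class codes, not real-data performance; event averaging
with few trials leaves physiological oscillations in the features;
linear models are structurally disadvantaged when chromophores are
pooled (each class is a union of HbO-, HbR- and HbT-shaped clusters -
one reason discriminant models trail the nonlinear models here, as
they do on the real task); and single-precision-free pure-R training
is compute-bound, which caps the problem sizes the test suite can
afford.
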