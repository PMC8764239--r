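---
title: "tinnconn methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tinnconn methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science and the engineering decisions behind
`tinnconn`: what the synthetic generator emulates and what it does not,
the exact estimator conventions, the classifier protocol, and the
numerical choices a maintainer would want written down. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The analysis in one paragraph

Resting-state EEG over the left and right auditory cortex (12 channels of
the 10–20 montage) is notch- and band-pass-filtered (50 Hz; 0.5–90 Hz),
baseline-corrected, re-referenced, and cut into 10-s epochs. Each epoch is
summarized by one connectivity matrix per measure — phase-locking value
(PLV), phase lag index (PLI), Pearson correlation (PCC), transfer entropy
(TE) — or by time–frequency comparison features (per-band rhythm mean/SD,
Welch band power). Flattened matrices (66 values for an undirected measure
on 12 channels) feed cross-validated classifiers of the four groups
(healthy, bilateral, left-sided, right-sided tinnitus). Group-level
statistics compare matrix entries across groups (Welch *t* difference
maps), compare classifiers (one-way ANOVA on repeated accuracies;
Kruskal–Wallis on times), and cluster channels by classical MDS of the
connectivity matrix.

## 2. Estimator conventions

**PLV.** Implemented as \(|\frac1T \sum_t e^{j\Delta\varphi_t}|\), the
magnitude of the mean phasor of the phase difference. A literal average of
(unwrapped) phase differences is unbounded and cannot satisfy the stated
range \([0,1]\); the mean-phasor form is the standard definition and the
only reading consistent with that range, so it is what the package
computes. Phases come from the angle of the analytic signal (FFT-based
Hilbert transform) of the band-filtered epoch — the most common
convention when the extraction method is otherwise unspecified.

**PLI.** \(|\frac1T \sum_t \operatorname{sgn} \operatorname{Im}(Z_i
Z_k^*)|\). The absolute value makes the index independent of the arbitrary
channel ordering (without it the sign flips when the pair is swapped) and
gives the conventional \([0,1]\) range. `sgn(0) = 0`, so exactly zero-lag
samples contribute nothing: PLI is insensitive to volume conduction by
construction.

**PCC.** The usual normalized covariance; a zero-variance input raises an
input error rather than silently returning 0.

**TE.** Histogram plug-in estimator in bits: both signals are discretized
into `bins` (default 4) equal-width amplitude bins over their own ranges,
the joint histogram of \((x_i^t, x_k^t, x_k^{t+\ell})\) (default lag
\(\ell = 1\)) is formed, and
\(\sum p \log_2 [p(x_k'\,|\,x_i,x_k)/p(x_k'\,|\,x_k)]\) is evaluated with
the \(0\log 0 = 0\) convention. A leading \(1/(T-1)\) factor sometimes
written in front of this sum is redundant (the probabilities already
normalize the average) and would break the exact worked example the test
suite pins: an i.i.d. equiprobable binary source copied to the target with
lag 1 carries exactly 1 bit. Plug-in TE is biased upward by roughly
(cells)/(2T ln 2); the independence tests use tolerances above that bias.

**Broadband by default.** Connectivity is computed on the full
preprocessed band (0.5–90 Hz), giving one matrix — hence one 66-length
vector — per epoch, which is what the CNN input shape (1 × 66) requires.
Per-band computation is available through the `band` argument.

**TE feature layout.** Whether TE should enter the classifiers as 132
directed values or 66 symmetrized ones is ambiguous; both layouts are
implemented (`te_layout = "directed"` is the default; `"symmetric"`
averages the two directions). Layout names are written into feature-table
headers so downstream consumers can never misalign — silent misordering
being the dominant real-world bug in this kind of pipeline.

## 3. The synthetic generator

The generator is a stated world, not a fit to data. Each channel is a sum
of six band-limited oscillators (one per rhythm) plus Gaussian noise:

\[ x_c(t) = \sum_b a_b \sin\bigl(2\pi f_b t + w_{c,b}(t) + \theta_{c,b}\bigr)
           + n_c(t), \]

with \(f_b\) the band-center frequencies and \(a_b\) the template's
`band_profile` (default alpha-dominant, as in eyes-closed rest:
δ 6, θ 8, α 20, β 5, low-γ 2.5, high-γ 1.5 µV). Three independent knobs
map one-to-one onto the estimator families:

* **`phase_coupling`** κ(i,j) — the cross-channel correlation of the
  phase-deviation processes \(w_{c,b}\). Deviations are mean-reverting
  (Ornstein–Uhlenbeck) with stationary variance \(s^2 = 4\) rad² and
  correlation time 0.1 s, smoothed with a 0.1-s Hann kernel so the
  instantaneous frequency stays bounded (a raw OU path is nowhere
  differentiable and defeats Hilbert phase estimation). The stationary
  phase-difference variance of a pair is \(2 s^2 (1-\kappa)\), so expected
  PLV rises smoothly from \(\approx e^{-4} \approx 0.02\) at κ = 0 to
  exactly 1 at κ = 1 (identical deviation processes). The exact smoothed
  variance is restored analytically, not empirically, so the map from κ to
  PLV does not depend on the realization.
* **`linear_mixing`** — the correlation matrix of the additive Gaussian
  noise (`noise_sd`, default 5 µV), read out by PCC.
* **`directed_gain`** g(i→k) — a one-sample-lag linear influence
  \(x_k(t) \mathrel{+}= g\, x_i(t-1)\) applied to the pre-influence
  signals, read out by TE (the white-noise component makes the lagged
  dependence detectable at any sampling rate).

Correlation matrices supplied by templates are repaired to positive
semi-definite by eigenvalue clamping (preserving the unit diagonal), so a
singular κ = 1 block is legal.

**Class templates** (`build_class_templates("default")`) encode the
qualitative cluster patterns the four groups show: healthy — three
interhemispheric couplings between homologous channels (FT7–FT8, T7–T8,
CP5–CP6); bilateral — one interhemispheric coupling plus a
right-hemisphere cluster; left-sided — two right-hemisphere clusters and
one left; right-sided — two mostly-left-hemisphere clusters (one
including a right channel). Coupling strength 0.85, mixing 0.7, directed
gain 0.6 on class-specific edges; the values are stated once here and are
not tuned. The `"lft_hft"` scenario splits the left-sided class into low-
and high-frequency-tinnitus variants differing **only** in
`band_profile` (LFT: boosted δ/θ, suppressed high-γ; HFT: boosted γ), so
only the rhythm/PSD features — not connectivity — can separate them.
`"null"` returns four identical templates for type-I-error testing.

**What a green test establishes — and what it does not.** The synthetic
recordings have controllable connectivity, realistic amplitudes and band
structure, and no artifacts. They do **not** have: 1/f background spectra,
ocular/cardiac artifacts, volume-conduction mixing from a head model,
nonstationarity, or inter-subject variability beyond the random phase
offsets. Classification accuracies on this world therefore validate the
*pipeline* (features preserve the generating structure; the protocol has
no leakage; the ranking connectivity > rhythm/PSD is reproducible), not
any clinical claim. The headline accuracies reported for real recordings
are not reproducible from this package and are not asserted anywhere in
its tests.

**Scale.** The default configuration mirrors the real protocol
(1,000 Hz, ~10-min recordings, 10-s epochs, ≈2,300–2,500 epochs across
42 recordings; the rejected-epoch count that produced exactly 2,312 valid
segments in the original protocol is unspecified, so epoch counts are
configurable rather than fixed). Tests and the acceptance suite run a
reduced but structurally identical world — 250 Hz (the lowest rate whose
Nyquist comfortably clears the 90-Hz band edge), 400 epochs — purely for
CPU budget; both are plain config values.

## 4. Preprocessing choices

* **Filters.** No IIR filter-design library is assumed: all filters are
  FFT-domain multiplications with a real, non-negative response —
  *exactly* zero-phase, exactly unit in-band gain, idempotent in the
  passband. Transitions are raised-cosine over a third of an octave
  (band-pass) or 1 Hz (notch, stop band ±2 Hz), so attenuation one octave
  outside the passband is complete. The trade-off versus forward–backward
  IIR filtering is circular boundary handling: a strong discontinuity
  between a recording's first and last samples leaks locally at the two
  edges. For 10-s-plus segments of zero-mean EEG this is negligible, and
  the response contracts (in-band within 1 dB, stop band ≥ 20 dB) are
  pinned by tests.
* **Re-referencing.** The reference electrode standardization technique
  (REST) requires a leadfield/head model that cannot be bundled; the
  default is the common average reference after per-channel baseline
  correction, which preserves the relative connectivity structure the
  features consume. `"REST"` is reserved as a named extension point and
  errors if requested.
* **Artifact handling.** Bad-lead interpolation and "abnormal epoch"
  rejection are acquisition-specific; the package exposes an identity
  interpolation hook and a default amplitude-threshold rejection
  (|sample| > 100 µV drops the epoch; `Inf` disables). ICA ocular/ECG
  removal is out of scope — the synthetic world is artifact-free.
* **Epoching.** Non-overlapping 10-s windows, trailing remainder
  discarded. Stage order is fixed: interpolation hook → notch → band-pass
  → baseline + re-reference → channel selection → segmentation →
  rejection.

## 5. Classifier protocol

* **Linear SVM** — L2-regularized hinge loss solved by dual coordinate
  descent (compiled; the liblinear algorithm), one-vs-one voting for
  multiclass, C = 1. Evaluated under leave-one-out CV and stratified
  10-fold CV; accuracy is the mean over folds of fold validation
  accuracy.
* **MLP** — hidden layers 200/200 (relu), Adam (lr 10⁻³), L2 penalty
  α = 10⁻⁷, at most 380 epochs over minibatches of ≤ 200 with early
  stopping when the training loss stalls (10⁻⁴ for 10 epochs) — α is read
  as the L2 penalty, the convention of the library the protocol names.
  Evaluated on a single stratified split per repeat at the protocol's
  ratio 1,622/2,312 ≈ 70 % train.
* **CNN-LSTM** — conv1d(16, k3, same, relu) → conv1d(32, k3, same, relu)
  → LSTM(32, sequences) → LSTM(32, final state) → batch norm → flatten
  (width 32) → dense 16 → dropout 0.2 → dense 8 → dropout 0.2 → softmax;
  Adam, cross-entropy. The printed conv output widths in the source
  protocol are not self-consistent for a length-66 input with kernel 3
  and stride 1; "same" padding with the LSTM consuming the 66-step
  sequence and returning its final 32-unit state is the only reading that
  reproduces the stated flatten width of 32, and is what is implemented.
  Every layer's backward pass is verified against numerical
  differentiation in the test suite. The CV split protocol follows the
  MLP. The model is the heaviest of the four and intentionally not part
  of the default pipeline configuration.
* **Standardization** (zero mean/unit variance per feature) is fit on
  training folds only, for SVM and MLP alike; a label-canary test pins
  the absence of leakage.
* **Repeats.** Each classifier × feature combination is repeated (default
  10×) with seed-derived fresh splits; per-repeat accuracies feed the
  ANOVA. Wall-clock times are recorded and compared with Kruskal–Wallis
  but never asserted against reference values — they are
  hardware-dependent.

## 6. Group statistics

* **Difference maps.** Per channel pair, a two-sided Welch two-sample *t*
  test across epochs, α = 0.05, **no multiple-comparison correction by
  default** — the analysis this mirrors reports per-cell p < 0.05;
  Benjamini–Hochberg is available via `p_adjust = "BH"`. Constant entries
  (e.g. the diagonal) give p = 1 with a warning rather than an error. The
  "common difference" mask is the element-wise AND over the three
  tinnitus-vs-healthy maps.
* **MDS clustering.** Dissimilarity `d = 1 − (v − min)/(max − min)` over
  off-diagonal entries (high connectivity → low distance; measure-
  agnostic; directed matrices symmetrized by averaging directions), then
  classical MDS (`cmdscale`) and single-linkage agglomeration cut at
  `threshold_fraction` × the maximum pairwise embedded distance
  (default 0.5). Singleton clusters are reported as unclustered (`NA`);
  with all-equal distances nothing merges below the cut, so every channel
  is unclustered — the documented, deterministic tie rule. Whether to
  embed the group-mean matrix or per-epoch matrices was open; the
  group-mean is the default (it is the object the cluster narrative
  describes), and per-epoch embedding is a one-line `lapply`.
* **ANOVA / Kruskal–Wallis.** One-way fixed-effects F computed in closed
  form so degenerate inputs can be *flagged* rather than raised: zero
  variance everywhere → F = 0, p = 1; separated means with zero
  within-group variance → F = ∞, p = 0. Kruskal–Wallis wraps the standard
  rank test.

## 7. Reproducibility and I/O

Every stochastic function takes an explicit seed and uses it through an
isolated RNG scope, so identical `(config, seed)` reproduce outputs bit
for bit; the pipeline writes a manifest (config snapshot, package version,
per-stage timings) before results, and result CSVs are byte-stable under
rerun except for the wall-clock-time column, which is hardware-dependent
by nature. Recordings are exchanged as delimited text with a JSON sidecar
(primary, text-only) or as minimal 16-bit EDF (one record per second,
uniform rate — the subset the package writes; round-trip accuracy is the
16-bit quantization step). Ground truth is a JSON sidecar.

## 8. Known limitations

* The synthetic world omits 1/f spectra, artifacts and head-model mixing
  (see §3); PLI on synthetic data is weaker than PLV by construction when
  couplings are near zero-lag, which mirrors its poor ranking in practice
  but is not evidence about real volume conduction.
* Plug-in TE is biased upward at small T; bin count is exposed and the
  bias bound documented rather than corrected (no surrogate correction).
* REST re-referencing and spherical-spline interpolation are named
  extension points, not implementations.
* The CNN-LSTM is a faithful but compact reimplementation; it is slower
  per epoch than a GPU framework and intended for protocol completeness,
  not throughput.
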