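---
title: "Decoding single-trial auditory evoked potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-trial auditory evoked potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aepdecode)
```

## The problem

A passively presented auditory probe (a 0.1 s chirp) evokes a stereotyped
cortical response — a negative deflection near 100 ms (N100) and a positive
one near 300 ms (P300). Detecting that response on *single* trials from dry
multichannel EEG recorded in a vehicle or simulator, against vibration,
muscle, blink and mains artifacts, is the core task this package addresses.
The decoder distinguishes 0.5 s epochs that follow a chirp onset from 0.5 s
epochs extracted from the silences between chirps — a balanced two-class
problem whose chance level is 50%.

Because real operational recordings of this kind are rarely shareable, the
package ships a synthetic session generator with complete ground truth
(mixing matrix, sources, per-trial evoked waveforms, planted bad channels).
Every pipeline stage is tested against that ground truth.

## The synthetic session generator

`simulate_recording()` builds a forward-mixed recording
`X = A S` (channels x samples = mixing x sources, in microvolts):

* **Evoked source.** An impulse train at chirp onsets convolved with the
  two-wave template `canonical_erp()`:
  `w(t) = a_e h(t; 0.05) + a_l h(t; 0.15)` with
  `h(t; tau) = t^2 exp(-t / tau)` normalised to unit peak, `a_e < 0`,
  `a_l > 0`. The continuous argmax of `h` is `2 tau`, so the waves peak at
  100 and 300 ms. Per-trial variability: multiplicative amplitude jitter
  (SD 20%) and Gaussian latency jitter (SD 10 ms) — values unreported in
  the ERP literature vary by paradigm; these are mid-range and configurable.
* **Background.** One 1/f ("pink") source per channel plus an 8–12 Hz
  alpha source, all with spatially smooth random topographies
  (volume conduction is emulated by smoothing across the electrode index —
  no biophysical head model).
* **Artifacts.** Frontal blink transients (raised-cosine bumps, ~0.3 s),
  20–80 Hz muscle bursts, a 0.5–3 Hz vibration component, and an optional
  mains sinusoid. Two severity regimes: `"off"` (bench-quiet: 18 uV blinks
  at 0.05/s, faint muscle, 2 uV vibration) and `"on"` (operational: 120 uV
  blinks at 0.25/s, dense 35 uV muscle bursts, 60 uV vibration).
* **Scale.** The background RMS at the channel where the ERP topography is
  strongest is fixed (default 7 uV, typical of band-passed EEG); `erp_snr`
  is the ratio of ERP RMS to that background RMS at the same channel. The
  default 0.25 puts the single-trial ERP peak near 5 uV. `erp_snr` scales
  the ERP source only, so doubling it exactly doubles the ERP contribution
  on every channel.
* **Planted bad channels** overwrite mixed data: a flatline (constant), a
  high-amplitude channel (repeated ±350 uV excursions), or a decorrelated
  channel (independent pink noise). Without plants,
  `X == A S` holds exactly, which the tests exploit.

The stimulus schedule draws inter-chirp silences uniformly from
0.6–2.5 s (the stated range is read as the support of a uniform
distribution; timing is resolved on the sample grid so the bounds are
exact in sample units). Silent epochs are packed into the lead-in and
inter-chirp regions by capacity-weighted slot sampling; they overlap
neither chirp epochs nor each other by construction. The mains amplitude
defaults to zero: a spatially uneven line source would make the
line-noise rejection rule flag healthy channels on otherwise clean
sessions, which would misrepresent what a clean session is.

What the generator does **not** emulate: real electrode geometry and
leadfields, non-stationary artifact statistics (e.g. artifact regimes that
drift within a session), attention-dependent ERP attenuation, or
electrode-popping transients. Tests passing on this generator therefore
demonstrate the pipeline's mechanics — recovery of planted structure —
not performance on any particular real recording.

## Preprocessing

**Band-pass filter.** A linear-phase windowed-sinc (Hamming) band-pass,
2–30 Hz, order 496 (497 taps, group delay 248 samples at 300 Hz), applied
forward–backward so the net phase is zero and the effective magnitude
response is squared. Edges are reflection-padded. Because the taps are
symmetric, the forward–backward pass is computed as a single FFT
convolution with the tap autocorrelation. Zero-phase filtering is the
right choice for offline analysis; it is also the one stage that is
non-causal, so "training" samples within ~1.7 s of the train/test boundary
depend weakly on early test samples. The fitted parameters are insensitive
to this (verified to < 1% in the tests), but bitwise independence from the
test span is impossible with any zero-phase front end.

**Bad channels.** Four rules, fitted on the training span only and applied
to both spans: amplitude above 100 uV; a flatline longer than 5 s; median
windowed correlation below 0.8 between a channel and its ridge-regression
prediction from all other channels (1 s windows, penalty 1e-3 times the
mean channel variance — with `T = (S + lambda I)^{-1}` the prediction for
every channel comes from one matrix inverse per window via
`x_i - (T x)_i / T_ii`); and a line-noise score (RMS above 45 Hz over RMS
below 45 Hz) more than 4 SD above the channel-population mean. Note the z
rule needs a realistic montage to be able to fire: a lone outlier among
`n` channels has `z <= (n-1)/sqrt(n)`. Flagged channels are removed, not
interpolated.

**Artifact subspace reconstruction.** Calibration windows are chosen by
robust z-scores of windowed RMS (windows kept when >= 93.75% of channels
lie within (-3.5, 5.5)); at least 30 s must survive. The calibration
statistic is the element-wise median of per-window covariances — which
need not be positive definite, so it is projected onto the PSD cone with
an eigenvalue floor of 1e-4 of the leading eigenvalue before taking the
principal square root `M`. Per-direction thresholds are
`mean + 5 SD` of the calibration RMS projected on the calibration
eigenvectors (cutoff 5 is the cited toolbox's historical default; later
versions use 20 — the knob is exposed). Processing slides 0.5 s windows
(0.25 s hop, raised-cosine blending): directions of the window covariance
whose RMS exceeds the mapped calibration threshold are zeroed and the
window is reconstructed with
`R = M %*% pinv(keep * (V' M)) %*% t(V)`, the identity when nothing is
flagged. The mapped threshold carries a finite-sample correction
`1 + sqrt(n_channels / window_samples)`: leading sample eigenvalues of a
short window are inflated by direction selection (the Marchenko–Pastur
edge), and without the correction the top direction of every window would
be trimmed even on data statistically identical to the calibration.

## ICA with weight transfer

`fit_extended_infomax()` is natural-gradient infomax with the extended
sub/super-Gaussian switch: after sphering to unit covariance, random
256-sample blocks drive
`W <- W + eta [I - K tanh(u) u' - u u'] W`, with `K = ±1` per component
from the running kurtosis-sign estimate, initial
`eta = 0.001 / log(n_channels)`, annealed by 0.98 whenever the update
direction turns by more than 60 degrees, divergence handled by a cold
restart at half the rate. The stop criterion is a summed squared weight
change below 1e-7 — chosen so that on a 3-source benchmark the recovered
global matrix is a scaled permutation to better than 0.98 row dominance;
a looser 1e-6 stops visibly short of separation. Components are ordered
by descending mean projected variance. Weights are fitted on the training
span and transferred unchanged to the test span; projection is strictly
linear (no centering — input is band-passed and effectively zero-mean).

Component selection replaces visual inspection: each component's
chirp-locked average (0–500 ms) is correlated with the canonical
two-wave template, and the top `k = 2` components with `|r| >= 0.4` are
kept (two components per condition is also what the visual procedure
settled on). Selection uses absolute correlation throughout — ICA's sign
and scale indeterminacy never matters. If nothing reaches the threshold
the pipeline falls back to all components with a warning.

## The Kalman ERP estimator

Each wave is a third-order linear system: a cascade of three first-order
stages with discrete pole `a = exp(-1/(fs tau))`, `tau = peak/2`. The
readout weights the cascade states as `(0, a, 2a^2)` (scaled to unit
peak), which makes the noiseless impulse response exactly the sampled
`n^2 a^n` — whose discrete argmax at 300 Hz is exactly sample 30 (100 ms)
for `tau = 0.05` and sample 90 (300 ms) for `tau = 0.15`. A final-state
readout of the same cascade would peak one to three samples early; the
state-weighted readout is what makes the peak latencies land on the
nominal values. The two cascades are stacked block-diagonally (6 states);
the onset input enters each cascade's first state with signed gains
(negative early = N100 negativity, positive late).

Noise: `Q = q I` (white state noise), scalar measurement noise
`R = 0.001 q` — the filter is scale-free in `q`, only the ratio shapes
the gain sequence, and the small ratio means the filter trusts the
measurements. `P0 = 10 I` for a fast burn-in. The onset impulse is applied
at *every* trial onset, chirp and silent alike: at test time labels are
unknown, so discrimination must come from the measurements, not from the
input schedule. The filter is causal (no smoothing pass); once the error
covariance reaches its steady state (checked against the Riccati fixed
point to 1e-8 relative Frobenius error) the constant gain is reused. In
the prescribed state coordinates the steady-state covariance has
magnitude ~1e7 (the Jordan cascade amplifies state noise), so covariance
comparisons are meaningful only in relative terms.

Pre-ICA mode filters every retained channel independently with the same
model; post-ICA mode filters only the selected component activations.

## Classification and inference

**LSPC.** The class posterior is a Gaussian-kernel expansion over training
points fitted per class by ridge least squares in closed form:
`theta_y = (G'G/n + lambda I)^{-1} G' b_y / n`. Prediction clips negative
scores at zero and normalises; an all-nonpositive score vector yields a
uniform posterior; exact ties resolve to "silent" (the conservative
choice — a missed chirp is preferable to a false alarm; configurable by
relabelling). Features are the raw 150 samples (0–500 ms at 300 Hz) of
every retained trace, concatenated.

**Model selection.** Randomised stratified 10-fold cross-validation on the
training trials over `sigma = median pairwise distance x {0.1, 0.3, 1, 3,
10}` and `lambda = {1e-3, 1e-2, 1e-1, 1}`, selecting by mean validation
accuracy, ties toward smaller `sigma` then larger `lambda`. With 150 + 150
training trials each fold complement holds 135 + 135. The
selection-evaluation cycle is repeated (default 100 times) with fresh fold
randomisation against the fixed test set; the permutation test repeats the
whole cycle on label-shuffled training data and uses the add-one p-value
`(1 + #{null >= observed}) / (n_perm + 1)`. Paired condition contrasts use
the two-sided Wilcoxon signed-rank test: exact sign enumeration up to
n = 25 without ties, normal approximation with continuity correction
beyond, zero differences dropped and counted.

**Metrics.** FPR = silent trials called chirp, FNR = chirp trials called
silent; on balanced sets `accuracy = 1 - (FPR + FNR)/2` exactly.
`d' = z(hit) - z(fa)` with rates clipped to `[1/(2N), 1 - 1/(2N)]`.

## Protocol and reproducibility

`run_condition()` follows the chronological protocol: filter; split each
label's earliest 75% of trials into training (200 + 200 trials give
150/150 train and 50/50 test); detect bad channels on the training span
and drop them everywhere; calibrate ASR on clean training segments and
apply it with fixed parameters; fit ICA weights on the training span and
transfer; Kalman-filter with all onsets; epoch, select, evaluate, and
permutation-test per variant (`pre_ica`, `ica`, `pre_ica_kalman`,
`ica_kalman`). All randomness flows from one master seed through named
substreams, so reports are bit-reproducible; a failing variant is reported
with its stage error while the others complete.

## Problem sizes used by the test suite

The property checks run at a reduced desk scale chosen once: 16-channel,
120-chirp (~200 s) sessions, 25 evaluation repeats, ICA capped at 150
passes inside pipeline runs, 100 permutation shuffles for the high-SNR
run (`erp_snr = 2`, artifacts off), and ten seeds for the artifact-on
ordering check (ICA + Kalman vs. the pre-ICA baseline). Source-separation
quality (Amari index < 0.05), ASR burst attenuation (>= 80% with < 10%
clean-data distortion) and exact recovery of planted bad channels over 20
seeds are checked at similarly small sizes. These sizes are large enough
for every qualitative property to be stable across seeds while keeping
the suite fast.

## Known limitations

* No EDF I/O: recordings live as matrices; events and reports round-trip
  through TSV/JSON.
* The robust channel prediction uses windowed ridge regression with a
  median over windows, not a RANSAC consensus; the two agree on
  everything the four rules are asked to catch here.
* No dipole modelling, no probability calibration beyond LSPC's clipped
  normalisation, no online (causal front-end) mode for the full pipeline.
* The synthetic artifact regimes are stationary within a session, so the
  documented real-world failure mode of ICA + Kalman under abruptly
  non-stationary artifacts is out of the generator's reach.
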