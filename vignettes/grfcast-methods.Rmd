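---
title: "Methods: predicting normal GRF waveforms from sacral accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting normal GRF waveforms from sacral accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

During running, the normal ground reaction force (GRF) — the force component
perpendicular to the (possibly inclined) running surface, expressed in
bodyweights (BW) — is the quantity from which most kinetic variables of
interest are derived: vertical impulse, loading rate, contact time, active
peak, step frequency. Force-measuring treadmills produce it directly; outside
the laboratory it must be inferred. `grfcast` infers it, frame by frame at
500 Hz, from a biaxial accelerometer taped over the sacrum (an approximation
of centre-of-mass acceleration) plus a handful of static descriptors, across
running speeds of 2.5–4.17 m/s and slopes from −10° to +10°.

The regressor is a sequence-to-sequence recurrent network:

* **input**: per frame, 13 features — the mean, standard deviation (population,
  divisor *n*) and range of the vertical and anteroposterior acceleration in a
  6-frame (12 ms) window centred on the frame (frames *t*−3 … *t*+2), plus
  body mass (kg), height (cm), speed (m/s), slope (°) and the percentages of
  the trial's steps landed rearfoot / midfoot / forefoot;
* **core**: a bidirectional LSTM (tanh cell) whose forward and time-reversed
  output sequences are averaged elementwise;
* **head**: a per-frame MLP with rectifier hidden layers of 128, 384 and 320
  units and a linear scalar output;
* **regularization**: 20% dropout on the inputs, 40% on the LSTM output;
* **training**: Adam, learning rate 0.001, batch size 32 full-length
  sequences, mean-squared-error loss, at most 1,000 epochs with early stopping
  once the training loss fails to improve by `min_delta` for 30 consecutive
  epochs.

Because no temporal normalization is applied — the network predicts one GRF
value per input frame — stance boundaries, contact time, impulse and step
frequency remain measurable from the prediction, which is the entire point of
the frame-by-frame design.

There is no deep-learning framework in this package's dependency set: the
BiLSTM, backpropagation through time, dropout and Adam are implemented in
RcppArmadillo and validated against finite-difference gradients in the test
suite. Glorot-uniform initialization is used for all kernels with the LSTM
forget-gate bias set to 1; weight updates are applied per batch (the
conventional reading of a batch-size-32 recipe).

## Signal processing

Raw trials arrive at 2,000 Hz. The pipeline, in order:

1. **Downsample** GRF and both acceleration channels to 500 Hz by zero-phase
   4th-order Butterworth anti-alias filtering (cut-off 0.4 × target rate)
   followed by integer-factor decimation. Non-integer rate ratios are
   rejected.
2. **Normalize** GRF to bodyweights (force / (mass × 9.81)) when it arrives in
   Newtons; the simulator emits BW directly.
3. **Low-pass filter**: GRF at 30 Hz, acceleration at 20 Hz, both 4th-order
   Butterworth applied forward–backward (zero phase). Zero-phase filtering is
   the biomechanics convention — phase lag would misalign the GRF and
   acceleration streams — and doubles the effective attenuation; the
   documented orders refer to the underlying design.
4. **Clip** negative vertical-acceleration samples to zero. Vertical
   centre-of-mass acceleration is negative throughout the aerial phase, and
   zeroing it helps the network hold predicted aerial GRF at zero.
5. **Window**: pad each acceleration trace with 3 copies of its first value
   and 2 of its last, then take one 6-frame window per GRF frame. The
   asymmetric (3, 2) padding is the only assignment that satisfies both the
   *t*−3 … *t*+2 span and the one-window-per-frame requirement.

The Butterworth designs are derived by bilinear transform of the analog
prototype, with DC gain forced to exactly 1; forward–backward filtering uses
odd-reflection edge padding and steady-state initial conditions (a constant
input passes through exactly). The implementation reproduces the reference
`scipy.signal.butter` coefficients to print precision and is tested against
the analytic magnitude response.

Two orderings are not pinned down by the published description: whether
negatives were clipped before or after filtering, and whether BW
normalization preceded filtering. This package filters, then clips (clipping
a filtered trace is idempotent and keeps the filter linear), and normalizes
before filtering (a scalar multiplication, so the order only matters for
reporting units).

## Feature scaling

All 13 features are min–max scaled to [0, 1] using minima and maxima pooled
over the *training* frames only. The published pipeline explicitly scales
the six window statistics; scaling the seven static descriptors as well is
an extension adopted here for optimizer conditioning. Degenerate features
(training min = max) map to 0; test-set values beyond the training range
scale beyond [0, 1] and are deliberately not clipped. Whether the source
study fitted normalization per cross-validation fold or globally is
unstated; this package fits per fold, which is the leak-free choice, and
the fold-level parameters are recorded in every evaluation report so the
property is testable. Step frequency is deliberately *not* an input feature.

## Stance segmentation and discrete variables

Stance is any maximal run of GRF samples above 5% BW. Raw thresholding
chatters on noisy predicted waveforms, so segmentation debounces by default:
aerial gaps shorter than 10 ms are merged and contacts shorter than 25 ms
dropped; both windows are configurable and can be disabled. Per contact of
`L` frames:

* **active peak** — maximum GRF over the inclusive frame window
  [0.40·L, 0.60·L] (offsets rounded half-up), which excludes early-stance
  impact peaks that can exceed the active peak downhill;
* **impulse** — trapezoidal integral over the contact, dt = 1/rate;
* **loading rate** — secant slope over the first 25 ms of stance,
  (F(25 ms) − F(0)) / 0.025, with linear interpolation at non-integer frame
  offsets (25 ms is 12.5 frames at 500 Hz); undefined and flagged for
  contacts shorter than 25 ms ("average slope" is read as a secant, not a
  regression);
* **contact time** — L/rate;
* **step frequency** — contact onsets per second of full trial duration.

Predicted waveforms must satisfy two plausibility boundaries before entering
any aggregate: the predicted contact count must equal the measured count
(validation mode only), and predicted step frequency must be ≤ 4 Hz
(inclusive at exactly 4). Failing trials are counted in the cohort failure
rate and excluded from all metric aggregates.

## Error metrics and validation designs

* RMSE in BW over the full waveform (stance + aerial).
* rRMSE = RMSE / (0.5 × (range(pred) + range(meas))) × 100.
* MAPE of each discrete variable on trial-aggregated values, averaged trial →
  subject → cohort; measured zeros are excluded with a flag.
* **LOSO**: one fold per subject; training, and normalization fitting, see
  only the remaining subjects. Grand means are means of per-subject means.
* **Slope split**: a single subject's 0° and ±10° trials train a personal
  model tested on the ±5° trials — interpolation to unseen speed–slope
  combinations.
* **Permutation feature importance**: a feature's whole-trial content is
  shuffled across trials (per-frame shuffling would destroy the temporal
  structure the model legitimately uses), predictions recomputed, and PFI
  reported as mean over permutations of permuted-RMSE / baseline-RMSE using
  the RMSE pooled over the subject's trials. The canonical 7-group view
  (`pfi_groups()`) aggregates the three vertical-acceleration statistics,
  the three anteroposterior statistics and the three foot-strike
  percentages.

## The synthetic gait simulator

No accession is deposited for the source study's treadmill data, so the
package ships a generator that emulates the acquisition: 5 s trials at
2,000 Hz over 5 slopes × 3 speeds plus ±10% step-frequency conditions at
3.33 m/s, 19 subjects by default (mass ~ N(68.1, 9.9) kg, height ~
N(173, 9) cm, per the cohort the pipeline targets).

The per-step GRF model is a half-sine active component
`A·sin(π·t/tc)` during stance plus a Gaussian early-stance impact bump
(peak at 15% of stance, width 5%) whose amplitude grows with downhill slope
and the rearfoot fraction — zero for sufficiently uphill slopes. The active
amplitude is chosen so the whole-step impulse equals `cos(slope) × period`
exactly: over whole strides the mean normal force must support the
surface-normal component of bodyweight. Contact time follows a duty-factor
model (0.70 − 0.02 × speed of the step period), and step frequency
increases mildly with speed and uphill slope (2.75 + 0.105·speed +
0.015·slope Hz, ±10% conditions multiplicative), landing in the 3.0–3.4 Hz
range reported for treadmill slope running. These effect sizes are
*declared*, not fitted — the source study does not quantify its subjects'
waveform variability — and they are deliberately conservative.

Vertical acceleration is derived from whole-body dynamics,
`a_v = g·(F_BW − cos θ)`, rather than drawn independently: this guarantees a
learnable mapping, mirroring the empirical finding that vertical
acceleration dominates feature importance. Realism layers on top: damped
soft-tissue ringing at each impact (25 Hz, 30 ms time constant, partially
mixed into the anteroposterior channel), white sensor noise, a biphasic
braking–propulsion anteroposterior wave, the along-surface gravity
component, and a small per-subject sensor tilt that mixes the axes —
because the physical sensors were never calibrated to the treadmill frame.
Every step's onset, contact time, amplitudes, impulse and the trial's
countable step frequency are recorded as ground truth, including the
numerically solved duration above the 5% BW threshold (what any
threshold-based measurement can actually see; the raw half-sine duration
differs from it by ~1.3%, more than the 1% oracle-equivalence budget).

What a green test on synthetic data does **not** establish: accuracy on real
runners. The generator has no step-to-step variability within a trial, no
inter-stride timing jitter, no surface compliance, no fatigue drift, and its
impact transients are smooth Gaussians rather than the sharper, more
variable transients of real footstrikes. Synthetic results validate the
*machinery* — shapes, conservation laws, leak-freedom, learnability — not
clinical accuracy.

## Scaled-down configurations

Desk-scale test runs shrink only what the acceptance criteria leave open:
the end-to-end check uses 8 subjects × 15 trials of 2.5 s (1,250 frames at
500 Hz — generated at that duration rather than truncated, which is
equivalent here because trials are stationary), LSTM width 32, and
additionally MLP 32/32/32, batch size 8, learning rate 0.002, and an epoch
cap of 40 with patience 10 (within the stated ≤ 100), because with
full-length sequences as samples a tiny cohort gives very few Adam updates
per epoch.

The dropout rates are also scaled, to 10% (input) and 10% (post-LSTM).
This is not cosmetic: heavy input dropout on a near-sufficient regressor
biases the MSE-optimal predictor toward shrunk amplitudes (during training
the surviving inputs are inflated by 1/keep, so the network that minimizes
dropout-loss underpredicts on clean inputs unless it has the capacity and
training time to exploit window redundancy to undo the corruption). The
full-width network trained for up to 1,000 epochs can learn that
compensation; a width-32 network trained for 40 epochs cannot, and with the
published 20%/40% rates it plateaus at a systematic ~25% amplitude
underprediction on training and test subjects alike. At 10%/10% the scaled
network generalizes across held-out synthetic subjects; with no dropout at
all it overfits the seven training subjects and its boundary pass rate
collapses — the regularizer is needed, just in proportion to the network.
The capability test for the training loop (learning y = 2 × mean
acceleration) similarly uses a larger learning rate (0.01), verified
empirically to master the map within its 200-epoch budget. The full-scale
defaults in `model_config()` are untouched by any of this.

## Known limitations

The LSTM hidden width is not stated in the published architecture; the
default of 128 is a guess, exposed in the configuration and flagged to
users. The early-stopping threshold "0.001 BW" conflates units (the MSE
loss is in BW²); it is interpreted as 0.001 in loss units. Only the normal
GRF component and two acceleration axes are modelled; mediolateral dynamics,
non-rigid surfaces, slopes beyond ±10° and foot-strike classification from
shoe accelerometers (whose percentages are consumed as given inputs) are out
of scope.
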