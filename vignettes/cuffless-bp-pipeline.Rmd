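---
title: "Cuff-less wristwatch blood pressure estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuff-less wristwatch blood pressure estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Wristwatch-type cuff-less monitors estimate systolic and diastolic blood
pressure (SBP/DBP) from two simultaneously recorded signals: a single-lead
ECG (between the wrists) and a reflective photoplethysmogram (PPG) at the
wrist. The physiological carrier is pulse transit time (PTT): the interval
from the ECG R-peak to the arrival of the pressure pulse at the wrist,
read off as the peak of the PPG first derivative. Higher arterial pressure
stiffens the vessel wall, speeds the pulse wave, and shortens PTT, so to
first order PTT falls linearly as BP rises. PTT alone is not enough for
absolute accuracy, which is why the pipeline adds waveform features,
demographics, a learned regression model, and a mandatory per-subject
calibration step (as wearable cuff-less standards require).

`wristbp` implements the full chain and, because raw clinical recordings
for such devices are generally not public, ships a signal simulator with
exact ground truth so that every stage can be validated end to end.

## Pipeline

For one 24-s measurement:

1. **Denoising.** Zero-phase Butterworth bandpass filters: 0.8–11 Hz for
   the PPG, 5–30 Hz for the ECG. The filters are 4th order and applied
   forward–backward (`signal::filtfilt`), so waveform peaks are not
   displaced; the input is extended by odd reflection before filtering so
   the slow 0.8 Hz high-pass edge does not leave visible transients inside
   the record.
2. **Beat separation.** R-peaks are found with a derivative-energy
   detector (Pan–Tompkins in spirit): squared first difference, 100-ms
   moving average, adaptive threshold at 20% of the maximum energy,
   candidate refinement to the local ECG maximum, 0.25-s refractory
   period. Each beat is windowed from its R-peak to 90% of the local RR
   interval; the first and last beats are dropped as partial.
3. **Quality gating.** Each beat's PPG segment is resampled to a fixed
   100-point grid; its quality is the mean Pearson correlation against
   every other beat's segment. The ten best beats are kept, and the
   measurement passes only if the minimum selected quality is at or above
   0.90 (boundary inclusive). Scoring against *all* beats — not only the
   selected ten — is deliberate: when a third or more of the record is
   corrupted by bad sensor contact, even the mutually consistent clean
   beats see their mean correlation collapse and the whole measurement is
   rejected, which is the behaviour a contact-quality gate must have.
4. **Features.** Per beat: PTT (time of the PPG derivative maximum within
   the R-anchored window; a maximum on the window boundary flags the beat
   invalid), an 8-band normalized PPG spectrum over 0.8–11 Hz, seven
   pulse-morphology descriptors (amplitude, half-height width, rise and
   decay times, normalized area, extreme slopes), plus heart rate and the
   subject's age, sex, height and weight.
5. **Outlier screening** (training only). A single-pass univariate
   3-sigma filter, then an undercomplete autoencoder refitted on the
   retained rows; rows whose reconstruction MSE exceeds mean + 3 SD are
   excluded (one-sided; boundary retained).
6. **Regression.** A fully connected network with batch-normalized hidden
   layers and a two-node linear output (SBP, DBP). The architecture —
   number of layers, nodes per layer, activation — is chosen by
   subject-grouped k-fold cross-validation; the winner is refit on all
   rows. Inputs are z-scored; target scaling is folded back into the
   output layer so the stored read-out maps hidden activations directly
   to mmHg.
7. **Calibration.** Because each output is an affine read-out of the
   final hidden layer, per-subject correction reduces to a gain and
   offset per channel, fitted by least squares over at least three paired
   device/manual measurements with the gain ridge-shrunk toward 1.
   Fewer than three pairs is refused outright.
8. **Aggregation.** The per-measurement estimate is the median of the ten
   per-beat predictions.

The validation layer implements the alternating 7-measurement sequence
(manual, watch, …, manual), nearest-reference pairing (ties to the
previous manual), Bland–Altman bias and 1.96 SD limits of agreement,
inclusive ±5/10/15 mmHg accuracy bins, RMSE, a two-sided paired t-test,
Pearson correlation with the r > 0.90 "high correlation" convention, and
the 2-of-3 hypertension rule (a reading is high iff SBP > 135 or
DBP > 85 mmHg, strictly).

## The synthetic signal generator

`simulate_recording()` builds each channel beat by beat. The ECG is a sum
of Gaussian bumps (P, QRS, T) with the QRS dominant — only R-peak timing
matters downstream, so no attempt is made at 12-lead realism. The PPG is
a train of gamma-shaped pulses
\(g(t) = (t/\tau)^k e^{-t/\tau}\) with \(k = 4\), \(\tau = 45\) ms
(foot-to-peak rise ≈ 180 ms), chosen so the first derivative has a single
dominant peak whose offset from pulse onset has the closed form
\(\tau(k - \sqrt{k})\). Each pulse is placed so that its derivative peak
lags the R-peak by exactly

\[ \mathrm{PTT} = a - b \cdot \mathrm{SBP} \]

plus per-beat noise (default 2 ms), giving the feature extractor an exact
oracle. The order-4 template also keeps the derivative lobe nearly
symmetric, so the zero-phase 11 Hz low-pass moves it by well under one
sample at 250 Hz — the measured estimator bias on clean beats is about
0.35 samples.

Cohort-level defaults mirror the validation population the package
emulates: SBP 129.6 ± 23.6 mmHg, DBP 69.5 ± 12.9 mmHg (correlation 0.6,
reject-resampled so SBP > DBP + 10 and PTT stays positive), heights
162.2 ± 8.6 cm, weights 67.5 ± 12.3 kg, ages uniform over 20–85. The
PTT intercept varies between subjects (sd 4 ms ≈ 4 mmHg at the default
slope): this is the device-unknown individual offset that per-subject
calibration exists to absorb. Watch measurements fluctuate around the
subject's resting BP with sd 6 mmHg (measurement-level, shared by all
beats of a measurement); manual references are read by two virtual
observers (sd 2 mmHg each) who repeat the measurement until they agree
within 4 mmHg and record their mean. Defaults not fixed by the emulated
protocol — sampling rate 250 Hz, beat jitter 10 ms, heart rate
70 ± 8 bpm — were chosen once as field-typical values.

What the generator does **not** emulate: dicrotic notches and reflected
waves, arrhythmia (enrolment assumed sinus rhythm), motion artefacts
beyond the three stylized corruption modes (flatline, noise burst,
saturation), sensor drift, or any dependence of PPG morphology on BP
beyond the PTT shift. Passing tests therefore demonstrate that the
pipeline recovers what this generator encodes — timing-coded BP with
realistic noise topology — not that the trained network would transfer
to clinical recordings.

## Numerical and design choices

* **Filter order** (4th, forward–backward → effective 8th) is a
  convention choice; only the type and bands are fixed by the emulated
  design.
* **Spectrum.** Band *power* fractions at the segment's natural FFT
  resolution (rectangular window, mean removed, no padding). At natural
  resolution a tone completing whole cycles in the segment is
  leakage-free, so band content is exactly localized; tapered or
  zero-padded analyses smear a tone's mainlobe across the 1.3 Hz-wide
  band edges and cannot localize even a pure tone to one band.
* **Beat selection** takes the ten *best*-scoring beats (not the first
  ten passing); the alternative is not distinguishable from the emulated
  description and best-10 is the stricter reading.
* **"Spatial correlation"** is read as sample-wise Pearson correlation
  between per-beat PPG waveforms on a common RR-normalized grid; a
  zero-variance (flatlined) segment correlates at 0 by convention rather
  than being undefined.
* **Autoencoder.** Single hidden layer, linear activations, bottleneck
  ⌈d/2⌉ by default, trained by full-batch gradient descent with momentum
  (convergence: relative loss change < 1e-5 or 2000 epochs). A linear
  undercomplete code is sufficient for reconstruction-error screening —
  what matters is that rows breaking the bulk correlation structure
  cannot be reconstructed — and it keeps the planted-outlier behaviour
  deterministic given the seed. The screen is retrained after the sigma
  pass (the alternative, training on the unfiltered table, lets extreme
  rows distort the code they are then judged by).
* **Network training.** Loss is MSE summed over the two outputs;
  optimizer is full-batch gradient descent (momentum 0.9, fixed learning
  rate 0.05) with early stopping on a subject-grouped validation split
  and best-weights restore. Batch normalization is applied to hidden
  layers (batch statistics during training, stored running statistics at
  inference). Fold assignment is grouped by subject so no subject's
  beats straddle a train/validation split.
* **Calibration form.** Re-fitting the whole output layer over hidden
  activations is over-parameterized for three pairs; the two-parameter
  affine correction per channel with ridge shrinkage λ = 50 mmHg² on
  (gain − 1) is the declared resolution, and it is exactly equivalent to
  rescaling/shifting the final linear map
  (`fold_calibration_into_model()` asserts this to machine precision).
  Degenerate fits (collinear device predictions, gains outside
  (0.25, 4)) fall back to gain 1 with the mean-difference offset, which
  also guarantees calibration never fits its own pairs worse than the
  uncalibrated device.
* **Aggregation.** Per-beat predictions with a per-measurement median:
  robust to a stray beat and insensitive to beat order.
* **Hypertension thresholds** are strict (> 135 / > 85) exactly as
  printed in the emulated protocol. The bundled concordance panel's
  published subject-level classifications are treated as ground truth
  because two of its printed cells are not re-derivable under any single
  threshold convention; concordance analyses therefore consume the
  printed classifications, not re-derived ones.

## Study sizes and what the synthetic study shows

`run_synthetic_study()` defaults to 40 training subjects × 4 measurements
(≈ 1 600 screened beats), a reduced architecture search (1–2 hidden
layers of 16 relu nodes, 3-fold grouped CV), and a 35-subject test cohort
run through the full calibration + 7-measurement protocol — 105 paired
readings, the size of the emulated study. These sizes keep a complete run
in the low minutes on one core; they are a deliberate desk-scale choice,
not a statistical optimum.

On that study the pipeline typically achieves r ≈ 0.97–0.99 between
estimated and true SBP on held-out subjects, and the proportion of
estimates within ±10 mmHg of truth sits at the binomial expectation
2Φ(10/6) − 1 ≈ 90% implied by the injected 6-mmHg measurement noise.
`calibration_improvement_experiment()` verifies that calibration strictly
shrinks the systematic bias of offset-shifted subjects (+8 mmHg default)
in ≈ 90–95% of replicates; with 20 replicates that rate carries a
Monte-Carlo spread of roughly ±10 points, and the occasional failing
replicate is one whose general-model subject error happens to cancel the
injected offset, leaving little bias to remove.

## Known limitations

* The general model is trained and evaluated on the simulator; no claim
  of equivalence with any commercial device's proprietary feature set or
  weights is made.
* The feature schema is fixed (versioned by name list); second-derivative
  PPG indices and HRV features are out of scope.
* Calibration is assumed temporally stable — no drift model or
  recalibration scheduling.
* The network is intentionally small; it is an estimator for the
  simulator's information content, not a general BP foundation model.
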