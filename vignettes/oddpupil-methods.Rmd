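---
title: "Models and methods behind oddpupil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oddpupil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`oddpupil` implements a trial-level analysis of concurrent pupillometry and
EEG recorded during a passive auditory oddball task, together with a
synthetic-data generator that stands in for raw recordings (which, for this
kind of clinical study, are typically not shareable). This vignette explains
the scientific model behind each stage, the tunable parameters and their
defaults, the design decisions taken where the protocol leaves room, and
what the test suite does and does not establish.

## The task

The paradigm is a passive auditory oddball: four blocks of 103 pure tones
(100 ms at 85 dB, interstimulus interval jittered uniformly between 1800 and
2000 ms). Each block opens with three standard tones that establish the
standard, followed by 100 pseudorandom tones of which 20% are oddballs
differing in pitch (500 vs 750 Hz). Which pitch serves as the oddball in the
first block is pseudo-randomized between subjects, and the assignment is
swapped between the two blocks of each half so that both pitches act as the
oddball once before and once after the arousal manipulation (an isometric
handgrip exercise between blocks 2 and 3). `build_schedule()` generates this
design deterministically from a seed.

Two choices are ours, not the protocol's:

* the pseudorandom order additionally forbids two consecutive oddballs
  (standard oddball-design practice; every oddball is preceded by at least
  one standard). The constraint is a flag
  (`forbid_consecutive_oddballs`), and with it on, oddball positions are
  drawn uniformly over all non-adjacent placements via a stars-and-bars
  construction;
* "forward/reverse" block labels: blocks 1 and 3 are forward, 2 and 4
  reverse, consistent with the within-phase pitch counterbalancing.

## Pupil preprocessing

Pupillometry proxies the locus coeruleus–norepinephrine (LC-NE) system:
baseline pupil size (BPS) tracks tonic arousal, the stimulus-evoked
pupillary response (SEPR) tracks phasic activity. Raw samples are two-eye
diameters at 300 Hz. The chain, applied per eye and then averaged:

1. **Range filter** — diameters below 2 mm or above 8 mm are implausible
   and marked invalid (strict bounds; the boundary values themselves
   survive).
2. **Dilation-speed filter** — per-sample speeds are the larger of the
   backward and forward absolute difference quotients over the valid
   subsequence; samples whose speed exceeds `median + 3 × MAD` are
   removed, and the pass is repeated once on the survivors ("the new trend
   line"). The MAD is unscaled (no 1.4826 consistency constant); a plain
   `3 × MAD` threshold, a forward-difference speed and the consistency
   constant are config options. Fewer than three valid samples leave the
   eye untouched with a warning record.
3. **Blink detection** — contiguous invalid runs spanning 75–250 ms are
   blinks; valid samples within 27 ms of either gap edge are discarded
   (partial occlusion distorts the diameter estimate). At 300 Hz that is 8
   samples on each side.
4. **Interpolation** — interior gaps up to 300 ms are filled linearly
   between their anchors and count as valid afterwards; longer and edge
   gaps stay missing.
5. **Eye averaging** — the mean where both eyes are available, the single
   eye otherwise. Filtering each eye independently before averaging is our
   reading of the protocol order.
6. **Baseline and response** — BPS is the mean diameter in the first
   250 ms after onset (the protocol's trial-based baseline, deliberately
   post-onset); the corrected series is the mono series minus BPS; SEPR is
   the mean corrected diameter 500–1500 ms after onset. All windows are
   half-open `[a, b)`.
7. **Validity** — a trial enters the analysis only if at least 50% of its
   samples are valid (imputed samples count as valid; whether the original
   code counted them is unstated — we do, and expose the threshold).

Two properties of the dilation-speed filter are worth knowing. First, on
very short series robust statistics cannot isolate a spike: in a six-sample
series with one excursion, half the speeds touch the spike, the median and
MAD inflate, and nothing is removed — the filter needs a few dozen samples
of context, which real trials always have. Second, the flagged fraction
under i.i.d. measurement noise is scale-free (roughly 5–8% with the
bidirectional speed), because `median + 3·MAD` cuts a fixed quantile of the
speed distribution; "clean" data in the sense of *no rejections* means
smooth, correlated signal, not merely spike-free noise.

## ERP extraction

Single-trial epochs span −500 to +800 ms around tone onset at 500 Hz,
channels Fz, FC1, FC2, FCz, Cz. The chain: a zero-phase (forward–backward)
4th-order Butterworth low-pass at 30 Hz, subtraction of the mean over the
pre-stimulus −500–0 ms per channel (the correction method itself is
standard ERP practice; the protocol states only the baseline window), and
electrode-cluster averages: FC1/FC2/FCz/Fz for the mismatch negativity
(MMN), Cz/FCz for the P3a.

MMN is the windowed minimum 100–150 ms after onset, P3a the windowed
maximum 150–250 ms; the reported amplitude is the mean over ±4 ms around
the peak sample (5 samples at 500 Hz) and the latency is the peak time.
Ties break to the earliest sample and peaks may sit on window edges — the
peak is defined as the windowed extremum, not a local extremum. The ±4 ms
amplitude window stays centred on the peak even at a window edge (it may
leave the search window, never the epoch). At the aggregated level the MMN
is additionally read off the oddball-minus-standard difference wave.

A block enters the EEG analysis only if at least two thirds of its
scheduled trials per stimulus type survive: `floor(2/3 × (20, 80)) =
(13, 53)`. The three lead-in standards are excluded from analysis tables.

The Butterworth design is implemented from the analog prototype via the
bilinear transform (no DSP package of the required kind is available in the
target environment); its magnitude response therefore satisfies the
closed-form `|H(ω)|² = 1/(1 + (tan(ω/2)/tan(ωc/2))^{2n})`, which the test
suite checks directly, along with DC preservation, stopband attenuation and
phase cancellation. `filtfilt()` uses odd-reflection padding and
steady-state initial conditions, the conventions of the reference
implementations in the field.

## Trial-level mixed models

One row per analysed trial: BPS, SEPR, MMN/P3a amplitude and latency, plus
design covariates. Each outcome is centred and scaled once across all
trials entering the model (sample SD; missing rows dropped listwise per
model). The core model is

```
outcome ~ stimulus * group * manipulation + block_direction + age + gender
          + (1 | subject)
```

fitted by REML (delegated to lme4). Factors use treatment coding with
references CON / standard / before / forward / m; reported contrasts are
differences of *marginal means* — model-implied cell means averaged with
equal weights over the levels of non-involved factors, covariates at their
mean — so they are coding-invariant. Equal (rather than proportional) cell
weights are a choice, exposed for scrutiny; with the balanced synthetic
design the two coincide in expectation. Contrast CIs are delta-method
Wald intervals. Factors observed at a single level (e.g. block direction in
a reduced one-block-per-phase design) are dropped from the default formula
as unestimable; rank-deficient fixed designs fail fast naming the aliased
columns.

Term tests are large-sample Wald chi-square statistics (reported alongside
as F = W/df); Satterthwaite degrees of freedom would require machinery not
available in the target environment, and at the trial-level sample sizes
this package is built for (tens of thousands of rows) the two are
indistinguishable. The `df_method` field of every result records this.

Model fit is summarised by Nakagawa's marginal and conditional R²: with
`σ²_f` the variance of the fixed-effects linear predictor, `σ²_α` the
random-intercept variance and `σ²_ε` the residual variance,
`mR² = σ²_f/(σ²_f+σ²_α+σ²_ε)` and `cR² = (σ²_f+σ²_α)/(σ²_f+σ²_α+σ²_ε)`.
`0 ≤ mR² ≤ cR² ≤ 1` holds by construction and is asserted on every fit.

Pupil–ERP coupling models (`pupil_erp_model()`) add standardized BPS and/or
SEPR as covariates to the same fixed structure, optionally interacting with
group.

## The synthetic generator

The generator's role is to provide data with the statistical structure the
analysis assumes, so that every stage is testable without recordings. Its
defaults describe one fixed world — a plausible adolescent cohort under
constant laboratory lighting — and were chosen once, on first principles,
not adjusted to test outcomes:

* **Pupil**: tonic level 5 mm with a between-subject SD of 0.5 mm (pupil
  models routinely show subject ICCs above 0.8, matching the near-0.9
  conditional R² such models report); a within-block linear drift of
  −0.05 mm/min (arousal wanes during a passive task); a gamma-shaped
  dilation kernel `(t/t_max)^n e^{n(1−t/t_max)}` with `t_max` = 930 ms and
  `n` = 10.1 (the canonical pupil-response parametrisation), so the
  500–1500 ms SEPR window captures the bulk of the response; dilation
  amplitude 0.05 mm for standards with a 0.03 mm oddball increment and a
  trial-to-trial SD of 0.05 mm; white per-eye measurement noise of
  0.05 mm; 15 blinks/min of 100–200 ms (binocular); 4 spike artifacts/min
  of ±1.5 mm (monocular); 10% whole-trial dropouts (recorded inclusion
  rates in comparable studies sit in the 80s). The after-manipulation
  tonic shift is +0.08 mm for ASD, +0.11 mm for MHC, 0 for CON — the
  clinical-groups-only arousal upregulation the analysis is designed to
  detect.
* **EEG**: Gaussian components on every channel — a negative deflection at
  125 ms (SD 20 ms), 1 µV for standards plus 1 µV for oddballs; a positive
  deflection at 200 ms (SD 30 ms), 1.5 µV plus 0.75 µV for oddballs —
  with subject intercepts (SD 0.5 µV) and trial-level amplitude
  variability (SD 0.5 µV), on a background of 1/f noise (2 µV) plus white
  noise (1 µV). Single-trial ERP features are therefore noise-dominated,
  as they are in reality (trial-level marginal R² in the percent range).
  No forward model and no topography: all channels carry the same signal,
  and clusters differ only through their noise averaging. An optional
  coupling parameter feeds the trial's pupil-amplitude deviation into the
  MMN amplitude to give pupil–ERP models a known ground truth.

What the generator does **not** emulate: gaze position and eye movements,
EEG scalp topography and volume conduction, non-stationary noise, age or
gender effects on any outcome (the covariates are inert), and drifts in
electrode impedance. A green recovery test therefore establishes that the
pipeline measures what the generator encodes — filters behave, windows are
right, models are unbiased with honest intervals — not that it would be
robust to every pathology of real recordings.

### Ground truth for recovery tests

BPS and SEPR are linear measurements, so generator effects map exactly onto
the measured scale (for SEPR via the kernel's window gain,
`sepr_window_gain()`, the mean of the baseline-corrected kernel over the
SEPR window; ≈ 0.67 at defaults). Windowed-minimum ERP extraction is *not*
linear under noise: the measured oddball−standard MMN contrast is an
attenuated version of the component increment, because the extremum of
signal-plus-noise is extreme-value biased. The recovery suite therefore
calibrates the measurement-scale MMN estimand once per run with a
high-precision independent Monte Carlo under the same generator settings
(independent seed) and checks CI coverage against that value. This is the
standard simulation-study construction of an estimand at the measurement
level; the extraction code itself is validated separately against
brute-force scans.

The recovery suite runs 100 cohorts of 30 subjects with a reduced design
retaining blocks 1 and 3 of the full schedule — one block per manipulation
phase. A literal "first two blocks" design would contain no
after-manipulation data at all, making manipulation effects unrecoverable;
retaining one block per phase preserves the contrast of interest at a
quarter of the compute. Both retained blocks are forward, so block
direction drops out of those models.

For throughput, `simulate_cohort_features(fast = TRUE)` generates and
reduces each subject with matrix operations: batched noise FFTs, one
compiled zero-phase filtering pass over all trials, vectorised peak
extraction, and the full preprocessing chain per trial in compiled code.
Because this path only ever consumes the two cluster-average waveforms, it
generates cluster-level EEG noise directly from three independent series
(the pooled FC1/FC2/Fz mean, FCz, and Cz) with exactly the covariance that
averaging five independent channel noises induces — including the
correlation the shared FCz channel creates between the MMN and P3a
clusters. The trial-wise path, which builds full five-channel epochs, is
the reference: with all noise at zero the two paths agree to machine
precision, with noise they agree in distribution, and both facts are
asserted in the suite.

## Power simulation

The Monte-Carlo power analysis targets the group × manipulation interaction
in the trial-level random-intercept model. The protocol states the effect
size (standardized β = 0.2), the sample (150 participants split 52/55/43)
and the test, but not the variance decomposition or which contrast carries
the effect. Our documented assumptions, all config knobs: the random
intercept carries 30% of unit total variance (ICC 0.3); β = 0.2 sits on the
ASD-vs-CON × after-vs-before contrast; the test is the omnibus Wald
chi-square (2 df) of the interaction at α = 0.05; 412 trials per subject,
half before and half after the manipulation. Because the manipulation
varies within subject, the intercept variance cancels from the contrast and
power at this configuration saturates near 100% — consistent with the
published estimate of 99.6% — and exact reproduction is
assumption-dependent, which is why the acceptance comparison allows
stochastic tolerance. The default of 200 replicates is a desk-scale choice
(Wilson 95% CI of ±~2 points near the boundary); `reps` scales it up.

Type-I calibration (β = 0) is asserted at a smaller configuration
(30 subjects × 40 trials, 500 replicates) purely for runtime; the Wald
test's null behaviour does not depend on the trial count beyond the
large-residual-df regime that any trial-level dataset is in.

## Numerical and degenerate-input policy

* Windows half-open; onset `t = 0` is the first sample at/after stimulus
  onset; blink/gap spans count one nominal sample interval beyond the
  first-to-last missing sample.
* Peak ties break earliest; standardization uses the sample SD (n−1) and
  refuses zero-variance or all-missing input; aliased designs error
  naming the offending columns; trials with no valid baseline sample are
  unusable; eyes with fewer than three valid samples skip the speed filter
  with a warning record.
* Every stochastic entry point takes an explicit seed; per-subject and
  per-replicate seeds derive from the master seed by a fixed congruential
  map, so cohorts are reproducible element-for-element and independent
  runs never share substreams.

## Known limitations

* The generator's effect magnitudes are synthetic choices; nothing here
  reproduces, or could reproduce, coefficients estimated on the original
  non-public recordings.
* Continuous-EEG preprocessing (re-referencing, ICA, artifact screening,
  channel interpolation) is out of scope; the package starts from epochs.
* Wald intervals and tests are large-sample; at very small subject counts
  (≪ 20) they will be mildly liberal, which the null-calibration suite
  bounds but does not remove.
* The HDF5 epoch container requires the Bioconductor package `rhdf5`
  (suggested, not imported); all other I/O is plain text.
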