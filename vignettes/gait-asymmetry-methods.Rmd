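---
title: "Methods: bilateral gait sEMG asymmetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral gait sEMG asymmetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gaitsemg)
library(dplyr)
```

## The problem and the measurement model

Surface EMG (sEMG) of the shank muscles — tibialis anterior (TA), soleus
(SOL), lateral and medial gastrocnemius (LG, MG) — is widely used as a
control source for active prostheses and rehabilitation robots, often
recorded from one leg only under a gait-symmetry assumption. This package
implements a pipeline that puts that assumption under test: it quantifies,
muscle by muscle, how differently the left and right limb behave during
quiet standing and steady treadmill walking, and how irregular each
muscle's activation profile is.

The raw signal is modelled, for the purposes of processing and of the
synthetic generator, as an amplitude-modulated band-limited stochastic
carrier: what carries physiological information at the time scales studied
here is the envelope of the interference pattern, not its phase. All
comparisons therefore run on sliding-window RMS envelopes normalized to a
per-muscle maximum voluntary contraction (%MVC), which removes electrode,
gain and anatomical scale factors and makes sides and subjects comparable.

## Pipeline stages and their parameters

### Filtering

`bandpass_notch()` applies a 4th-order Butterworth band-pass, 10–500 Hz by
default, forward and backward (zero phase), then a biquad notch at the
50 Hz mains frequency with quality factor 30. Acquisition hardware usually
band-limits already; this stage exists so that synthetic signals and any
raw re-analysis share one code path. Two numerical details matter:

* the notch's impulse response rings for a few tenths of a second
  (time constant ≈ 2Q/ω₀ ≈ 0.19 s at 50 Hz), so the signal is padded by
  odd reflection (up to 1 s) before `filtfilt`; without padding the edge
  transients leave several percent residual RMS on a pure 50 Hz tone;
* band edges must satisfy 0 < low < high < fs/2, and signals shorter than
  the filter warm-up are rejected rather than silently filtered.

### RMS envelope and %MVC normalization

`rms_envelope()` uses a 125 ms window with 50% overlap by default — a
conventional smoothing for gait sEMG; the envelope's own sampling rate
(fs/hop) travels with the object, so downstream stages are independent of
this choice. The window is exposed because it is also a bandwidth: a
125 ms window cannot follow envelope modulations much faster than ~8 Hz,
which matters both for onset timing and for the ripple feature of the
generator (below).

The MVC reference (`extract_mvc()`) is the maximum of a 1 s moving average
of the MVC-trial envelope rather than the raw envelope maximum: a single
spiking frame should not define 100%. A zero reference is an error —
normalization is then impossible by construction, not a warning.
`mvc_normalize()` refuses to normalize twice.

One statistical subtlety is documented here deliberately: the left and
right references are estimated from separate MVC trials, so even perfectly
symmetric muscles end up with a small coherent multiplicative offset
between their %MVC curves. Rank statistics are sensitive to coherent
offsets in flat curve regions however small the sampling noise becomes, so
a "symmetric" validation construction must share one reference across
sides; with real data this sensitivity is part of the method and worth
keeping in mind when interpreting borderline p-values.

### Gait-cycle segmentation by right-TA onset

The gait cycle is defined by muscle activity rather than foot contact: a
cycle starts when the right TA begins to contract and ends when it
contracts again. This suits an EMG-only protocol (no footswitches or
kinematics) and pins phase 0 to an electromyographically observable event.
Both limbs are cut on this single clock.

The onset criterion is not standardized in the literature, so
`detect_onsets()` makes its choices explicit and configurable:

* threshold = baseline level + k · spread, with k = 3 by default;
* baseline level = mean of the channel's lowest-decile frames (no
  separate rest recording exists per speed in the protocol);
* spread = 1.4826 · MAD of the whole channel. A spread estimated only
  from the lowest-decile frames would be biased far below the resting
  variability (a truncated tail has artificially small SD), placing the
  threshold inside the resting distribution and firing on noise; the MAD
  of the full channel is robust as long as bursts occupy less than about
  half the frames, which holds for TA;
* an onset must be an upward *crossing* (a record that begins above
  threshold does not fire at its first frame), sustained for at least
  50 ms, with a 0.45 s refractory period. The refractory value is chosen
  to bridge the dip between the TA swing burst and the swing-to-stance
  transition burst at the slowest cadence considered (~0.33 s at a 1.1 s
  cycle) while staying below the shortest cycle at fast walking (0.67 s),
  so each cycle fires exactly once.

A constant envelope returns zero onsets (no crossing exists); fewer than
two onsets yield an empty cycle set with a warning rather than an error,
and the pipeline records such recordings as per-speed issues.

Because the threshold is baseline-relative, onset indices are invariant
under uniform rescaling of the envelope — segmentation does not depend on
amplitude units.

### Phase normalization and ensembles

`time_normalize()` resamples each half-open cycle [start, end) at phases
k/100, k = 0..99, by linear interpolation; point 100 would coincide with
the next cycle's point 0, so contiguous cycles tile the record without
double-counting. A cycle of exactly 100 frames reproduces its frames
verbatim. `ensemble_average()` takes the pointwise mean and *population*
SD across cycles; `phase_annotation()` labels phases below 0.6 as stance
and the rest as swing (the conventional 60/40 split at normal walking),
configurable.

When several subjects are analyzed, cycles are pooled across subjects by
default (`pool = "cycles"`); `pool = "subjects"` first averages within
subject and ensembles the per-subject means. The default treats the cycle
as the sampling unit, which matches how the ensemble curves are used
downstream; the alternative weights subjects equally.

### Sample entropy

`sample_entropy()` measures irregularity as
SampEn = −log(A/B), with B and A the counts of ordered template pairs
within tolerance r (maximum norm, strict inequality) at lengths m and
m + 1. Defaults m = 2 and r = 0.2 in SD units of the standardized series —
the conventional recommendation for physiological series (r between 0.1
and 0.25 SD). Standardization precedes matching, so the result is
invariant to affine rescaling of the input.

Two formulations are implemented:

* **standard** (default): the Richman–Moorman convention with the same
  N − m templates at both lengths, so the ratio is a genuine conditional
  probability and the value is non-negative whenever defined. If no pair
  still matches at length m + 1 the value is +Inf and flagged
  `undefined`; if nothing matches even at length m the tolerance is too
  small for the data and an error is raised.
* **binomial**: a step-by-step formulation that circulates in parts of
  the applied literature, using all N − m + 1 templates at length m,
  dividing ordered-pair counts by the unordered-pair binomial coefficient
  (so the "probability" can reach 2), and orienting the ratio as
  −log(φ_m / φ_{m+1}), which is non-positive in practice. It is provided
  for auditing published numbers, not as a default.

Both formulations are verified against an independent brute-force O(N²)
enumeration in the test suite. One property worth stating precisely: the
match fractions are non-decreasing in r by construction, but the entropy
value itself is a ratio of counts and can fluctuate upward between nearby
tolerances in finite samples; only across well-separated tolerances is the
decrease reliable. The tests assert exactly that.

### Left/right statistics

`rank_sum_test()` is a two-sided Wilcoxon rank-sum with midranks. The
p-value is exact — full enumeration of the rank-sum null — when the
combined sample size is at most 20 and there are no ties, and otherwise a
normal approximation with tie-corrected variance and continuity
correction. Significance is declared at α = 0.05. No multiple-testing
correction is applied across the muscles × speeds grid; that mirrors the
single-comparison convention of the protocol this package models, and
users can always correct the reported p-values themselves.

What the two samples are is a design decision the protocol leaves open,
so it is explicit and configurable here:

* **static**: the pooled envelope frames of each side, computed with
  non-overlapping windows (`overlap = 0`) so the frames entering the test
  are approximately independent — the rank-sum p-value assumes
  exchangeable independent observations;
* **dynamic**: the two 100-point ensemble curves of the muscle at that
  speed. These 100 phase points share the deterministic activation shape,
  so the test here is an ordinal comparison of two curves, not a
  calibrated test on independent observations; its p-values are
  meaningful for detecting coherent left/right level differences but
  should not be read as frequencies under a sampling null.

The asymmetry descriptors are Δd = |mean_left − mean_right| in %MVC
points (symmetric under limb swap; summarized per muscle into max/min
across speeds by `delta_d_summary()`) and the left/right activity ratio
(which inverts under limb swap).

## The synthetic generator: what it emulates, and what not

`synth_gait_emg()` builds each channel as
x(t) = A · s(φ(t)) · n(t), where n(t) is zero-mean Gaussian noise
band-limited to 10–500 Hz, s(φ) = baseline + e(φ) the activation shape at
gait phase φ, and A = mvc_amplitude × asymmetry gain ×
(1 + speed_gain · speed). Phase 0 is right-TA activation onset, matching
the segmenter's target definition. Defaults encode the study conditions
this package models: fs = 2000 Hz, 15 s per treadmill speed, speeds
1.0–4.5 km/h, nine subjects in cohort scenarios, amplitude rising with
speed (speed_gain = 0.15 per km/h), resting floor baseline_level = 0.15,
and cycle duration 60/(45 + 10·speed) s — a cadence that rises with speed,
chosen as a realistic walking cadence since the protocol reports none.

The default activation templates are wrapped Gaussian bumps: TA centred at
phase 0.78 (swing) with a smaller burst at phase 0 (the swing-to-stance
transition, where all four muscles act simultaneously); SOL broad over
stance (centre 0.35, width 0.15); LG and MG late stance (centre 0.45,
width 0.08). These match the qualitative timing of the four muscles during
walking and are fully configurable.

Two numerical choices deserve explanation:

* the carrier is band-limited by masking the discrete Fourier transform
  of white Gaussian noise rather than by an IIR filter: this confines the
  carrier's power exactly to the band (a finite-order Butterworth leaves
  a percent-level leak in its transition bands) and keeps the process
  Gaussian. The scale is set by the *theoretical* SD of the masked
  process, not the realized sample SD — pinning each channel's realized
  power would artificially equalize left and right and bias null
  statistics of downstream tests;
* the per-channel `ripple` option multiplies the activation shape by
  1 + a·sin(2π·k·φ) with k = 2 oscillations per cycle by default. The
  ripple is phase-locked (so it survives ensemble averaging) and slow
  (so it survives the ~8 Hz bandwidth of the 125 ms RMS window even at
  the fastest cadence, where one cycle spans only ~11 envelope frames).
  It injects controlled extra irregularity into selected channels — the
  fixture used to verify that the sample-entropy stage sees a genuinely
  rougher right MG as rougher.

`synth_static_emg()` produces stationary carriers at
amplitude × baseline_level per channel (standing holds a low tonic
activation with no phase structure), and `synth_mvc_trial()` full-scale
carriers as normalization references.

What the generator does *not* emulate: motor-unit structure (no MUAP
trains, recruitment or conduction-velocity effects), fatigue-related
spectral shifts, electrode artefacts, cycle-duration variability within a
recording, kinematics or ground-reaction forces, and any cross-channel
correlation beyond the shared cycle clock. Passing tests on synthetic data
therefore demonstrate that the pipeline's stages do what they claim on
signals of realistic amplitude, band and timing structure — not that the
biological interpretation of any real dataset is settled.

## Verification design and problem sizes

The test-suite scenarios use sizes chosen to make their Monte-Carlo noise
small relative to the effects they check: the type-I calibration runs
2000 symmetric standing replicates of 4 s each (32 independent frames per
side per replicate); gain recovery uses 60 gait cycles; the
direction-property scenarios use nine subjects per speed across all eight
speeds, 15 s each; segmentation fidelity uses 20 seeded 12-cycle runs at a
0.2 resting floor. The brute-force sample-entropy oracle covers 50 series
up to N = 200, and the exact Wilcoxon enumeration all sample sizes up to
6 per group. `scripts/acceptance.R` re-runs all of these from scratch
under a user-supplied seed.

## Known limitations

* The onset detector assumes a burst-type channel whose active fraction
  stays under about half the frames; it is applied only to the right TA,
  which satisfies that. Applying it to a tonically active muscle (e.g.
  SOL at some cadences) would need a different spread estimator.
* The dynamic rank-sum p-values compare dependent curve points, as
  discussed above.
* %MVC normalization inherits the MVC trial's estimation error as a
  coherent per-channel scale offset.
* Sample entropy on 100-point curves sits at the short end of the
  recommended series lengths for m = 2; values are comparable across
  curves of the same length, which is how they are used here.
* The gait-cycle definition (right-TA onset) is intentionally
  non-standard; curves are not phase-aligned with heel-strike-based
  conventions and should not be compared to them point by point.
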