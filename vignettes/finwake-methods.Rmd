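---
title: "Methods: pectoral fin kinematics and muscle activity in a cylinder wake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pectoral fin kinematics and muscle activity in a cylinder wake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finwake)
```

## The problem

Rainbow trout holding station behind a D-section cylinder sit inside a von
Kármán vortex street. In that flow they show two stereotyped pectoral-fin
behaviors: *braking*, where both fins are abducted against the flow to
arrest an upstream drift into the cylinder's suction zone, and *Kármán
gaiting*, where the body slaloms between shed vortices at the shedding
frequency and single fins make quick, often asynchronous extensions that
steer the body laterally. Strikingly, fin extension in this regime does not
imply muscle activity: fins can be moved passively by the low pressure of
passing vortices, held against vortex suction by their antagonist muscle,
or driven conventionally by their agonist.

`finwake` implements the measurement chain for this system — ventral-view
pose tables (DeepLabCut CSV dialect; 7 midline points, 5 points per fin, at
150 frames s⁻¹) and 4-channel fin-muscle EMG — together with a
synthetic-trial generator that plants known events, bursts and velocity
profiles so every stage of the chain can be validated end to end. The
original recordings behind this kind of experiment are typically not
deposited; the generator is therefore a first-class part of the package,
not a test fixture.

## Coordinate and interval conventions

The cylinder center is the origin; x increases downstream and y is lateral
(positive toward the fish's right in ventral view). Forward (upstream)
motion therefore has negative x-velocity, so a braking approach prints a
negative velocity followed by a positive one. Frames are 0-based, the time
of frame *k* is *k*/frame_rate, and all event intervals are half-open
[onset, offset): the offset is the first frame after the run.

## The kinematic chain

**Smoothing.** Tracked points are smoothed with a centered moving average
whose window is 20% of the frame rate (30 frames, 0.2 s, at 150 fps). At
the edges the window shrinks to the available samples so length is
preserved. The filter attenuates extrema — a conservative estimate of
maxima and minima — and has a sinc-shaped frequency response: gain ≈ 0.50
at 3 Hz and a null at 5 Hz for a 0.2 s window. That has two consequences
the package is explicit about:

* **Body-wave metrics are computed on the unsmoothed track.** The tail-beat
  oscillation whose amplitude and wavelength the gait criteria measure sits
  at 2–5 Hz, exactly where the smoother attenuates or annihilates signal.
  Smoothing is applied where it matters for the analysis: the fin-extension
  series and the COM position before differentiation.
* **Velocity estimates are blurred by ±0.1 s** around any change, which the
  generator takes into account (below).

**Fin extension.** Extension of a fin is the perpendicular distance from
the fin tip (fin point 3) to the infinite line through the two base points
(fin points 1 and 5), divided by body length L. The infinite line (rather
than the segment) matches the geometric definition of the fin base and is
differentiable everywhere; the absolute distance makes the metric
rotation- and translation-invariant. Base points closer than 10⁻⁶ cm give
a missing value for that frame rather than an arbitrary number.

**Event detection.** Frames with extension ≥ 0.05 L form events. Maximal
above-threshold runs separated by gaps shorter than 2 frames are merged
first (hysteresis against single-frame dropouts), then runs shorter than
3 frames are discarded; both knobs are exposed. `t_max` is the earliest
argmax in the run. Likelihood-gated points (below a 0.9 floor) are
linearly interpolated across gaps of at most 5 frames — the automated
surrogate for manual outlier correction — and longer gaps stay missing and
cannot join events.

**Synchronicity.** A left and a right event are simultaneous when their
overlap is at least 50% of the *shorter* event's duration — the strictest
symmetric reading of "50% overlap", exposed as a parameter since the
denominator (shorter, longer, or union) is a genuine choice. Pairing is
greedy by largest overlap with each event used at most once.

**Bout classification.** Kármán gaiting requires all five criteria:
station holding (|net drift| ≤ 0.1 L), a traveling wave (per-point phase of
the lateral oscillation regresses on arclength with a significantly
nonzero slope; wavelength λ = 2π/|slope|), tail-tip lateral excursion
> 0.5 L, wavelength > 1 L, and no transient high-frequency tail beats
(> 10% of the bout with more tail energy above 1.5× the dominant frequency
than in the dominant band). Braking requires net upstream drift, a forward
velocity excursion below −1 cm s⁻¹ followed within 0.5 s by a rise above
+1 cm s⁻¹, no sustained tail oscillation, and no whole-body undulation.
Rigid-body sway (all points in phase) reports an infinite wavelength with
a dedicated flag: the wavelength criterion is then trivially satisfied but
the traveling-wave criterion is not. Oscillation itself is declared by a
Fisher-g-style test on the tail spectrum (peak/mean above a size-dependent
threshold holding the white-noise false-alarm rate near 1%) — a plain
peak-to-median rule proved too permissive on noise-only spectra.

## The EMG chain

Channels are demeaned, then bandpass filtered with a 10th-order Butterworth
applied forward and backward (zero phase), so burst onsets are not delayed
— material when 0.2 s association windows are involved. The default band
mirrors the analog chain (100–3000 Hz) with the upper edge clamped to
0.45× the sampling rate.

The "spikes at least 25% of the mean spike amplitude" rule is circular as
stated (the spike population defines the mean that defines spikes). The
declared resolution is a two-pass rule: candidates are |signal| peaks above
`noise_k` (default 5) times a MAD-based noise floor with a 2 ms refractory
spacing; the mean spike amplitude is the mean absolute amplitude of the
candidates; the 25% threshold is then applied against that mean. Both
knobs are exposed. The rule is scale-invariant and monotone in the
threshold by construction.

Spikes with inter-spike intervals ≤ 50 ms group into bursts (onset = first
spike, offset = last; singletons span one refractory period). The
channel-sweeping wrapper drops bursts with fewer than 2 spikes: an
isolated exceedance is overwhelmingly a noise or movement artifact, and
this is the automated surrogate for visually vetting raw traces. No
digital 60 Hz notch is applied by default, since an analog notch is
assumed upstream.

## Coupling and statistics

Pre/post velocities are means over [t_max − 0.2 s, t_max) and
(t_max, t_max + 0.2 s]; windows truncated by the record edge are computed
when at least half the window exists, and flagged. The pre/post comparison
standardizes the paired differences, checks normality against a standard
normal with a one-sample Kolmogorov–Smirnov test, then runs a paired
two-tailed Student's t-test — paired because pre and post belong to the
same event; an unpaired variant would discard that structure. Raw p-values
are reported without multiplicity correction, matching the small number of
planned tests; zero-variance differences are reported as degenerate rather
than producing an undefined statistic.

Each event is split at `t_max` into an abduction phase [onset, t_max] and
an adduction phase [t_max, offset]. Per phase, overlap of the ipsilateral
muscles decides the pattern: agonist only → *active*; neither → *passive*
(vortex-driven fin movement); antagonist only → *resistive*; both →
*active* with a co-contraction flag (reported, not collapsed, because
braking characteristically co-activates abductor and adductor). Muscle
association windows use the same 0.2 s on either side of `t_max`, per
muscle and side.

## What the generator emulates — and what it does not

A Kármán-gait trial oscillates midline point *i* at arclength *s·L* as
`A(s)·sin(2πft − 2πsL/λ)` about a drifting COM, with the shedding
frequency f = St·U/D (St = 0.2). The amplitude envelope is linear from
0.02 L at the snout to **0.28 L** at the tail tip. The tail amplitude was
set just above 0.25 L because a 0.25 L amplitude yields a peak-to-peak
excursion of exactly 0.5 L, which sits *on* the strict `> 0.5 L` gait
criterion; 0.28 L keeps the default trial unambiguously inside the
criterion without depending on noise. The default wavelength is 1.2 L.
Published data do not include amplitude envelopes or wavelengths for
individual fish; these defaults are declared stand-ins at the plausible
end of the criteria's ranges.

Fin geometry is exactly controllable: base points ride the body wall
0.08 L apart, and the tip is displaced perpendicular to the base following
a triangular profile whose 0.05 L crossings *are* the planted onset and
offset. Piecewise linearity in a ±0.1 s neighborhood of each crossing
makes the crossing time invariant under the moving-average smoother, so
"recover the planted onset within 2 frames" is well-posed under the
default smoothing.

A braking trial drives the COM with an upstream plateau velocity, a
reversal at `brake_time`, and a downstream plateau. Because the 0.2 s
smoother blurs a velocity step across the window boundary (a leak of ≈ d/8
of the jump in the continuous limit), the generator solves for the plateau
velocities by pushing a unit step through the *exact discrete* measurement
operator — trapezoid position integration, the same moving average,
central differences, the same window means — so that the chain returns the
configured pre/post targets (−4 and +3 cm s⁻¹ by default). Ground truth
records those window-mean targets. Velocity-recovery checks evaluate the
windows at the ground-truth `t_max`: the detected `t_max` can jitter by a
frame or two, which slides the windows across the blur and would test
event localization, not the velocity estimator.

EMG bursts are trains of 2 ms biphasic spikes (one sine period; 500 Hz
fundamental, inside the default band at the 5 kHz default sampling rate)
at a planted rate and amplitude over Gaussian baseline noise. The default
amplitude is 12× the baseline s.d. Noise is independent per sample and per
coordinate; there is no autocorrelated digitization error, no fin-shape
deformation, no hydrodynamic coupling between body and fin, and no vortex
field — the wake enters only through the frequency, amplitude, and the
planted passive/active event structure. Passing tests therefore establish
that the measurement chain is correct and calibrated, not that it is
robust to every artifact of real video.

One published constant is ambiguous: the EMG digitization rate is printed
as "1000 kilosamples s⁻¹" alongside a 3000 Hz analog high cutoff. The
package treats the EMG rate as required metadata; the generator's default
is 5000 samples s⁻¹, which represents both the spike waveform and the
analog bandwidth. At the spec'd Strouhal default of 0.2, the slowest
experimental flow (45 cm s⁻¹) gives 1.8 Hz, marginally below the nominal
"~2–5 Hz" band — the published band is approximate and implies an
effective Strouhal nearer 0.22; the default keeps St = 0.2 and the checks
read the band edge as approximate.

## Problem sizes and calibration choices

Cohort validation uses 200 seeded trials per behavior at default noise for
label recovery (≥ 95% required; observed 100%), planted event timing
(within 2 frames), burst timing (within 20 ms at 12× noise amplitude) and
braking velocity recovery (within 10%). Statistical calibration uses an
event-level pair simulator (per-event s.d. 3.5 cm s⁻¹, consistent with
standard errors near 0.3 cm s⁻¹ at cohorts above 100 events): 2,000 null
cohorts of 20 events for the type-I error (required within [0.03, 0.07])
and 200 cohorts of 50 events for power against the planted lateral flip
(+1.8 → −2.3 cm s⁻¹; required ≥ 0.9). Full-trial simulation is reserved
for the recovery checks where the whole chain matters.

## A worked example

```{r example}
meta <- trial_meta(body_length_L = 21.7, flow_speed_U = 65)
trial <- simulate_trial(default_synth_config("karman_gait", meta, seed = 1))
res <- suppressWarnings(analyze_trial(trial$pose, trial$emg, meta))
res$bout$label
res$events[, c("side", "onset", "offset", "t_max", "peak_extension",
               "synchronicity", "zone")]
res$bursts
res$coupling[, c("side", "pattern_abduction", "pattern_adduction",
                 "onset_any")]
```

## Known limitations

* The wavelength estimator assumes a single dominant frequency; multi-modal
  gaits would need a band-limited phase estimate per mode.
* The activation taxonomy uses binary overlap; it does not weigh burst
  intensity or timing within a phase.
* Zone boundaries for event positions (suction zone within 15 cm downstream
  and 3 cm lateral; wake to 30 cm) are configuration, not inference.
* The generator's noise model is white; DeepLabCut errors in real video are
  bursty and correlated with occlusion, which is only partially emulated by
  the likelihood-gating path.
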