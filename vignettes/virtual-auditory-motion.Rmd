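---
title: "Rendering and analysing quantized auditory motion in virtual auditory space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rendering and analysing quantized auditory motion in virtual auditory space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasmotion)
```

## The problem this package addresses

Moving sound sources presented over headphones are almost always an
illusion assembled from stationary pieces: a bank of binaural impulse
responses is measured at discrete azimuths, the source signal is convolved
with each filter in turn, and the segments are concatenated so the image
appears to glide across space. Two engineering choices shape that illusion —
the *spatial quantization* of the filter grid (how many degrees separate
adjacent filters) and whether the filters are *anechoic* (head-related
impulse responses, HRIRs) or carry *room reflections* (binaural room
impulse responses, BRIRs). `vasmotion` provides an end-to-end simulation of
a psychophysical experiment built on exactly these choices: it synthesises
the filter banks, renders spatially quantized audio-visual motion, verifies
the acoustics of the synthetic room, simulates forced-choice observers
judging which modality leads, and estimates the psychometric quantities
(point of subjective equality and slope) that such an experiment reports,
together with their bootstrap confidence limits and a repeated-measures
ANOVA across conditions.

The package deliberately contains *no human data*. Every stage that would
involve a measurement in the laboratory — the HRIR robot arm, the in-situ
BRIR recording, the human subject — is replaced by a synthetic, fully
parameterised stand-in whose ground truth is known, so that the analysis
machinery can be validated by parameter recovery rather than by eye.

## The experimental design being simulated

The simulated task pairs a moving visual reference (fixed trajectory from
−70° to +70° along the frontal horizon) with a moving auditory stimulus
displaced by a signed spatial offset $\mu$ along the motion direction.
Positive $\mu$ is an auditory lag (the visual stimulus leads in space).
Both stimuli move at one of three velocities — 25, 50 or 100 °/s — and the
auditory motion is quantized at steps of $\theta = 1°$ or $5°$. Each
velocity has a fixed set of nine offsets:

| velocity (°/s) | offsets $\mu$ (°) |
|---|---|
| 25 | 0, ±1.25, ±2.5, ±5, ±10 |
| 50 | 0, ±2.5, ±5, ±7.5, ±10 |
| 100 | 0, ±5, ±10, ±15, ±20 |

A block is ten passes over the nine offsets (90 trials), offset order
shuffled within each pass and motion direction strictly alternating between
trials. The observer reports the leading modality (2AFC). Because the nine
offsets per pass are an odd count, the pass boundary parity flips every
cycle, which spreads each offset close to evenly over the two directions;
exact direction balance per offset is not enforced (the design only demands
alternation).

Counting every occupied grid position (both endpoints included) for one
dwell of $\theta/v$ seconds reproduces the design's printed durations for
the 5° grid: 29 positions × 0.2/0.1/0.05 s = 5.8, 2.9 and 1.45 s at the
three velocities. On the 1° grid the same rule gives 141 × 1/25 = 5.64 s at
25 °/s, not 5.8 s; the sources for this design do not say how (or whether)
the 1° condition's duration was equalised, so the package keeps the single
transparent counting rule and does not guess — durations are whatever
`total_duration()` computes from the rule.

## Synthetic spatial filters

### Anechoic pairs (`synth_hrir`)

Individualised measured HRIRs cannot be shipped, so the anechoic filter is
a spherical-head model that preserves the two binaural cues the experiment
manipulates across azimuth:

* **ITD** — the Woodworth rigid-sphere formula
  $\mathrm{ITD}(\theta) = \frac{a}{c}(\theta + \sin\theta)$, with head
  radius $a = 0.0875$ m and $c = 343$ m/s, applied as a windowed-sinc
  fractional delay (so ITD varies smoothly, not in whole samples). At 90°
  this gives ≈656 µs.
* **ILD** — a first-order single-pole/single-zero head-shadow filter
  (high-shelf gain ≈2 toward the near ear, deep attenuation ≈0.1 on the far
  side, corner frequency $2c/a$), the standard first-order spherical-head
  approximation.

At azimuth 0 the two ears are identical by construction, which several
tests exploit. The model omits pinna cues, torso reflections and
measurement noise; consequences are discussed under *Limitations*.

### The room and its reverberant pairs (`room_spec`, `image_source_brir`)

The design names only two facts about the recording room: its volume
(17 m³) and its reverberation time (RT60 ≈ 200 ms). Everything else is this
package's choice, made once:

* **Dimensions 3.4 × 2.5 × 2.0 m** — an unremarkable small listening room
  with the right volume.
* **Uniform wall absorption from Sabine's equation**,
  $\alpha = 0.161 V / (S\,\mathrm{RT60}) \approx 0.337$ for the default
  room — a single coefficient on all six surfaces.
* **Listener at (1.3, 1.15, 1.2) m**, facing the long axis, sources on a
  1 m frontal arc. Two considerations fix this point. First, ear height
  1.2 m under a 2 m ceiling puts the nearest image (the ceiling) at a path
  of 1.887 m, i.e. 2.58 ms after the direct sound — inside the 2–3 ms
  first-reflection gap the simulated room is meant to show. Second, the
  three wall distances are deliberately *pairwise distinct*: a listener
  placed symmetrically (equal distances to floor and a side wall, or
  centred between side walls) makes distinct mirror images exactly
  coincident in time, so weak arrivals stack into spuriously prominent
  peaks — a measure-zero degeneracy that real, furnished rooms do not
  exhibit and that corrupts peak-based metrics. Slightly asymmetric
  placement is therefore the more faithful stand-in, not a tuning.
* **Image-source synthesis with amplitude reflection coefficient
  $\sqrt{1-\alpha}$ per bounce** and spherical $1/d$ spreading (referenced
  to 1 m). The square root matters: $\alpha$ is an *energy* absorption
  coefficient, so amplitude must lose $\sqrt{1-\alpha}$ per bounce for the
  rendered decay to match the Sabine/Eyring prediction; applying
  $(1-\alpha)$ to amplitude would halve the reverberation time. Each
  arrival is spatialised through the spherical-head model at its lateral
  arrival angle (front–back direction does not matter to a spherical
  head), with filters cached on a 1° angle grid for speed; the direct path
  uses the exact azimuth.
* **Reflection order default 3** for the rendered BRIRs: enough to populate
  the first ~21 ms densely at this room size. Validation of the decay uses
  a deeper render (order 34, 150 ms), since RT60 needs 35 dB of decay.
* **Truncation** keeps the 21 ms after the direct onset (1008 samples at
  48 kHz) and applies a 1 ms raised-cosine fade at the cut; a hard cut
  would splatter broadband energy across the spectrum. The onset is the
  first sample within 20 dB of the peak.

The Schroeder backward-integration estimate of the default room's RT60
lands near 216 ms — within the ±25 % band one can expect given that Sabine
is itself an approximation to the image-source decay.

### The simulated measurement chain (`ess_generate`, `ess_deconvolve`)

Real filter banks are measured with exponential sine sweeps and recovered
by deconvolution. The package simulates this chain: a logarithmic sweep
with a 2 ms raised-cosine taper at each end, and an inverse filter built by
regularised spectral inversion with a flat unity target across the sweep
band and a third-octave raised-cosine roll-off outside it. This inverse
*is* the classical amplitude-compensated time-reversed sweep up to an
in-band equalisation; the spectral construction was chosen because the
plain time-reversed form leaves a few-percent in-band ripple and scale
error, while the round trip through the regularised inverse recovers a
known 21 ms filter with in-band relative L2 error near $10^{-4}$. A delay
margin keeps the inverse's slightly anti-causal high-frequency end from
wrapping circularly. Deconvolution extracts the response at a known
zero-lag index; recovering the band-limiting pre-ringing requires asking
for ~20 ms of pre-onset window (`pre` argument), which the tests do.

Passing every reverberant filter through this chain is available behind
`build_filter_set(ess_roundtrip = TRUE)` but is off by default — it is a
fidelity check on the measurement simulation, not part of rendering.

## The carrier and the rendering rule

The source signal is white noise passed through a bank of 79 narrow bands
(centres 400–16 000 Hz every 200 Hz, each 100 Hz wide at −3 dB) and
multiplied by a common 20 Hz full-depth raised-sine envelope, which gives
all bands coherent amplitude modulation and encourages the bands to fuse
into one auditory object. Three literal-minded choices deserve note, all
resolved in favour of implementing the stated layout exactly: the band
spacing (200 Hz) exceeds the bandwidth (100 Hz), so the spectrum has gaps;
the bank starts at 400 Hz although the nominal noise band starts at
300 Hz, so nothing below 400 Hz survives; and the envelope starts at its
minimum with full (0→1) depth, since only the rate and the purpose of the
modulation are specified. The bands are realised as a zero-phase
raised-cosine-edged magnitude mask applied in the frequency domain — a
zero-phase FIR in effect — with the half-power point placed exactly at
±50 Hz from each centre.

Rendering slices the carrier into consecutive dwell-length segments, one
per occupied azimuth, convolves each slice with the filter pair at its
azimuth, and joins segments by **overlap-add of the convolution tails**:
the tail of each segment rings into the start of the next. For piecewise
time-invariant filtering this splice is exact — with the same filter at
every azimuth, segmented rendering equals one full convolution to machine
precision, which is the strongest oracle test the renderer has. A linear
crossfade join is available (`method = "crossfade"`) for comparison with
implementations that blend rather than add; it is not exact and is not the
default. Segment boundaries follow the cumulative rule
$b_k = \mathrm{round}(k\,\delta f_s)$, so rounding errors do not
accumulate: timing drift stays below half a sample over any trajectory.
Rendered stimuli are not normalised by default (normalisation would break
the exactness oracles); `normalize = TRUE` peak-normalises to −1 dBFS.

## Acoustic verification metrics

* **D/R** (`estimate_drr`): direct window from 0.5 ms before the main peak
  to 1 ms after it (configurable) — safely inside the default room's
  2.58 ms first-reflection gap — versus everything later;
  binaural pairs are scored per ear and averaged in dB. The anechoic
  spherical-head filters have almost no tail, so their D/R is very high
  (tens of dB, or infinite for a bare delay); what the pipeline relies on
  is the *ordering* — anechoic D/R strictly exceeds that of the matching
  truncated BRIR — not any particular value, which would depend on the
  physical measurement chain being simulated. Whether to score truncated
  or full BRIRs is left to the caller; both are meaningful and both are
  exercised.
* **RT60** (`estimate_rt60`): Schroeder backward integration, straight-line
  reading of the −5 to −35 dB span, RT60 = 2 × that span. If the response
  never reaches −35 dB the estimate extrapolates and warns.
* **Early reflections** (`detect_reflections`): local maxima after the
  direct peak above a −20 dB (default) threshold relative to it, thinned to
  a 0.25 ms separation floor so ringing inside one reflection is not
  counted twice. Binaural pairs are scored per ear against that ear's own
  peak — combining ears sample-wise would misread the far ear's
  ITD-delayed direct arrival (~0.4 ms at 45°) as a reflection — and then
  merged. Peak levels are returned alongside the times. The *major*
  reflections (the six strongest, the number visible in a measured example
  BRIR of such a room) fall inside the 21 ms preserved window; the package
  does not claim that *no* threshold-level arrival exists beyond 21 ms,
  because in any room with RT60 ≈ 200 ms the discarded tail is quiet but
  not silent.

## Observers and psychometrics

The simulated observer is *decision-level*: it never hears the rendered
waveform. Its probability of responding "vision leads" at offset $\mu$ is

$$\psi(\mu) = \lambda + (1 - 2\lambda)\,\Phi\!\left(\frac{\mu -
\mathrm{PSE}}{\beta}\right),$$

a cumulative Gaussian with symmetric lapse rate $\lambda \le 0.06$ at both
asymptotes. Symmetric lapses are the simplest model consistent with a 2AFC
judgment that has no objectively correct answer. The sign convention makes
the chain self-consistent end to end: an observer whose true PSE is
positive produces data whose fitted PSE is positive, i.e. a tendency to
judge the auditory stimulus as leading at physical alignment.

Fitting (`fit_pf`) is constrained maximum likelihood: $\beta > 0$,
$\lambda \in [0, 0.06]$, bounded quasi-Newton from five deterministic
starts (a probit-regression moment estimate plus spread and location
jitters), ties broken by likelihood then smaller lapse, with a Nelder–Mead
polish if a line search fails. Perfectly separated data are flagged
(`degenerate`) with $\beta$ at the lower optimizer bound rather than
rejected. The reported $\beta$ is the *standard-deviation* (spread)
parameter of the Gaussian in degrees — the only reading under which slopes
are comparable across velocities in common units — and its square is also
carried (`beta_var`) for anyone who prefers the variance reading of
"slope". Confidence limits come from a parametric bootstrap: synthetic
datasets drawn from the *fitted* $\psi$ at the observed offsets and trial
counts, refit from the parent estimate, 95 % percentile intervals (BCa was
judged unnecessary for interval widths at 90-trial blocks).

The two-way repeated-measures ANOVA (`rm_anova`) tests each within-subject
effect against its own subject-by-effect interaction term, with no
sphericity correction (the F and p values being emulated are plain
RM-ANOVA outputs); it is computed through `stats::aov` error strata and
verified in the tests against an explicit sums-of-squares decomposition.
Zero-variance tables return F = 0, p = 1 rather than 0/0.

## What the tests establish, and at what sizes

The suite validates each stage against an independent oracle: closed-form
ITD values, hand geometry for the nearest image source, brute-force
convolution for the renderer, an independently written likelihood plus
grid search for the fits, and an explicit mean decomposition for the
ANOVA. Stochastic guarantees use the sizes a desk-scale study affords, all
chosen as round numbers in advance: 100 simulated 90-trial blocks for PSE
recovery (median absolute error < 1°), 200 blocks × 200 bootstrap
replicates for interval coverage (observed ≈ 0.90), 1000 replicates for
ANOVA type-I error (observed ≈ 0.05 per effect), and a 6-subject
2-condition × 3-velocity null study for end-to-end sanity. The acceptance
script re-runs the same computations from scratch at the same sizes.

## Limitations

* The spherical-head filters carry no pinna or torso cues; simulated
  anechoic D/R is therefore far higher than any measured HRIR's, and
  absolute D/R values should not be compared against physical recordings —
  only the anechoic > reverberant ordering is meaningful here.
* The image-source room is empty, rigid-walled and frequency-independent
  in its absorption; real rooms scatter and absorb preferentially at high
  frequencies.
* Observers are decision-level. Nothing in the response stream reflects
  the waveform actually rendered, so these simulations validate the
  *analysis* pipeline (design → responses → fits → inference), not any
  auditory model of motion perception. Connecting rendered waveforms to a
  model observer is future work.
* Passing tests on synthetic data show the machinery is correct and
  calibrated, not that a human experiment would yield any particular
  result.
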