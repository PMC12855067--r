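---
title: "Methods: spike-and-wave discharge analysis in rodent sleep EEG"
author: "somnispike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-and-wave discharge analysis in rodent sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somnispike analyzes 24-h mouse EEG/EMG recordings for spontaneous
spike-and-wave discharges (SWDs): brief, high-voltage, rhythmic cortical
events with a ~6.7 Hz fundamental and a second spectral component near
13.3 Hz, occurring overwhelmingly during slow-wave sleep (SWS) and with a
pronounced circadian rhythm that peaks near the light-to-dark transition
(ZT12 on a 12:12 light/dark cycle). This vignette documents the models,
the tunable parameters, and the design decisions behind each stage, and
states what the synthetic validation can and cannot show.

## Data model

A recording is a set of equal-length channels (microvolts) with roles
`EEG_frontal`, `EEG_parietal`, `EMG`, a sampling rate, and a Zeitgeber
anchor `start_zt` (hours since lights-on at sample zero). Vigilance is a
hypnogram: one label per 10-s epoch over WAKE/SWS/REM/ARTIFACT, where
epoch *e* covers the half-open interval [10e, 10e+10) s and ARTIFACT
epochs are excluded from every downstream denominator. Events are
half-open intervals [onset, offset) with the vigilance state of their
onset epoch. All on-disk times are seconds from recording start; ZT is
always derived, never stored, so there is a single source of truth for
time. Signals travel as EDF (16-bit; a JSON sidecar carries the ZT anchor,
since EDF's own clock is wall time), hypnograms and events as plain CSV.

## Preprocessing

The acquisition chain is reproduced digitally: EEG band-passed
0.3-70 Hz, EMG high-passed at 10 Hz, both notched at 50 Hz (Q = 30).
Filtering is zero-phase so marked event boundaries carry no group delay;
it is realized in the frequency domain as the |H(f)|^2 response that a
forward-backward Butterworth pass applies, computed in overlapping FFT
chunks with reflected edges. At sampling rates where a corner is not
realizable (e.g. 100-Hz simulations cannot hold a 70-Hz low-pass),
`adapt_filter_spec()` lowers the corner to 40% of the rate and drops an
unrealizable notch; the analyses here concern 0.5-30 Hz, which both
configurations pass identically.

Artifact tagging is a stand-in for manual screening, which real studies
apply by eye: an epoch is relabeled ARTIFACT when |EEG| exceeds 10 times
the recording's median absolute deviation for at least 0.5 s cumulative,
or contains clipped samples. Both constants are exposed; the pre-tagging
labels are kept in a shadow field. The rule is deliberately conservative
— exclusion only, no signal repair.

## Synthetic recordings with ground truth

Because validating detection and attribution requires truth no real
recording provides, the generator is a first-class module. It is
phenomenological, not biophysical: it reproduces the statistical
structure of the target data, not thalamocortical dynamics.

**Vigilance states.** An inhomogeneous Markov chain over WAKE/SWS/REM at
10-s resolution with separate lights-on and lights-off transition
matrices. The defaults were calibrated by solving the phase-wise stationary
distributions to a 24-h composition of ~50% SWS and ~5% REM with sleep
concentrated in lights-on, a polyphasic bout structure (mean SWS bouts
of ~3 min lights-on and ~2 min lights-off, several hundred transitions
per day), and REM entered only from SWS. One deliberate liberty: REM
bouts are long (~5 min, versus ~1-2 min in real mice) so that REM
cycling does not dominate the baseline transition rate — the coupling
ratio below is a stated calibration target, per-state bout durations
are not, and the two cannot both match real mice at the pinned
awakening hazard of 3 (the ratio is structurally
~0.67 x hazard-boost + 0.26 under transition-flow balance, independent
of overall bout scaling).

**Events.** Conditional on the state sequence, SWD counts per epoch are
Poisson with state intensities 7.3/h in SWS, 0.43/h in WAKE, 0.77/h in
REM — chosen so the affected-strain profile yields ~93 events/day split
~94%/5%/1% across SWS/WAKE/REM — multiplied by a circadian factor
`c(t) = exp(beta cos(2 pi (t - 12)/24)) / I0(beta)` with `beta = 1.24`,
which is strictly positive, has daily mean 1, and makes the SWS-rate
ratio between the ZT11-12 and ZT5-6 bins equal to
`exp(1.24 (cos(-pi/24) - cos(-13 pi/24))) ~ 4`. Control profiles scale
the intensities (`ola_like`: 1.5/day; `c57_like`: none). Events are
placed uniformly within their epoch without overlap and may spill into
the next epoch; their attributed state is the onset state.

**Coupling.** In the epoch following an SWD-containing SWS epoch,
P(SWS to WAKE) is multiplied by the awakening hazard (default 3; row
renormalized). The hazard acts on one epoch only, matching an
epoch-lagged conditional-probability analysis. Under the calibrated
matrices this yields a transition-probability ratio (SWD-containing vs
SWD-free epochs) of ~2.3; with hazard 1 the ratio is 1 by construction,
which the tests verify as a null property. A power note: each event adds
only ~0.06 expected transitions, while day-to-day transition counts vary
with SD ~16, so the between-animal fragmentation correlation is weak at
realistic cohort sizes; the property test uses a 36-animal cohort
spanning a wide severity range (20-600 events/day) where direction and
significance are stable.

**Waveform.** Each discharge is
`A1 sin(2 pi f0 t) + 0.45 A1 sin(2 pi f1 t)` with f0 = 6.73 Hz and
f1 = 13.28 Hz under a raised-cosine envelope (0.1-s ramps). The second
component is set independently rather than at exactly 2 f0 because the
measured second peak of such discharges is not an exact harmonic.
Durations are log-normal (arithmetic mean 2.0 s, log-SD 0.25) truncated
to [4/f0, 6] s, so every event satisfies the 4-cycle criterion by
construction; `A1` is 2.5 times the RMS of the surrounding state's
background EEG. Background EEG is a per-state mixture of three
unit-variance noise streams (delta-emphasized 40/8/10 uV for SWS,
broadband 8/10/12 uV for WAKE, theta-dominant 5/25/8 uV for REM) and the
EMG is high-passed noise at 30/8/3 uV RMS for WAKE/SWS/REM. Streams are
synthesized spectrally in seamless equal-power-crossfaded chunks; all
randomness flows from one seeded generator, so fixtures are
bit-reproducible. Known omissions: no precursor oscillations before
discharges, no EMG movement artifacts, no mains interference by default
(an optional `mains_hz` exercises the notch), and state-conditional
backgrounds that are far more stereotyped than real cortex.

**What passing tests show.** Recovery of counts, state shares, peak
frequencies, durations, circadian parameters and the coupling ratio on
this generator demonstrates that the analysis chain is correct and
internally consistent at realistic SNR. It does not demonstrate
performance on real recordings, where artifact structure, inter-animal
variability and non-stationary backgrounds are richer; the detector's
configurable criteria and the review-export path exist for that setting.

## Sleep scoring

A transparent three-rule classifier per 10-s epoch, using band powers
from the per-epoch Welch PSD (2-s Hanning, 0.5-s overlap — the same
estimator as the event spectra) and EMG RMS: WAKE if EMG RMS exceeds the
muscle-tone threshold; else SWS if the delta (0.5-4 Hz) fraction of
0.5-30 Hz power reaches the delta threshold; else REM if theta
(5-9 Hz)/delta reaches 2; else SWS. Auto-calibration sets the EMG
threshold at the midpoint of a 2-class k-means on log EMG RMS (falling
back, with a warning, to a fixed value if the distribution is not
bimodal) and the delta threshold at the 60th percentile of
sleep-candidate epochs. Scoring refuses recordings without EMG — WAKE
and REM are not separable from cortical EEG alone. Epochs containing
SWDs are scored from the same features, mirroring practice where
discharges occur inside scored SWS epochs. Against generator truth the
scorer agrees with >99% of epochs; against real, visually scored data a
rule this simple would do worse, which is why every attribution result
is also computed from ground-truth hypnograms in the tests.

## Discharge detection

The detector implements a permissive candidate pass followed by
acceptance criteria:

1. Band-pass 3-20 Hz (brackets both spectral components) and take the
   analytic envelope, smoothed by a 0.15-s moving average (averaging
   over the sub-cycle beat of the two-component waveform).
2. Background: rolling 60-s median of 1-s envelope levels, excluding
   ARTIFACT epochs, expanded per sample. The median is applied across
   blocks, where a 2-s discharge occupies only 2-3 of 60 blocks and so
   cannot inflate its own background.
3. Candidate cores where envelope >= 1.5 x background, merged across
   gaps < 0.3 s.
4. Cycle test: supra-threshold oscillation peaks whose successive
   intervals lie within [1/20, 1/3] s; the longest valid run must hold
   at least 4 peaks and span at least 0.45 s. Run ends far below the
   run's typical amplitude (threshold-grazing noise cycles chained onto
   the event) are trimmed.
5. Rhythmicity: the autocorrelation of the band-passed segment,
   evaluated at the run's own cycle period and at twice that period,
   must reach 0.65. Period hypotheses come from both the overall and the
   fastest-cluster median interval, each also tried at half and double
   (a strong second component doubles the peaks; weak alternate cycles
   halve them).
6. High-amplitude route: events whose smoothed envelope exceeds 4.5
   times background are accepted at a relaxed rhythmicity bar (0.4).
   The 1/n-normalized autocorrelation is deliberately conservative at
   the two-period lag on short segments — the price of suppressing the
   noisy estimates short noise bursts produce there — and brief
   discharges pay that price too; amplitudes 4.5 times background do
   not occur in stationary background, so amplitude substitutes for
   part of the rhythmicity evidence exactly where the latter is
   unstable.
7. Spike sharpness: power near twice the dominant frequency must be at
   least 8% of the power at the dominant frequency. Spike-wave
   complexes are sharp and carry a strong second component; smooth
   narrow-band oscillations such as REM theta bursts do not.
8. Boundaries extend to the zero crossings just beyond the first/last
   run peak; overlapping refinements collapse to one event. Events take
   the state of their onset epoch.

Criteria 1-4 are the permissive pass: on stationary noise they still
fire thousands of times per day, exactly the behavior that manual studies
resolve by visual inspection. Criteria 5-7 are this package's automated
stand-in for that inspection, and they are the deliberate design center
of the detector: they encode the properties a reviewer actually uses
(sustained rhythmicity; outsized amplitude; spiky, harmonic-rich
morphology) rather than any parameter of the synthetic waveform. With
defaults, validation runs show per-day recall ~0.98 and precision ~1.0
on affected-strain days and zero false positives across event-free
control days. Setting
`min_rhythmicity = 0` and `min_harmonic_ratio = 0` recovers the fully
permissive detector for use with the review export
(`export_review()` / `apply_review()`).

Invariants verified by tests: raising the amplitude threshold never
yields more events; detections are invariant under amplitude scaling of
the whole recording; every accepted event lies inside a permissive
candidate region.

## Event spectra

Each event's PSD uses Welch's estimator with 2-s Hanning windows and
0.5-s overlap; events shorter than one window use a single Hanning
window of the event length (the common case at ~2-s durations). The
overlap is read literally as 0.5 s, not 50%. Because a 2-s window alone
has 0.5-Hz bins, the FFT is zero-padded to a <= 0.1 Hz grid and peak
locations are refined by quadratic interpolation over the three bins
around each maximum; for noiseless sinusoids of >= 2 s this is accurate
to well under 0.05 Hz. The reference PSD is the same estimator over all
artifact-free epochs (windows never span epoch boundaries, so the
per-epoch average equals the concatenated estimate restricted to
within-epoch windows). Normalization is ratio-first, then
percent-of-total: event/reference per bin — the reference floored at its
1st percentile to keep the ratio finite — interpolated onto the common
0.1-Hz grid over 0.5-30 Hz and rescaled to sum to 100. Both
intermediates are retained. Peaks are the two most prominent local
maxima over a running-median baseline in 3-20 Hz, reported in ascending
order; cohort summaries report per-event-then-per-mouse averages and the
peaks of per-mouse mean spectra separately, since either convention is
defensible and they differ slightly.

## Architecture, interaction, circadian statistics

Bouts are maximal same-state runs of epochs; transitions are adjacent
label changes among artifact-free epochs. ARTIFACT epochs break runs
without creating transitions — inventing a transition across an excluded
gap would inflate fragmentation. The identity
`transitions = bouts - contiguous segments` is asserted on every
analysis. The SWD-sleep interaction uses any-overlap containment ("an
epoch containing an SWD") for conditional transition probabilities, with
onset-containment available as an option; the probability ratio carries
a seeded 1000-resample bootstrap CI as supplementary output.
Per-animal transition counts versus event counts give a Pearson
correlation with a two-sided t test on n-2 df.

Circadian statistics bin event onsets into 24 hourly ZT bins, normalized
per minute of SWS in each bin (rates are NA for hours without SWS). The
Rayleigh test maps ZT to phase, reports the mean resultant length R,
Z = nR^2, and the small-sample-corrected approximation
`p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))` (Zar 1999), pinned
because textbook approximations differ; its calibration is enforced by a
uniform-null Kolmogorov-Smirnov property test. The cosinor is ordinary
least squares of `M + bc cos(wt) + bs sin(wt)` at a fixed 24-h period,
fitted to hourly bin counts by default (matching how such profiles are
plotted), with amplitude `sqrt(bc^2 + bs^2)`, acrophase
`atan2(bs, bc) * 24/(2 pi) mod 24`, and a zero-amplitude F test on
(2, n-3) df. Recording days are analyzed separately; pooling requires an
explicit choice by the caller.

## Problem sizes and numerical choices

The validation suite simulates 24-h recordings at 100 Hz (the analyses
top out at 30 Hz, so this halves nothing of scientific interest; 400 Hz
is supported and used for the I/O and filter tests). The acceptance
cohorts are 8 affected animals (seeds 1-8) for counts, shares, peaks,
durations and circadian recovery; 20 scored animals for composition; 50
control animals for the control event rate; 50 hypnogram-level days for
the coupling ratio and its hazard-1 null; 200 replicates for the
Rayleigh calibration. Degenerate inputs are handled explicitly: zero
signal detects nothing; an all-ARTIFACT recording raises "no analyzable
epochs"; a constant series has cosinor amplitude 0 with a
null-compatible test; empty event tables flow through every stage.

## Limitations

The scorer is a surrogate for visual staging and inherits its
simplicity; micro-arousals shorter than an epoch are invisible by
construction. The detector's curation criteria were designed against
stereotyped synthetic noise; real artifacts (chewing, grooming) have
rhythmic components that may require retuning `min_rhythmicity` or human
review. The generator's circadian modulation is a single-harmonic
exponentiated cosine; real discharge rhythms can be skewed. No
between-strain inference is provided: group-level statistics beyond
summaries are intentionally out of scope.
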