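# somnispike

Analysis of spontaneous spike-and-wave discharges (SWDs) in 24-h mouse
sleep EEG/EMG recordings, for sleep and epilepsy researchers working with
rodent models of absence-like epilepsy and disturbed sleep.

SWDs are brief, high-voltage rhythmic cortical events — operationally, a
discharge pattern of at least 4 cycles at an amplitude at least 1.5-fold
above the background EEG — with a theta-range fundamental (~6.7 Hz) and a
second spectral component near 13.3 Hz. They occur almost exclusively in
slow-wave sleep (SWS), follow a circadian rhythm peaking near the
light-to-dark transition (ZT12), and couple to sleep fragmentation: state
transitions are more than twice as likely after an epoch containing a
discharge. somnispike implements the full analysis chain:

- **I/O**: EDF signals (16-bit, JSON sidecar for the Zeitgeber anchor),
  CSV hypnograms (10-s epochs, WAKE/SWS/REM/ARTIFACT), CSV event tables.
- **Preprocessing**: zero-phase acquisition-chain filters (EEG 0.3-70 Hz,
  EMG high-pass 10 Hz, 50-Hz notch) and MAD-based artifact tagging.
- **Sleep scoring**: a transparent rule-based stager (EMG tone, delta
  fraction, theta/delta ratio) with auto-calibrated thresholds.
- **SWD detection**: permissive amplitude/cycle candidate pass over the
  3-20 Hz analytic envelope against a rolling-median background, plus
  rhythmicity and spike-sharpness acceptance criteria that stand in for
  visual curation; a review-export path for human audit.
- **Event spectra**: Welch PSD (2-s Hanning, 0.5-s overlap) per event,
  normalized against the whole-recording artifact-free PSD, rescaled to
  percent of total, with sub-bin extraction of the two characteristic
  peaks.
- **Sleep architecture and interaction**: time in state, bouts,
  transition pairs, fragmentation, state attribution of events,
  conditional transition probabilities around SWD epochs, and the
  fragmentation-discharge correlation.
- **Circadian statistics**: hourly ZT histograms normalized per minute
  of SWS, the Rayleigh uniformity test (Zar's approximation), and a
  fixed-period 24-h cosinor (MESOR, amplitude, acrophase).
- **Synthetic generator**: 24-h EEG/EMG recordings with ground-truth
  hypnograms and event tables, calibrated to an affected strain
  (~93 discharges/day, ~94%/5%/1% SWS/WAKE/REM, 4-fold ZT11-12 vs ZT5-6
  SWS-rate ratio, awakening hazard 3) and control strains (~1.5 or 0
  events/day), so every stage is validated against known truth.

The model at the core of the cosinor stage is
`y(t) = M + A cos(2*pi*(t - phi)/24)` fitted by least squares; the
circadian intensity of the generator is the exponentiated cosine
`c(t) = exp(beta*cos(2*pi*(t - 12)/24))/I0(beta)`, `beta = 1.24`. The
detection criteria (1.5x background, >= 4 cycles) and the Welch settings
(2-s Hanning, 0.5-s overlap) are the field-standard definitions; see the
methods vignette (`vignettes/somnispike-methods.Rmd`) for every design
decision and parameter.

## Worked example

```r
library(somnispike)

# one simulated affected animal, 24 h at 100 Hz, analyzed end to end
a <- run_animal("jax_like", seed = 1)

nrow(a$events)                       # 95 detected discharges
round(a$mean_event_duration_s, 2)    # 1.84 s mean duration
round(c(a$peak1_hz, a$peak2_hz), 2)  # 6.76 13.27  (spectral peaks, Hz)
round(a$attribution$state_shares_pct, 1)
#  SWS WAKE  REM
#  100    0    0                     (% of events by vigilance state;
                                     #  this animal's few WAKE-state
                                     #  events fell below threshold)
round(a$interaction$ratio, 2)        # 3.03  P(transition | SWD epoch)
                                     #       / P(transition | clean epoch)
round(a$circadian$cosinor$acrophase_h, 1)  # 11.7 (ZT of peak event count)
round(a$detection_eval$recall, 2)    # 0.99 against generator ground truth
round(a$scoring_eval$accuracy, 3)    # 1     epoch agreement with truth
```

Numbers above are what this exact call prints (seeded); your platform
should reproduce them bit for bit. `run_cohort()` repeats this across
seeds and returns a per-animal summary table; `make_report()` renders it
to Markdown. For real recordings, start from `read_edf()` and
`analyze_recording()`.

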