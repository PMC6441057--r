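---
title: "Methods: sleep staging, spectral connectivity and ripple-spindle coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging, spectral connectivity and ripple-spindle coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sleepcouple` implements a complete analysis chain for multichannel rodent
sleep electrophysiology: rule-based sleep staging from a cortical screw EEG
and an EMG channel, Welch spectra with 1/f whitening, interregional
magnitude-squared coherence, theta-gamma phase-amplitude coupling, CA1
sharp-wave-ripple detection, and ripple-triggered cortical spindle-band
power with group statistics. Because analyses of this kind are usually
validated against recordings that cannot be shared, the package ships a
synthetic generator that produces multichannel recordings with exact ground
truth; every claim the test suite makes is a recovery claim on that
generator. This vignette explains each method, the tunable parameters, the
design decisions taken where the procedures are conventionally
underspecified, and what validation on synthetic data does and does not
establish.

## Sleep staging

Recordings are divided into 2-s bins. For each bin the cortical screw
channel's short-time Fourier content is estimated with 1-s Hamming windows
at 50% overlap inside the bin, averaged, and reduced to four band powers:
delta (1-4 Hz), theta (5-9 Hz), alpha (10-15 Hz) and gamma (30-48 Hz).
Delta and theta match the bands used for connectivity; the alpha and gamma
edges are the package's own choice (the gamma edge stops below the 50-Hz
line). The EMG feature is the maximum, within the bin, of a 50-ms
moving-average rectified-EMG envelope.

Classification applies, in order of precedence:

1. **Movement** - EMG envelope maximum above a threshold, by default 2 times
   the standard deviation of the rectified EMG over the whole recording.
   An absolute override (`staging_thresholds(emg_threshold = )`) stands in
   for per-animal adjustment against video. The reference is the SD of the
   rectified signal rather than of the bin-wise maxima: the latter collapses
   to near zero on recordings without movement, which would label every bin
   as movement.
2. **REM** - theta/delta ratio above twice its recording mean.
3. **NREM** - alpha/gamma ratio above its recording mean.
4. **Waking immobility (WI)** - everything else.

When a bin satisfies both the REM and NREM criteria, REM wins: its
threshold (twice the mean) is the stricter, more specific criterion. Two
merging passes then relabel single gap bins: a non-movement bin flanked by
REM bins becomes REM if its theta/delta ratio is still above the mean, and
a non-movement bin flanked by NREM bins becomes NREM if its alpha/gamma
ratio is not below half the mean. The passes iterate to a fixed point, so
merging is idempotent.

For state-dependent analyses, matched 20-s epochs are selected per REM
bout: the first 10 REM bins form the REM segment; the 10 bins immediately
before REM onset are excluded as the transitional pre-REM period (their
labels are deliberately unconstrained - the exclusion is about the
transition, not about what the classifier called those bins); the 10 bins
before that must all be NREM and form the matched NREM segment.

## Spectra

`welch_psd()` estimates one-sided power spectral density from 2-s Hamming
windows at 50% overlap (19 segments per 20-s epoch), mean-removed per
segment, normalized so the density integrates to the signal variance. The
0.5-Hz grid resolves the 1-4 Hz delta band. Whitening multiplies the
density by frequency, flattening the 1/f background. Line interference is
handled by masking (default 50 +/- 1 Hz): masked bins are excluded from band
integrals, band coherence averages and group statistics rather than
filtered out, so no estimate is contaminated by interpolation.

## Magnitude-squared coherence

`msc()` computes `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` from
Welch-averaged auto- and cross-spectra with the same segmentation as the
spectra (19 segments per 20-s epoch). The magnitude-squared form is used
because it is the estimator bounded in [0, 1] for all inputs. Two
estimator facts matter for interpretation and are covered by tests: a
single segment gives coherence identically 1 (the function refuses to
compute it), and for independent signals the estimator is biased upward by
about 1/K, here 1/19 ~ 0.053 - band means of independent channels sit near
that floor, not at zero. Coherence spectra are averaged across epochs
within animal and state before band averaging (delta, theta, spindle
10-18 Hz, high beta 19-30 Hz); the animal is the experimental unit.

## Phase-amplitude coupling

`modulation_index()` implements the Kullback-Leibler modulation index: both
bands are extracted with zero-phase band-passes, phase comes from the
analytic signal of the slow band and amplitude from the envelope of the
fast band; mean amplitude is binned into 18 phase bins, normalized to a
distribution, and the MI is the KL divergence from uniform scaled by
log(18), hence bounded in [0, 1] and exactly 0 for a flat envelope. The
KL-based variant was chosen over mean-vector-length alternatives because it
is bounded and robust to bin count. REM segments of one animal are pooled
at the phase-bin histogram level - filters never see concatenation joins.
The comodulogram grid spans phase 2-12 Hz (2-Hz bands) by amplitude
20-120 Hz (20-Hz bands); the 20-Hz amplitude bandwidth accommodates the
modulation sidebands of phase frequencies up to ~10 Hz. The per-animal
summary is the mean MI over the high-coupling region, phase 7-8 Hz by
amplitude 60-90 Hz.

All band-pass filtering in the package is zero-phase by construction:
frequency-domain multiplication with unit passband gain and raised-cosine
transitions. On segments of tens of seconds the circular wrap-around is
confined to the segment edges; PAC trims 0.25 s per segment edge before
binning.

## Sharp-wave-ripple detection

The detector band-passes the CA1 channel to 150-250 Hz, squares it,
smooths over 10 ms, and z-scores against the mean and SD over all NREM and
WI samples of the session (movement is excluded because EMG contaminates
the ripple band; session-wide rather than per-epoch baselines keep the
z-scale comparable across events). Candidates are contiguous regions above
2 SD with boundaries at the crossings; candidates closer than 20 ms are
merged; events must last 50-100 ms; and in the default `"band"` mode the
peak z must lie within [2, 5] - reading "2 to 5 SD" as an acceptance band.
The alternative `"fma"` mode (boundaries at 2 SD, peak must *exceed* 5 SD,
the FMAToolbox threshold-pair convention) is one switch away, because the
phrase is genuinely ambiguous. The intraripple frequency is the median
instantaneous frequency (analytic-signal phase derivative) inside the
event.

Manual screening of detections against spiking activity is replaced by an
automatic veto with two rules: an event is rejected when its
high-frequency-band (500-1000 Hz) z at the peak exceeds twice the
ripple-band z (a transient dominated by spike energy), or when the median
high-frequency z across the event exceeds 0.5 (sustained broadband power -
the signature of a merged burst of population spikes, which can otherwise
satisfy the duration window). Both thresholds are `ripple_config()`
parameters. Below a sampling rate of ~1.1 kHz the veto band collapses and
the veto is skipped.

## Ripple-triggered cortical coupling

Only NREM ripples trigger cortical averages, and each animal contributes at
most `cap` events (default 585, chronologically first) so animals enter
group comparisons with equal weight. The low-frequency triggered average
band-passes mFC to 1-50 Hz and averages +/-1-s windows around ripple peaks.
The spindle-power analysis band-passes mFC to 10-18 Hz, squares, smooths
over 100 ms (resolving 0.5-1-s spindle bursts), averages across events per
lag, and normalizes by the baseline: mean power over 2-s epochs centered at
the midpoints between consecutive used ripples. The peak normalized power
is the maximum within +/-0.5 s of the ripple peak. By default every midpoint
epoch is used, matching the plain description of the procedure; at high
event rates short inter-ripple gaps place some midpoint epochs inside the
peri-event window, so `exclude_within_s` optionally drops midpoints whose
epoch edges come within a guard distance of any used ripple - the
validation simulations use a 1-s guard for exactly this reason. The
inter-ripple baseline itself is reported per animal for the between-group
comparison of spindle power away from ripples.

## Group statistics

Spectra are compared per frequency bin with two-sample t-tests
(pooled-variance by default - the classic reading of "two-sample t-test";
Welch via a flag) and Benjamini-Hochberg FDR within one channel-by-state
panel. Band coherence is compared with permutation tests on the group
labels; when the number of distinct assignments does not exceed the
permutation budget (always, at these group sizes) the distribution is
enumerated exhaustively, making the p-value deterministic. BH families are
one per channel-by-state spectrum panel and one per state-by-pair band set
for coherence - the granularity at which such panels are conventionally
annotated. The BH step-up itself is delegated to `stats::p.adjust`; the
test suite checks it against a brute-force implementation of the step-up
definition.

## The synthetic generator

`generate_recording()` builds, per state bout: a 1/f pink background with a
shared component across neural channels (so interregional coherence is
nonzero and band-structured) plus white noise; NREM delta (2 Hz, shared
phase across channels with region gains), a continuous sigma rhythm and
discrete 13-Hz spindle bursts on cortical/thalamic channels; REM theta
(7.5 Hz, shared) with 60-90 Hz gamma on hippocampal channels whose
envelope is `1 + kappa * cos(theta phase)` - the standard construction
whose modulation index grows monotonically with kappa; EMG bursts during
movement; CA1 ripples (160 Hz) in NREM and WI at 9/min; and, when the
coupling gain `g > 0`, an mFC spindle burst at each ripple peak plus a
50-ms lag with amplitude proportional to `g`. A single master seed drives
everything; cohorts derive per-animal seeds deterministically.

Three design points deserve emphasis, because they are what make detector
validation well-posed rather than incidental:

* **Spiking background.** The CA1 channel carries a Poisson multi-unit
  spiking background (biphasic ~1-ms transients, 25/s). A pyramidal-layer
  electrode's high-frequency baseline is dominated by spiking; it is the
  reason ripple detections need screening against spikes at all, and it is
  what gives the detector's z-scale a realistic heavy-tailed baseline.
* **Calibrated, well-defined events.** The injected ripple amplitude is
  calibrated against the recording's own baseline so the detector's
  smoothed-power z at the peak equals `amp_sd` (default 3), and the
  ripple-band component of the background is crossfaded out under the event
  (plus a 30-ms guard). Without the crossfade, interference between the
  event and in-band background noise spreads the realized peak z by well
  over 1 SD, and no detector can keep a 3-SD population inside a [2, 5]
  acceptance band with 95% recall; the point of injecting calibrated
  events is precisely that their detector response is known.
* **Operational duration.** `dur_ms` (default 60) is the time the
  calibrated event spends above the detection threshold - the same
  threshold-crossing definition of ripple duration the detector reports and
  the field uses. The generator solves for the waveform support (a
  tapered-flat cosine envelope) that produces that footprint, and
  ground-truth start/end are the predicted crossings. A duration defined
  on the waveform support instead would differ from any threshold-based
  measurement by a factor depending on peak height, making "duration
  recovery" ill-posed.

The continuous NREM sigma rhythm is generated as a constant-envelope
oscillation whose frequency wanders slowly over 10-15 Hz, rather than as
filtered Gaussian noise. Filtered noise has chi-squared band-power
fluctuations (CV ~ 1), and an event-triggered average over hundreds of
events inherits per-lag noise near the +/-10% level; the constant-envelope
construction provides the stationary spindle-band power that the
normalization analysis presumes of uncoupled data.

What the generator does *not* emulate: biophysical (conductance-based)
dynamics, volume conduction, electrode drift and movement artifacts beyond
EMG amplitude, plaque pathology, or the across-animal heterogeneity of
real cohorts (animals differ only by seed). Passing recovery tests on this
generator therefore demonstrates that the chain is implemented correctly
and calibrated - that staging rules, estimators, detector and statistics
recover known structure at realistic SNR - not that the pipeline's
sensitivity or specificity transfers quantitatively to any particular
recording rig or mouse line.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 10 animals x 10-min sessions
for staging recovery (accuracy >= 0.90, REM bout recall >= 0.95); 3 x 10-min
NREM sessions for ripple recovery (recall/precision >= 0.95, duration within
+/-10 ms, frequency within +/-5 Hz) and 2 x 10 min of event-free background
for the false-positive rate (< 1/min); 10 seeds x 60 s of REM per kappa for
PAC monotonicity; a 35-min NREM session at 20 ripples/min (1 kHz sampling)
for the 585-event normalization flatness check; and 100 replicate cohorts
of 5 coupled vs 4 uncoupled animals (3-min NREM sessions, 1 kHz, 40 events
per animal) for the coupling contrast (t-test power >= 0.8 on peak
normalized power; inter-ripple baseline null in >= 90% of replicates). The
down-scaled sampling rate and session lengths in the simulation studies
keep the full validation runnable on a laptop; every analysis parameter is
otherwise at its default.

## Known limitations

* The staging rules are threshold-based and recording-relative; recordings
  whose state composition is extremely skewed (almost no NREM, say) shift
  the mean-ratio references and degrade the rules, as they would in the
  original procedure.
* Coherence is not corrected for the 1/K bias; comparisons are valid
  because every group shares K.
* The FDR family definitions and the REM-over-NREM tie precedence are
  conventions; both are configurable, and conclusions that depend on them
  should be checked under the alternatives.
* The spike veto is a heuristic stand-in for expert screening; on real data
  its thresholds should be reviewed against a manually scored sample.
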