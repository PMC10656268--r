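---
title: "Detecting and coupling sleep oscillations: methods and design notes"
author: "sleepLFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and coupling sleep oscillations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepLFP)
```

# What this package computes

During NonREM sleep, three oscillations organize the hippocampal-cortical
dialogue thought to underlie systems memory consolidation: hippocampal
sharp-wave ripples (high-frequency bursts in CA1, here 100-300 Hz in
natural sleep and 90-200 Hz under anesthesia, where brain rhythms slow),
cortical sleep spindles (9-20 Hz waxing-waning events) and cortical delta
waves (1-6 Hz down-state waves). `sleepLFP` detects these events in local
field potential (LFP) recordings, quantifies their temporal coupling
(delta-spindle, delta-ripple, ripple-spindle sequences, triplets, and
ripple-spindle co-occurrence), measures ripple locking to the
slow-oscillation phase, parameterizes the aperiodic (1/f) component of the
power spectrum as an excitation/inhibition proxy, summarizes sleep
architecture, and computes the object-exploration discrimination index
used as the behavioral memory readout.

Every stage is driven and validated by a synthetic LFP generator with
exhaustive ground truth, so the pipeline is testable end to end without
any recorded data.

# The synthetic generator

`generateRecording()` builds multi-channel recordings (HPC, PFC, three
accelerometer axes) from a `simConfig()`:

* **Aperiodic background.** The LFP background is synthesized by spectral
  shaping: Fourier coefficients are drawn as complex Gaussians with
  variance proportional to the target one-sided density
  $P(f) = 10^{\mathrm{offset}} f^{-\chi}$ and inverse-transformed.  This
  makes the log-log spectrum linear *in expectation at every bin*, so
  slope recovery by the spectral module is unbiased by construction —
  the reason we chose exact spectral shaping over an autoregressive
  approximation, whose spectrum only approaches a power law
  asymptotically.  Optional Gaussian bumps on the log-spectrum emulate
  oscillatory peaks.
* **State-dependent rhythms.** NonREM segments add a slow oscillation
  (default 1 Hz) on the PFC channel; REM segments add theta on HPC (7 Hz
  in the natural-sleep regime, 4.5 Hz in the anesthesia regime, where
  all bands are slowed).  These mirror the features the state scorers
  rely on, which is what makes the anesthesia classifier testable.
* **Events.** Oscillation events are sinusoids under a smooth unimodal
  envelope.  The default envelope is a tapered cosine (Tukey, taper
  fraction 0.25) rather than a pure Hann window: detectors measure event
  duration between threshold crossings of the envelope, and a Hann
  envelope spends only about two thirds of its nominal duration above a
  half-amplitude boundary, which would make ground-truth durations
  systematically unrecoverable — in particular, 110-200 ms "long"
  ripples would be measured short of the 100 ms class boundary.  The
  plateaued envelope keeps the measured duration within a few percent of
  the nominal one while preserving a smooth rise and fall.  A Hann
  envelope remains available (`envelope = "hann"`).
* **Coupling and phase.** Coupled pairs are placed with the trailing peak
  at a controlled lag + uniform jitter.  When a phase target is given,
  the NonREM slow oscillation is one globally coherent cosine and ripple
  peak times are computed from phases drawn from a von Mises
  distribution, so the ground-truth phases are exact by construction.
  Phase convention: 0 degrees at the slow-oscillation *peak*, 180 at the
  trough (the convention is a free choice; we document it and use it
  consistently in `soPhaseAtEvents()`).
* **Artifacts and motion.** Artifacts are large square excursions on both
  LFP channels; accelerometer channels have low variance during sleep
  and elevated variance during wake and artifacts.

A single seed drives one RNG stream in documented order (backgrounds,
state rhythms, events, couplings, phases, artifacts, accelerometer), so
identical configurations reproduce bit-identical recordings.

What the generator does *not* emulate: biophysical waveform asymmetries
(sharp-wave/ripple complexes, spindle frequency chirps), amplitude
distributions of real events (no published distributions exist for these
data, so detector sensitivity is characterized in units of background SD
rather than matched to a cohort), non-stationary background, and
movement artifacts with realistic spectra.  Passing tests therefore
demonstrate algorithmic correctness and calibrated sensitivity on
idealized events, not field performance on any particular recording rig.

# Preprocessing

Both regimes follow the same recipe with different constants, all
surfaced in `pipelineConfig()`:

* **Decimation** (`downsampleSignal()`): zero-phase 3rd-order Butterworth
  low-pass, then integer decimation.  Natural sleep: 30 kHz to 2.5 kHz,
  1.25 kHz cutoff.  Anesthesia: 30 kHz to 600 Hz, 300 Hz cutoff.  The
  stated order is the filter prototype order; forward-backward filtering
  doubles the effective attenuation order.
* **Band-pass** (`bandpassFilter()`): zero-phase Butterworth, so
  band-centered transients keep their peak sample (verified to within one
  sample in the tests).
* **Artifact blanking.** Chronic (`blankArtifactsChronic()`): samples
  above an amplitude threshold are replaced by the bout mean, together
  with a 1-s build-up window before each artifact; the threshold defaults
  to 8 robust SDs (1.4826 MAD) of the bout because the MAD, unlike the
  SD, is not inflated by the artifacts being sought.  The replacement
  mean is computed over below-threshold samples only, again to avoid
  artifact bias.  Blanking happens *after* band-pass filtering so
  replacement discontinuities cannot ring inside a detection band.
  Acute (`blankArtifactsAcute()`): the first 15 min are discarded
  (probe-settling), artifacts are flagged on the summed absolute value of
  the two unfiltered LFP channels, and `[artifact - 0.5 s,
  artifact + 3.5 s]` is replaced with the artifact-free mean; ripple-band
  traces must be filtered *before* blanking and are passed through
  `alsoBlank` so they receive the identical mask.

The chronic amplitude threshold is a per-session parameter with a
per-bout override, since session-wide versus per-bout thresholding is an
open choice; the robust default makes either stable.

# Sleep states

Natural-sleep hypnograms (1-s epochs over wake / NonREM / intermediate /
REM) are *ingested*, never computed — manual scoring is upstream of this
package.  `sleepArchitecture()` computes total sleep time, per-state
percentages, bouts (maximal runs; only bouts longer than 4 s enter the
duration statistics, shorter ones remain listed with an `included`
flag), transition counts between consecutive differing labels, and
45-min-binned state percentages, with a partial final bin normalized by
its own duration.

For anesthetized recordings `classifySleepLike()` reproduces a two-state
scorer: per 10-s epoch and region, band powers (slow oscillation 0.1-1,
delta 1-3, theta 3-6, low beta 10-20, low gamma 30-45, high gamma 55-80,
ripple 90-300 Hz), the theta/slow-oscillation ratio and the epoch
amplitude are computed from a multitaper spectrum; features are
z-scored; the first two principal components are clustered with 2-means
(10 restarts, fixed seed); and the cluster with the higher mean PC1 is
labeled NonREM-like.  Design choices worth noting:

* **Sine tapers.** The multitaper estimate uses the orthogonal sine-taper
  family with $K = 2\,NW - 1 = 7$ tapers for a time-bandwidth product of
  4.  Sine tapers have near-optimal broadband bias behavior and a
  closed form, which keeps the estimator simple and fast at any epoch
  length.
* **Standardization.** Band powers span orders of magnitude; without
  z-scoring, PC1 would simply be the largest band.  Whether the original
  scorer standardized is unknowable from its description; we standardize
  and flag this as the one classifier choice a user may wish to vary.
* **Orientation stability.** The PC1 sign is fixed so the summed loading
  of the slow-oscillation power features is positive; "higher mean PC1 =
  NonREM-like" is then invariant to the arbitrary sign of an
  eigenvector.
* **Artifact epochs** are flagged when the epoch amplitude deviates from
  the median by more than 3 scaled MADs (a MAD of zero flags nothing),
  labeled `ARTIFACT`, and excluded from the fit.

# Event detection

All detectors threshold the *envelope* (modulus of the analytic signal)
of the band-passed trace rather than the raw rectified trace: the
envelope rides the oscillation's peaks, which is what visual
thresholding of "voltage peaks" effectively follows, and it makes
duration estimates insensitive to carrier phase.

**Ripples** (`detectRipples()`): a candidate is a run of envelope samples
above the threshold lasting at least 20 ms (natural sleep) or 50 ms
(anesthesia); runs closer than 20 ms / 80 ms are merged; boundaries are
then extended outward to the half-threshold crossings; the peak is the
envelope maximum.  The threshold (`rippleThreshold()`) is built per
study day: SD of the concatenated band-passed NonREM signal per trial
period (only periods contributing > 3 min of NonREM), times 5, averaged
across periods, plus a 5 uV offset (chronic).  Ripples are classed SHORT
(<= 100 ms) or LONG (> 100 ms) by measured duration.  Events overlapping
blanked intervals are discarded; if a half-threshold boundary search
runs into a blanked region the event is truncated at the region edge.

**Quiet-wake ripples** (`detectQuietWakeRipples()`) run the same detector
inside wake-labeled bouts and veto candidates during movement
(accelerometer resultant above mean + 2 SD of the sleep-period
resultant — compared against the *window mean*, since movement is
sustained whereas the instantaneous resultant of quiet wake is noisy),
during locomotion theta (5-10 Hz power above twice its NonREM median)
and during high-amplitude artifacts.  These veto thresholds are
documented defaults, not published constants.

**Spindles** (`detectSpindles()`): envelope smoothed over 100 ms must
exceed 2.5 envelope-SDs for 0.4-3.0 s and exceed 5 SDs at least once;
runs closer than 100 ms are merged before the duration test (a waxing-
waning spindle can dip briefly below threshold).  **Delta waves**
(`detectDeltaWaves()`): an upward zero-crossing segment whose positive
peak exceeds 2 SDs of the filtered trace and whose trough (before the
next upward crossing) falls below -1.5 SDs, with wave duration within
100-1000 ms.  The spindle/delta thresholds descend from a freely-moving-
animal toolbox whose per-rat tuned values are unrecoverable; the
defaults here are stated explicitly and are ordinary tuning parameters.

Two calibration realities are worth knowing.  First, SD-based thresholds
are computed on signal that *contains* the events, so dense or huge
events inflate their own threshold; at realistic densities (a few
percent duty cycle) the inflation is small.  Second, a narrow-band
zero-phase filter rings: a 200 ms burst at 14 Hz leaves the 9-20 Hz
filter roughly 450 ms wide, so duration floors act on the filtered
trace, not on the generating burst.

# Coupling statistics

Sequences are ordered peak-to-peak intervals within inclusive windows:
delta-spindle 100-1300 ms, delta-ripple 50-400 ms, ripple-spindle
2-1000 ms (`detectPairs()`); delta-ripple-spindle triplets join the two
pair sets on the shared ripple (`detectTriplets()`); co-occurrence
(`detectCooccurrence()`) holds when a ripple lies within a spindle or
either event's endpoint lies inside the other, with both directional
counts reported because one spindle can host several ripples; D-SwR
(`detectDSwR()`) marks spindles that trail a delta and host a ripple.
Window endpoints are inclusive — the plain reading of "between x and y"
— and all qualifying pairs are counted (no deduplication when one delta
precedes two spindles; both the all-pairs count and the unique-spindle
count can be derived from the records).  `fractionInSequences()` uses
set membership, so multiplicity cannot inflate the fraction of ripples
participating in sequences.  All of these equal brute-force
enumerations exactly in the tests.

Phase locking: `soPhaseAtEvents()` reads the 0.5-4 Hz analytic phase at
ripple peaks (peak = 0 degrees); `phaseLockingTest()` is the Rayleigh
test (the classical uniformity test for a unimodal alternative; the
original analysis reports significance without naming its test), using
Zar's finite-sample approximation for the p-value, which simulation
shows calibrated to within half a percent at n = 100.

# Spectral parameterization

`computePSD()` is a Welch average of Hann-tapered 4-s windows with
0.25-s overlap on a 0.25 Hz grid to 100 Hz, with a zero-phase 50 Hz
notch.  `fitAperiodic()` parameterizes the log10 spectrum without a knee
(only offset and exponent are interpreted downstream): a robust linear
fit in log-log coordinates initializes the aperiodic component; residual
peaks are fitted as Gaussians largest-first while they clear both the
absolute height floor (0.05 log10 units) and a relative floor of 2 SDs
of the residual spectrum — the relative floor prevents estimation noise
in a single-session Welch spectrum from being fitted as oscillations —
with widths constrained to 1-8 Hz and at most 6 peaks (bounded for
determinism); the aperiodic component is then refit on the
peak-subtracted spectrum.  The default fit range is 1-100 Hz excluding
45-55 Hz, since the notch distorts that neighborhood.  On exactly
log-linear inputs the fit is exact to numerical precision; on
synthesized 120-s backgrounds the exponent and offset are recovered to
within about 2 % across exponents 0.5-2.

`eventTriggeredSpectra()` averages single-window spectra of 4-s windows
centered on ripple peaks per region and length class, against a baseline
of seeded random 4-s NonREM windows.  The 4-s event window matches the
baseline segment length; the event-centered window length is otherwise a
free choice and is exposed as a parameter.

# Behavior

`discriminationIndex()` is
$(t_\mathrm{novel} - t_\mathrm{familiar}) / (t_\mathrm{novel} +
t_\mathrm{familiar})$, undefined (reported `NA`) at zero total
exploration.  `behaviorSessionTable()` emits the tidy per-trial table the
group-level repeated-measures statistics consume, with the test trial
flagged and the "showed memory under vehicle" inclusion rule provided as
a column, never silently applied.  Group-level inference itself (ANOVA
families, post hoc tests) is deliberately out of scope: those are
standard tools operating on this table.

# Orchestration and reproducibility

`runSession()` chains preprocess, states, detection (on concatenated
NonREM bouts, with timestamps mapped back to the session timeline),
count binning, coupling, spectral parameterization and behavior, and
emits a manifest (config hash, seed, package version, per-stage counts).
Identical configurations reproduce identical outputs; disabled stages
make their dependents fail fast by name.  `selftest()` runs a condensed
ground-truth suite and supports fault injection on the ripple threshold
to confirm the recall property actually bites.  In-session chronic
blanking uses 25 robust SDs of the band-passed trace as its artifact
threshold: artifacts are an order of magnitude larger than band-limited
oscillations, and a lower multiple would blank large genuine ripples.

# Numerical choices and problem sizes

Filters are `signal::butter`/`filtfilt`; the analytic signal is computed
by the FFT construction; k-means uses 10 restarts under a fixed seed
with the standard algorithm; ties in peak finding resolve to the
earliest sample.  Intervals are half-open `[start, end)` seconds
everywhere except the inclusive coupling windows and co-occurrence
endpoint checks, which are inclusive by stated convention.  Degenerate
inputs (empty bouts, zero-power traces, MAD = 0, all-wake hypnograms,
all-artifact epochs) return empty or flagged results rather than NaN,
and are all exercised in the tests.

The validation suite sizes its simulations to what the properties need
rather than to realism: detector fidelity uses a 30-min NonREM session
at 2.5 kHz with 200 ground-truth ripples at 10x band SD; aperiodic
recovery uses 120-s, 1 kHz backgrounds (10 per exponent); the classifier
uses twenty 10-s epochs at 600 Hz; phase locking uses 100 ripples on a
1 Hz slow oscillation.  These are the same conditions the acceptance
script re-runs from scratch.

# Known limitations

* Detector sensitivity is characterized in background-SD units on
  idealized waveforms; absolute uV thresholds for a given rig still need
  per-animal inspection, exactly as in the original workflow.
* The anesthesia classifier assumes two separable states; it has no
  notion of intermediate states.
* The aperiodic model is knee-free; spectra with a clear knee (wide fit
  ranges, ECoG) would bias the exponent.
* Non-integer decimation ratios are not implemented (both supported
  regimes are integer).
* Manual sleep scoring, spike-band analyses, re-referencing and line
  tracking of time-varying noise are out of scope.
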