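---
title: "Analyzing pulsed fish calls with holocall: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing pulsed fish calls with holocall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocall)
```

## The problem

Holocentrid fishes (soldierfishes and squirrelfishes) produce pulsed calls:
short trains of one to about ten transient pulses, each pulse one contraction
cycle of the paired sonic muscles that drive the swim bladder. Because the
muscle contraction rate sets the pulse repetition rate, the fundamental
frequency (F0) of a multi-pulse call equals the reciprocal of the pulse
period, while the dominant frequency (Fpeak) reflects the resonant content of
the individual pulse. Some taxa additionally emit their pulses in *blocks*
separated by longer gaps ("sounds with pattern"), a temporal arrangement that
carries taxonomic information.

`holocall` turns one-call-per-file recordings into the standard per-sound
variables, aggregates them per individual, and quantifies how well taxa
separate in the resulting acoustic space: standardized PCA, convex-hull
occupancy, and discriminant classification with correct-classification rates
(CCR).

## The measurement chain

**Conditioning.** Recordings are taken as 44.1 kHz/16-bit mono WAV; other
rates and widths are normalized on read (multi-channel input is averaged;
off-rate input is linearly resampled — holocentrid calls live far below any
plausible recorder Nyquist, so linear interpolation is adequate). Calls are
band-pass filtered 50–4000 Hz with a 4th-order Butterworth applied forward
and backward (`signal::filtfilt`). The zero-phase property matters: all core
variables are timing variables, and pulse peaks must not shift.

**Pulse detection** (`detectPulses`). The amplitude envelope is the magnitude
of the analytic signal, smoothed with a 1 ms moving average. Pulse peaks are
envelope local maxima that (a) exceed `ampThresholdRel` (default 0.2) of the
global maximum and (b) come within 75% of the largest envelope value inside
the refractory distance `minPeriodMs` (default 4 ms, safely below the ~4.5 ms
period implied by the 220 Hz F0 ceiling). The quasi-maximum condition rejects
ripple on decaying pulse tails — such ripple sits far below the peak that
casts it — while keeping true peaks whose window still contains the previous
pulse's immediate tail when periods barely exceed the refractory distance. Sub-threshold input returns an empty train: "no pulses"
is a valid measurement. Sound onset and offset are the first and last
crossings of 10% of the maximum, read on the lightly smoothed *rectified*
waveform rather than the analytic envelope — the analytic envelope of a sharp
attack is acausal and would push the onset early by more than a millisecond.

**Per-sound variables** (`extractFeatures`). Duration (onset to offset, ms),
pulse count, mean pulse period (mean of *all* peak-to-peak periods, intervals
included — see below), last-pulse duration, F0, Fpeak, and, for patterned
sounds, mean interval, block count, and mean pulses per block. Variables that
do not apply are `NA`, never zero: a single-pulse call has no period and a
sound without pattern has no interval.

The **last pulse** is measured because no later pulse can mask its decay: its
duration runs from the half-rise point of its envelope to the decay below 10%
of its own peak. For an exponential envelope with decay constant tau this
reads approximately `tau * ln(10)`. The half-rise onset marker was chosen
because the 10% point of a near-instant attack is dominated by smoothing
spread; the envelope used here is noise-floor compensated (the floor,
estimated by the envelope median, otherwise adds in quadrature and delays the
decay crossing).

**Spectral variables.** One Hamming-windowed transform of the whole sound,
zero-padded to at most 5 Hz bin spacing regardless of call length. Fpeak is
the maximal-power bin in the 50–4000 Hz band, ties broken to the lowest
frequency. F0 is estimated only for calls of more than two pulses (shorter
calls have no harmonic structure): the spectral peak nearest the
period-derived prior `1000 / mean period`, searched within ±35% of the prior
on a *whitened* spectrum (power divided by its own local moving average).
Whitening prevents the rising flank of the pulse-resonance peak from dragging
the comb-line maximum upward — a few-Hz bias that is visible on short calls,
whose comb lines are tens of Hz wide. The estimate is cross-checked against
the prior; disagreement beyond 20% sets a quality flag.

## The pattern rule

A period is an **interval** (block gap) when it exceeds `ratio` times the
sound's mean pulse period, with `ratio = 1.25` by default; the last period is
never an interval; and sounds of three or fewer pulses are a single block,
automatically without pattern. Blocks are the maximal runs between intervals.
Two points deserve comment:

* **Which mean?** The mean includes all periods, candidate intervals too. An
  exclude-intervals mean would make the rule circular (intervals defined
  relative to a mean that depends on which periods are intervals); the
  single-pass comparison against the plain mean is the only self-consistent
  reading, and it is what `segmentBlocks` implements, in one pass.
* **Calibration.** `calibrateIntervalRatio` reproduces the threshold-selection
  procedure: among candidate multipliers (1.15–1.40) it returns the one whose
  computed block counts disagree with visually annotated counts for the
  fewest sounds, ties toward the smaller candidate.
  `makeCalibrationSounds` builds an annotated sample whose within-block
  periods reach just above 1.20x the mean and whose intervals sit just below
  1.30x, so exactly one candidate reproduces every annotation.

Sounds are then classed P1 (1 pulse), P2 (2 pulses), P3 (>2 pulses, no
pattern), P4 (>3 pulses in blocks); the four classes partition any corpus.

## From sounds to individuals

Individuals, not sounds, are the unit of the comparative analyses (the
classification denominators are individual counts). Per specimen, the ~20
best sounds by SNR are analyzed (`selectBestSounds`; SNR is estimated on the
*unconditioned* recording — band-passing removes most of the broadband noise
and would inflate every estimate by ~7 dB). `summarizeIndividual` averages
each variable over the sounds where it is defined and adds the percentage of
patterned sounds. Four variables known to scale with body size — duration,
pulse count, last-pulse duration, dominant frequency — are divided by total
length (`X(TL)^-1`, per mm); rows lacking TL are excluded from comparative
analyses. Because TL is constant within an individual, normalizing per sound
and then averaging coincides with normalizing the individual means (asserted
in the tests).

## The multivariate layer

**PCA** is computed on centered, unit-variance variables (they mix ms, Hz,
counts and percent; covariance PCA would let the largest-variance unit
dominate). Components with eigenvalue above 1 are retained for
interpretation. Loading signs follow a deterministic convention (largest
loading positive) so runs are reproducible bit for bit.

**Hull occupancy.** Convex-hull area/volume of each taxon's individuals in
the first 2 or 3 PCs, plus two relative measures: RCHS (volume per species)
and RCHI (volume per sampled individual). The 3D volume is computed exactly
by supporting-plane enumeration (every plane through three points with all
points on one side contributes `face area x centroid distance / 3`); point
sets are one-per-individual, so the cubic enumeration is cheap, and the
closed forms (unit square, unit cube, random tetrahedra against |det|/6) pin
it down in the tests. Degenerate (coplanar) groups get volume 0 with a
warning.

**Discriminant classification.** `discriminantCCR` fits flexible
discriminant analysis by optimal scoring: class indicators are regressed on
the standardized variables, optimal scores are extracted in the D-orthogonal
complement of the trivial constant score, and observations are classified by
Mahalanobis distance with pooled within-class covariance in the variate
space, with log-prior correction. With the default linear basis this is
exactly linear discriminant analysis — `method = "lda"` routes through
`MASS::lda` and serves as an independent cross-check, and the test suite
asserts identical assignments on 1000 random datasets. A quadratic basis
(`basis = "poly"`) is available but off by default. The headline CCR is
resubstitution (matching the "classified x out of y individuals" convention);
leave-one-out is available via `cv = "loo"` and is the better measure of
generalization — on small per-class samples resubstitution flatters the
many-class comparisons.

**Univariate harness.** Per variable: Shapiro–Wilk on residuals and Bartlett
across groups gate the parametric path at p < 0.05; log and square-root
transforms are tried when the raw data fail; the parametric path runs t
test/ANOVA with Tukey post hoc (alpha 0.05), the non-parametric path
Wilcoxon–Mann–Whitney/Kruskal–Wallis with Dunn post hoc under
Benjamini–Hochberg correction. Dunn p-values follow the one-sided
`P(Z >= |z|)` convention judged at alpha 0.025 (equivalently alpha/2).
Correction is applied within each variable's post-hoc family only; no global
correction across variables. The full decision trail is returned.

## The synthetic-call generator

`synthCall` renders a call as damped sinusoids: each pulse oscillates at a
drawn resonance frequency with exponential envelope decay `lastPulseTauMs`;
each new muscle contraction re-excites the single resonator, so a pulse's
decay is interrupted at the next pulse onset (the last pulse rings out fully,
which is exactly why only its duration is a reliable measurement). Gaussian
noise brings the call to the template SNR (default 20 dB, the "best sounds"
regime). Same seed, same waveform.

Template draws are organized as truncated normals with physical bounds, and
two links keep the templates self-consistent:

* **F0 first.** F0 is drawn and the period follows as `1000 / F0` — the
  causal direction of the sonic mechanism. The printed per-taxon period and
  F0 statistics are not exactly reciprocal (e.g. a 9.5 ms mean period
  alongside a 115 Hz mean F0); drawing F0 keeps the F0 target exact and
  leaves the period within its own spread. F0 draws are capped at 220 Hz,
  the ceiling observed across holocentrid calls, and the resonance is
  truncated at 200 Hz: below that a damped-sinusoid pulse is under ~1.5
  carrier cycles and has no oscillogram-readable peak (the emulated
  dominant-frequency range is ~240–400 Hz).
* **Duration drives the pulse count.** Registry templates draw the call
  duration and derive the pulse count from the drawn period and block
  layout. Drawing the count independently of the period produces unrealistic
  long calls for slow-period individuals; in the field data, slow-period taxa
  make fewer pulses. Templates with no duration distribution (useful for
  controlled fixtures) draw the pulse count directly, with the discretization
  de-biased so the realized mean equals the stated mean.

Individuals get their own voice: individual means are drawn with 0.7 of the
template sd and sounds vary around them with the complementary fraction, so
the taxon-level spread stays at the template sd; pattern propensity varies
between individuals as a Beta draw (concentration 1.8) around the taxon
probability, mirroring the very large per-individual spread of the percentage
of patterned sounds; block gaps scale with the individual's period so the
interval-to-period ratio of the taxon is preserved. Planted intervals are
guaranteed recoverable: every interval is lifted, if necessary, above 1.27x
the call's realized mean period, and block counts are capped so enough
within-block periods remain to hold the mean down.

What the generator does **not** emulate: harmonically rich real timbre,
amplitude trends across a call (crescendo/decrescendo — pulse amplitudes are
constant), propagation or tank reverberation, and multi-call recordings.
Passing tests therefore demonstrate that the measurement chain and the
statistical layer recover known structure under the stated noise model; they
do not certify performance on field recordings with overlapping calls or
nonstationary noise.

`synthFeatureCohort` draws the per-sound feature rows directly (no audio) for
many-replicate statistical experiments, adding measurement noise matched to
what the audio chain exhibits (8% on last-pulse duration, ~1 ms on call
boundaries, about one spectral bin on frequency reads). Without that noise,
constant per-taxon parameters would act as fingerprints and make any
classifier look perfect.

## Numerical choices and degenerate inputs

* Times are ms, frequencies Hz everywhere; the canonical rate is 44100 Hz.
* Zero-phase filtering pads with reflected signal so start-up transients fall
  outside the call.
* Empty pulse trains are valid results; empty inputs to aggregations are
  named errors (`holocall_empty_input` etc.), and every error in the package
  carries a condition class.
* Absent values are empty CSV cells, never 0 or -1.
* Block spans are 0-based inclusive internally.
* Degenerate hulls (collinear/coplanar) return 0 with a warning, not an
  error; a single class is an error for the discriminant layer.
* Exact separation in the discriminant fit is handled with a vanishing ridge
  on the pooled within-class covariance.

## Problem sizes in the tests

The validation suite runs cohorts of 30 individuals x 20 sounds per subfamily
for end-to-end recovery (about 1200 rendered calls), 10,000 random period
vectors against the brute-force rule oracle, 1000 random datasets for the
optimal-scoring/LDA equivalence, and 50 replicates of a nested
2-subfamily/4-genus/8-species taxonomy (10 individuals x 12 sounds per
species, feature-level) for the hierarchy property. These sizes give stable
means at a few minutes of total runtime; the generator scales to larger
cohorts with the same interfaces.

## Known limitations

* The pipeline assumes one call per file (the recording protocol); it does
  not segment continuous field recordings.
* F0 estimation for 3–4 pulse calls rides on wide comb lines; its per-sound
  error is a few Hz and shrinks in per-individual means.
* The interval rule is deterministic by design; no probabilistic block
  detection is attempted.
* Hull volumes in more than 3 dimensions are out of scope (2D/3D match the
  acoustic-space scatterplots).
* Resubstitution CCRs on small classes are optimistic; use `cv = "loo"` when
  sample sizes per class are small.
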