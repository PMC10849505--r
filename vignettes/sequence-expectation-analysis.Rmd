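---
title: "Sequence expectation analysis: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence expectation analysis: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the experimental design it models, the statistics it computes, the
conventions it fixes where the underlying procedures are ambiguous, and
what passing its tests does and does not establish about real recordings.

## The paradigm and its clock

Mice passively view sequences of four 250 ms oriented gratings followed by
800 ms of gray screen, so one presentation spans exactly 1800 ms. Three
sequences are used: the standard ABCD, the omission deviant ABBD (B held
on screen through the slot where C was expected — no visual transition
marks the violation), and the substitution deviant ACBD (a familiar but
unexpected element in the B slot). On baseline (day 0) and test (day 5)
sessions all three sequences are shown in interleaved blocks of 100
presentations separated by 10 s rests, five blocks per sequence, giving
500 presentations per sequence; training days show ABCD only. A 1-minute
gray period brackets the session.

`build_protocol()` lays this out on an exact millisecond clock and
`frames_for_event()` maps intervals to acquisition frames at a nominal
30 Hz. A frame belongs to an event iff its start time falls in
`[onset, offset)`. Two consequences are embraced rather than hidden:

* 250 ms is not an integer number of 33.3 ms frames, so element windows
  alternate between 8 and 7 frames depending on onset phase, while the
  800 ms gray period is always 24 frames. Trial tensors therefore use the
  minimum window length across the selected events (all trials align; at
  most one trailing frame is sacrificed) rather than padding.
* The retino-cortical information delay (~67 ms) is represented as exactly
  2 acquisition frames everywhere; 66 vs 67 ms phrasings are rounding of
  the same 2-frame offset.

Two windowing conventions coexist in the analyses and both are
implemented in `extract_trials()`: **shift** (the window starts 2 frames
later but keeps its full length — used for selectivity, where analysis
windows are "still 250 ms") and **truncate** (the first 2 frames are
dropped and the window ends at the event offset — used by the
prediction-error and correlation stages, which exclude the first ~66 ms).
Each caller states its mode.

## The synthetic population

`generator_config()` / `generate_population()` / `simulate_session()`
emulate deconvolved two-photon activity with planted ground truth. The
generator's defaults are the study conditions; they are chosen once, on
the phenomenology the analyses assume, and are not tuned per analysis.

**Cell classes.** 8 mice × 171 cells by default. Element-selective
fractions follow the observed day-0 / day-5 selectivity table
(A 6.1/2.7 %, B 10.0/7.1 %, C 6.1/2.6 %, D 9.2/4.3 %); gray-responsive
cells (9.4/10.3 %) are split 2:1 between *gray-onset* cells (a bump ~300
ms after gray onset, SD 40 ms across cells) and *gray-ramp* cells
(activity rising linearly to the end of the gray period). The remainder
is unresponsive background.

**Evoked responses.** Each driving event of a cell's class contributes a
Gaussian bump `amplitude * exp(-(t - (onset + latency))^2 / (2 sigma^2))`
sampled at frame start times within the event window (bumps are confined
to their driving event — deconvolved activity is temporally precise, and
confinement makes window statistics exactly attributable). The default
bump SD of 60 ms makes responses span most of an element, matching the
observation that population activity tiles the entire stimulation period.
Amplitudes are log-normal around 5 a.u. (sdlog 0.2); baseline is 0.05
a.u./frame; additive Gaussian frame noise (SD 0.5) is truncated at zero,
respecting the nonnegativity of deconvolved amplitudes.

**Latency distributions.** Day-0 latencies are Beta(2.5, 1)-distributed
over the (67, 250] ms post-delay window — density increasing toward late
times, reproducing the baseline pattern in which few cells peak at onset
and mass accumulates across each element. Day-5 latencies are a 50/50
mixture of Beta(1, 5) and Beta(5, 1) over the same window — the
post-training bimodal pattern locked to element onsets and offsets.

**Planted expectation-violation effects.** B cells emit activity in the
held-B window (position 3 of ABBD) scaled so that the *expected
time-averaged omission PE ratio equals the configured multiplier*
(defaults 1.10 on day 0, 1.44 on day 5); C cells in the unexpected ACBD
slot are scaled analogously relative to the expected C-in-ABCD response
(defaults 0.88 / 0.84). The scaling is calibrated on the observable
scale: because frame noise is truncated at zero, the expectation of a
window mean is `E[max(0, X)] = mu*Phi(mu/sd) + sd*phi(mu/sd)` per frame,
and the deviant-window profile is solved (monotone root-finding) so that
this truncated expectation equals the multiplier times the
standard-window expectation, using the same 2-frame-offset windows the PE
analysis uses. Without this calibration the planted multiplier would not
be recoverable: truncation bias and the 7-vs-8-frame window-length
mismatch would pull measured ratios toward 1. The calibration assumes
frame-aligned presentations (true for the standard protocol, where
1800 ms spans exactly 54 frames) and is exact at unit drift gain.

**Drift.** Each cell carries a multiplicative gain `g_t = exp(eta * W_t)`
with `W` a standard Gaussian random walk over session presentations
(default eta = 0.01). The gain multiplies evoked components only, so a
zero-amplitude population carries no decodable information. Because both
windows of an omission ratio lie in the same presentation, drift cancels
exactly in the planted PE effect. An optional rotation-like component
(`latency_swap_frac`) lets a fraction of cells switch to a second
preferred latency halfway through the session, for exploring drift that
survives vector normalization; it defaults to 0.

**Seed policy.** One master seed; population draws, session rendering and
noise use deterministic child seeds per stage and day, so identical
configurations reproduce byte-identical sessions.

## Selectivity: fixing an ambiguous rule

The selectivity criterion — "mean response more than two standard
deviations above the other stimuli" — admits two readings, and the choice
matters enormously. Taking the SD *across the other stimuli's mean
responses* makes the rule scale-free: an unresponsive cell whose five
stimulus means differ only by sampling noise still gets labeled whenever
one mean exceeds the others' spread, which happens for roughly a third of
pure-noise cells regardless of how small the noise is. Taking the SD
*across the pooled single-trial responses* to the other stimuli anchors
the threshold to trial-to-trial variability; false positives on
unresponsive cells are then negligible and planted class fractions are
recovered to within binomial error. The package implements both
(`sd_mode`), defaults to the trial-based reading, and uses the
deterministic tie rule (ties labeled `none`) in place of manual curation
of mixed-selectivity cells. The strict sparseness measure
(`stimulus_driven_flags`) keeps the across-time mean + 2 SD threshold; on
brief synthetic bumps it is deliberately conservative, and the package
only relies on its ordering relative to the permissive visual-modulation
measure, not its absolute level.

`visual_modulation()` tiles 266 ms (8-frame) chunks with 133 ms (4-frame)
gaps inside grating and gray spans and compares the chunk-mean
distributions with a two-sample KS test (p < 0.05). One refinement: the
tiling phase rotates across spans. At a fixed phase the same trailing
frames of every span (e.g. all of element D) would never be sampled,
silently blinding the test to late-responding cells; rotation samples all
phases over the session while preserving the chunk/gap structure within
each span.

## Prediction-error statistics

`pe_analysis()` recomputes responsive sets per day (cells are not tracked
across days), extracts deviant and standard windows in truncate mode, and
forms per-cell ratios; cells whose standard-window mean does not exceed
1e-6 of the population mean are excluded and counted. Window identities
follow the element letter, not the slot: the substitution standard is C
in ABCD (position 3) versus deviant C in ACBD (position 2). The omission
deviant window applies the same 2-frame offset as visible transitions,
for symmetry, even though the B1-to-B2 transition is invisible. Day
distributions are compared with a two-sample KS test whose `n` is
reported as the combined sample size. The hierarchical bootstrap
resamples mice with replacement, pools their cells, resamples cells to
the pool size, and stores the mean — 1000 iterations by default,
applicable to scalar ratios and to per-frame traces alike. A screen for
"exclusive" deviant responders uses an activity bar of mean + 2 SD on the
deviant window and a deliberately lower silence bar (mean + 1 SD) on all
other conditions; with no such class planted, the screen reports ~0
cells.

## Population geometry and decoding

PCA operates on the three sequence-mean trajectories concatenated in time
(a time-by-cell matrix), centered per cell but not variance-scaled —
deconvolved amplitudes are meaningful units, and standardization would
inflate silent cells. Scores are re-split by sequence; the count of
components reaching 90 % cumulative variance is reported. Element
correlations use the 6 unordered pairs of truncated, time-averaged
element vectors per presentation (3000 coefficients per sequence per full
session); zero-variance vectors drop their pairs and are counted rather
than imputed. Drift curves bin all pairwise response-vector correlations
by trial distance (default bin width 50 trials, configurable; block
indices can restrict to within-block pairs).

Decoders are linear support-vector classifiers (cost 1, no class
weighting) with per-cell standardization computed from training folds
only. The stimulus design has 15 classes (12 element-in-sequence + 3
per-sequence gray) split half/half per class; the block design trains on
50 trials per block and tests the remaining 250; the temporal design
treats each of the 24 gray-period frames as a class and splits *by gray
period*, so all frames of one period fall on the same side — the
leakage-detector test (shuffling labels within periods) confirms chance
accuracy. Shuffled-label runs calibrate every design against its analytic
1/K chance. Reported elsewhere as 3.1 %, the gray-period chance level is
taken here from the 24-bin definition (1/24 = 4.2 %); the within-sequence
time decoder uses all sequence frames (30 at 30 Hz) by default.

## Time fields

Trials are split even/odd by within-condition order (1st, 3rd, ... are
odd); each half is averaged and each cell's peak frame found with ties
broken to the earliest frame. Cells whose two peaks agree within 4 frames
(133 ms) are consistent; flat traces are inconsistent by convention.
Consistent cells receive their time field from the all-trial average.
Under pure frame noise the two peaks are independent and uniform, so the
null consistency probability is exactly 196/576 ≈ 0.34 for 24-frame
windows — the suite checks the implementation against this enumeration.
Histograms can omit the 2 post-onset delay bins of each element;
gray-period analyses use the full 24-frame window with no offset (gray
onset is a visible transition). Heatmap ordering is stable, with a
cross-validated mode (sort on even halves, display odd) that removes
artificial temporal structure from the display.

## Problem sizes and what the tests show

The test suite and the acceptance script run reduced-scale versions of
the full design, chosen to keep the statistical structure intact:
full-protocol sessions (500 presentations per sequence, 1500 gray
periods) with 96-cell populations for structural counts and chance-level
calibrations; 480-cell, 100-presentation sessions for recovery of planted
selectivity fractions, PE multipliers (within ±0.05 at ≥ 100 B cells),
latencies (within 1 frame), and drift monotonicity; 20 decoder iterations
with 100-trial-per-class subsamples where only a chance level is being
estimated (chance is insensitive to these sizes; the acceptance script
records the sizes it used alongside each value).

Passing these tests establishes that every stage computes what it claims
on data with known structure. It does not establish that real V1
recordings have that structure: the generator plants Gaussian bumps with
event-confined support, independent truncated-Gaussian frame noise, and
gain-random-walk drift, whereas real deconvolved data have correlated
noise, bursting, cross-event calcium bleed-through, and drift of unknown
form. Real-data quantities that depend on those properties — absolute
decoder accuracies, the ~60 % consistent-cell fraction, the ~10
components for 90 % variance — are emulated qualitatively, not asserted.

## Known limitations

* Cells are not tracked across days, so cross-day analyses are
  distributional only (as in the design being modeled).
* The omission/substitution calibration is exact in expectation at unit
  drift gain; with drift enabled the recovered group means deviate by
  O(eta^2), well inside the ±0.05 recovery band at the default eta.
* The strict sparseness measure is conservative on brief transient
  responses (see above); interpret its absolute level accordingly.
* Serialization uses CSV/JSON only; activity matrices are regenerated
  from seeds rather than stored.
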