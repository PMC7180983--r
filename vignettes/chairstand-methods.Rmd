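---
title: "Counting sit-to-stand transitions from a chair-mounted ultrasound sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting sit-to-stand transitions from a chair-mounted ultrasound sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chairstand)
```

## The measurement problem

The 30-second chair–stand test (30-s CST) counts how many times a person
stands fully upright from a chair in 30 s. It is a standard lower-limb
strength measure and a marker of frailty in older adults, normally scored by
a trained rater. An instrumented chair replaces the rater with an ultrasound
range sensor on the backrest: the torso-to-backrest distance, sampled at
10 Hz, dwells near ~15 cm while sitting, rises to ~50 cm while standing, and
traces a quasi-periodic signal over the test. Scoring the test then becomes
a signal-processing problem: count the sit-to-stand transitions in a
300-sample distance trace, robustly to measurement artifacts.

Two artifact regimes matter. Signals from young subjects in a laboratory
show sparse, narrow outlier spikes. Signals from older adults in a clinical
setting show abundant clustered spikes — plausibly chair motion or
lean-and-rock strategies — and sometimes an elevated sitting baseline when
the subject does not lean back between stands. The two detection algorithms
in this package differ precisely in how they cope with these regimes.

## Algorithm v1: moving median with peak thresholds

`detect_v1()` runs four stages on a `distance_signal`:

1. **Outlier reset.** Samples strictly above 70 cm (far beyond any upright
   distance) are replaced by 15 cm, a typical sitting distance.
2. **Moving median**, 0.7-s centered window (7 samples at 10 Hz).
3. **Peak merging.** Strict local maxima of the filtered trace that are
   closer together than the *peak distance threshold* PDT are a single
   peak. PDT is data-adaptive: the median inter-maximum gap multiplied by
   the *distance factor* DF.
4. **Validation.** A merged peak counts only if its height strictly exceeds
   the *peak height threshold* PHT (cm).

The PDT definition is circular on its face (peaks are needed to compute the
gap median that defines peak merging). The only reading consistent with a
single pass — and the one implemented — computes the gap median over **all**
strict local maxima of the filtered signal before any merging. Plateau
maxima report their first index; merged peaks report the highest member,
earliest on ties.

The tuned DF and PHT used on the original recordings were never published.
The shipped defaults, `DF = 0.5` and `PHT = 30` cm, were fixed once by grid
calibration on synthetic fixtures (`calibrate()` reproduces the procedure)
and sit comfortably between the sitting baseline and standing plateau; both
are configurable.

A 7-sample median absorbs up to three spiked samples per window, which is
why v1 is reliable in the young regime: isolated narrow spikes never pass
the filter. Its failure mode is equally mechanical: when four or more
spiked samples fall in one window — the clustered bursts of the older
regime — the median itself jumps and a spurious peak appears.

## Algorithm v2: moving minimum with an adaptive threshold

`detect_v2()` replaces the median with order statistics that ignore upward
artifacts entirely:

1. **Outlier nulling.** Samples strictly above 99 cm become missing (`NA`).
2. **Moving minimum**, 0.7-s centered window, ignoring missing values. Any
   upward spike narrower than the window is erased completely.
3. **Adaptive sitting–standing threshold (SST).** With 4-s windows on the
   preprocessed signal, `SST = movmin + ATW * (movmed - movmin)`; the
   *adaptive threshold weight* ATW in [0, 1] places the threshold between
   the local minimum envelope and the local median. The binary signal
   `filtered > SST` encodes sitting/standing; missing samples compare as
   sitting, so a nulled outlier can never create a standing state.
4. **Edge detection and cascade.** Stand-up moments are rising edges of the
   binary signal (an initial standing state at t = 0 carries no stand-up
   and is not an edge). Edges closer than the *minimum peak distance* MPD
   (seconds) merge into one peak; peaks closer than the *minimum samples
   between peaks* MSBP (samples) merge again; finally peaks whose height
   does not strictly exceed the *minimum subject distance* MSD (cm) are
   discarded. The cascade runs in exactly that order. A peak's height is
   the maximum filtered value over the contiguous above-threshold runs
   containing its edges, and its index is the position of that maximum.

Defaults — `ATW = 0.5`, `MPD = 1` s, `MSBP = 5` samples, `MSD = 25` cm —
were likewise fixed by synthetic re-calibration, since the originally tuned
values were never published. MSD has a second use beyond noise rejection:
invalid attempts (stand-ups that stop short of upright, around 35 cm) can
be excluded from the score by raising MSD into the gap between the invalid
and upright peak heights, and `calibrate()` against valid counts recovers
such a discriminating value.

## Calibration

`calibrate()` reproduces the tuning procedure: an exhaustive grid search
over named detector parameters, scored by the mean error against manual
counts on an annotated calibration set. "Mean error" is implemented as mean
*absolute* error — a signed mean could reach zero by cancelling over- and
under-counts. Ties break first by the smaller magnitude of the mean signed
bias, then by grid order, so results are deterministic. A detector failure
on a signal scores as that signal's annotated count (the worst case, as if
zero were reported) rather than aborting the search. Four coarse-grid v2
parameters remain desk-scale; no gradient methods are warranted.

## Reliability and classifier statistics

Device scoring is validated as an inter-rater reliability problem: each
subject is scored by the human rater and by the algorithm, and agreement is
measured with the single-rater, absolute-agreement, two-way intraclass
correlation, McGraw–Wong ICC(A,1):

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with rows = subjects, columns = raters ($k = 2$). Absolute agreement (not
consistency) is the right form because a device that systematically adds
one stand per test should be penalized. The F test of ICC > 0 uses
$MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ degrees of freedom; the 95% interval
uses the McGraw–Wong F bounds with Satterthwaite degrees of freedom. A
degenerate table (zero total variance) has no defined ICC and is an error;
a table with perfect agreement but real between-subject variance returns
ICC = 1 with a degenerate interval at 1.

Reliability bands follow Koo–Li cutpoints, left-closed: [0, 0.5) poor,
[0.5, 0.75) moderate, [0.75, 0.9) good, ≥ 0.9 excellent — left-closed so
that 0.50 reads moderate and 0.86 reads good. Because a point estimate can
sit in a band the data cannot defend, `icc_a1()` also reports a
*supported* band computed from the lower confidence bound: the reliability
level the sample can actually ensure.

For the derived three-class functional classifier (below average / average /
above average), `classifier_report()` compares accuracy against the
no-information rate (NIR) — the accuracy of always predicting the most
common class, 75% in the validation cohort design. It reports the exact
Clopper–Pearson 95% interval, a one-sided exact binomial test of
accuracy > NIR, Cohen's arcsine effect size
$h = 2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_0}$, and the power of the
one-sample proportion test at $\alpha = 0.05$ under the normal
approximation on the arcsine scale, $\Phi(\sqrt{n}\,h - z_{1-\alpha})$.

Score-to-class translation uses gender- and age-banded 25th/75th-percentile
ranges. Scores equal to a percentile bound read as *average* (the
inclusive reading of "between the percentiles"); the worked boundary cases
do not discriminate this, so it is a documented convention. The shipped
table (`inst/extdata/normative_synthetic.csv`) is a **synthetic,
user-replaceable fixture** consistent with the published gender/age
patterns, not a reprint of the published normative standards.

## The synthetic-signal generator

The validation recordings were never deposited, so the package generates
its own study conditions (`synthetic_spec()`, `generate_signal()`,
`generate_cohort()`), encoding the *observed* features of the two regimes,
not a biomechanical mechanism:

* **Trapezoidal cycles.** A torso-to-backrest distance dwells at the
  sitting baseline (15 cm) and the standing plateau (50 cm) with ~1-s
  ramps; sinusoids would never dwell. Cycles start after a 1-s lead-in and
  may not overlap (period ≥ 2 × rise time).
* **Cadence.** Young subjects draw periods from 1.8–2.6 s (11–16 stands
  per test), older subjects from 2.2–3.4 s (8–13 stands): older slower
  than young, and a 30-subject older cohort totals roughly 300 transitions,
  matching the scale of the validation cohort (~335).
* **Noise.** Gaussian, 0.5 cm (young) or 1 cm (older), truncated at zero.
* **Spikes.** A burst-Poisson process: onsets at 0.05/s (young) or 0.5/s
  (older), geometric burst sizes with mean 1 (young, isolated) or 4
  (older, clustered), one height per burst drawn uniformly from
  60–150 cm (young) or 40–110 cm (older) so heights straddle the 99-cm
  ceiling and exercise both preprocessing branches, with substantial mass
  in the 40–70 cm band that resists v1's 70-cm reset. Burst width is
  capped at 0.6 s — under the 0.7-s filter window — and onsets have a 1-s
  dead time, because physical artifacts (momentary chair motion, a passing
  limb) are brief and do not overlap; this reproduces the observed
  phenomenology that the moving minimum removes them completely while the
  moving median passes clustered bursts as spurious peaks.
* **Invalid attempts.** Each cycle is truncated short of upright (at
  35 cm, or halfway to upright from an elevated baseline) with per-cycle
  probability 3.3% in the older regime — matching the reported scarcity of
  about 11 invalid among 335 transitions, scattered over a handful of
  subjects.
* **Elevated baselines.** About a quarter of older subjects draw a
  17–30 cm sitting offset (no lean-back), pushing filtered-signal minima
  above 30 cm — the regime where the adaptive threshold loses contrast and
  v2's counts start missing by about one event.

All randomness sits behind one seed; cohorts derive per-subject seeds by
counter, so generation is reproducible signal-by-signal and does not
disturb the caller's RNG stream. Ground truth (cycle onsets, validity,
counts) is exact by construction, and every detector test compares against
it, never against eyeballed values.

What the generator does **not** emulate: real chair displacement dynamics,
breathing and clothing artifacts, ultrasound beam geometry, or any
biomechanics of the sit-to-stand cycle. Passing tests on synthetic cohorts
therefore demonstrates that the algorithms behave as designed under the
documented signal model — not that the device is clinically valid on real
recordings.

## Numerical conventions and edge cases

* Sample indexing is 0-based in all reported events; the time of sample
  *i* is exactly *i*/rate seconds.
* Window lengths in samples are `round(window_s * rate_hz)`, promoted by
  one if even, so windows have a symmetric center (0.7 s at 10 Hz → 7).
  Windows are centered and shrink at the edges; a trailing window would
  lag transition times by half a window.
* The median of an even count of finite window members is the mean of the
  two central values; an all-missing window yields the missing marker.
* All thresholds compare strictly ("over 70 cm", "over 99 cm",
  "exceeds PHT/MSD").
* Both PHT and MSD are absolute filtered-signal heights, not heights above
  a local baseline; nothing in the algorithm definitions requires a
  baseline reference, and the absolute reading keeps v1 and v2 symmetric.
* With fewer than two local maxima, v1's PDT is undefined and no merging
  is applied.
* A v2 recording whose samples are all nulled by the 99-cm ceiling is
  unusable and raises an error rather than returning zero stands.
* One known sensitivity: nulling a sample that was a moving-minimum
  window's *unique* minimum (a ramp sample) moves the filtered signal by
  one order statistic, so an outlier landing exactly on a ramp can shift a
  reported event index — never a count, at plateau-preserving cadences —
  by one sample (0.1 s). This is inherent to order-statistic filtering
  with missing data, not an implementation artifact.

## Problem sizes used by the test suite

The suite regenerates everything at run time: 1000 random sequences (up to
1000 samples, windows 3–41) against a brute-force filter oracle; 100
noise-free signals across 2–6-s cadences for exact counting; 200
spike-injection trials; 50-signal cohorts per regime for the young/older
contrast; 30–50-signal batches for the elevated-baseline degradation; 1000
random rating tables against an explicit sums-of-squares ICC oracle; exact
binomial-tail enumeration for all n ≤ 50; and 10-signal calibration sets.
These sizes give stable pass/fail behaviour for the directional properties
while keeping the full suite around a minute of CPU.

## Known limitations

* The synthetic regimes are stylized; the package's accuracy statistics on
  them say nothing quantitative about accuracy on real recordings.
* Algorithm v1 cannot distinguish valid from invalid transitions at all,
  and v2 only does so through MSD when the two peak populations are
  separable in height.
* The normative fixture table is synthetic; clinical use requires the
  published standards.
* Scores near a percentile boundary inherit the detector's ±1 count error;
  a one-count error can flip the class even at good ICC levels.
* No real-time/streaming variant: filters are centered, so the full
  recording must be available.
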