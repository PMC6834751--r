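---
title: "Scoring behavioral lateralization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring behavioral lateralization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralize)
library(dplyr)
```

This vignette documents the models behind `lateralize`, the parameters that
matter, and the choices we made where the underlying assay conventions leave
the design genuinely open.

## The free-movement-pattern Y-maze

A fish explores a three-arm maze continuously for an hour.  Every passage
from one arm to a *different* arm is a binary choice — left or right relative
to the arm it came from — so a session yields an ordered token stream over
\{L, R\}.  Three families of metrics are computed from that stream:

1. **Tetragram profile.** A window of four consecutive choices slides over
   the whole-session stream with stride 1, giving `n_turns - 3` overlapping
   words over a 16-word alphabet (`llll` … `rrrr`).  Relative frequencies are
   taken over the window count, so they always sum to 1.  The *alternation
   score* is the combined relative frequency of `lrlr` and `rlrl`
   (working-memory-like search); the *repetition score* is `llll` + `rrrr`
   (perseveration).
2. **Bias index.** For any set of turns,
   `bias% = 100 x (turns to one side) / (total turns)`; left and right
   percentages are complementary.  The whole-session bias feeds a strict
   three-way classification: right-biased if right% `>` threshold (default
   60), left-biased symmetrically, otherwise non-biased.  Exactly 60% is
   non-biased — the threshold is strict.
3. **Consistency.** The session is cut into half-open 10-min bins
   `[k*600, (k+1)*600)`; the per-bin bias percentages give a mean and a
   coefficient of variation per side across bins with at least one turn.

### Choices the assay literature leaves open

* **Tetragram denominator.** "Frequency as a proportion of the total number
  of turns" is ambiguous between `n_turns` and the window count
  `n_turns - 3`.  We use the window count: it is the only denominator under
  which the 16 relative frequencies sum to 1, which the profile plots and
  oracle comparisons rely on.  At session-scale turn counts (≈150–200) the
  two differ by under 2%.
* **CV convention.** Sample SD (n − 1 denominator), reported as a percentage
  of the mean.  With six bins the sample/population choice changes the CV by
  a factor of `sqrt(6/5)` ≈ 1.10; we state ours so results are comparable.
* **Whole-hour classification.** The class label uses the whole-session
  bias, not the mean of per-bin biases; bins only feed the consistency
  statistics.  When a per-bin tetragram breakdown is requested
  (`count_tetragrams(by_bin = TRUE)`), a window belongs to the bin of its
  fourth turn, because that is when the choice pattern completes.
* **Turn-direction convention.** Nothing pins "left" to a particular arm
  transition; it depends on which side of the maze the camera sees.  We fix
  *clockwise neighbour (viewed from above) = R* and expose
  `maze_geometry(clockwise_is_right = FALSE)` to mirror it.  All metrics are
  equivariant under this reflection (left and right labels swap), so the
  choice is a naming convention, not a modelling assumption.
* **Same-arm re-entries.** An arm → centre → same-arm excursion completes no
  left/right choice and emits no token; it is counted separately in the QC
  attribute rather than silently merged, since trackers disagree on whether
  to log it.
* **Engagement exclusion.** Subjects are excluded below a configurable
  minimum turn count (default 20 over the hour).  Screening pipelines
  exclude non-engaged animals but rarely publish a numeric rule; ours is an
  explicit config value, and excluded subjects are listed in the run
  manifest rather than dropped invisibly.

## The synthetic turn model

The generator draws tokens from a first-order Markov chain with
`a = P(R | previous L)` and `b = P(R | previous R)` — the minimal model that
can express both a marginal side bias and the alternation/repetition axis.
Its stationary right-turn probability is `a / (a + 1 - b)`; `a = b` collapses
to an i.i.d. Bernoulli stream.  Turn times come from a constant-rate
exponential process truncated at the session length, the simplest timing
model consistent with per-bin count analysis.  Each simulated sequence is
also rendered as the arm-entry path a tracker would log, so synthetic
cohorts exercise the full pipeline including turn coding — not just the
metric layer.

The closed-form oracle `expected_tetragram_freqs()` gives each word's
expected relative frequency as `pi(w1) * P(w2|w1) * P(w3|w2) * P(w4|w3)`.
The test suite checks it against an independent brute-force enumeration
(length-6 paths, stationary-weighted, window-averaged) and against empirical
frequencies from 10,000-turn simulations within three binomial standard
errors.  Two caveats are worth knowing: overlapping windows are positively
correlated, so the binomial standard error slightly understates the true
sampling variability of persistent chains, and the degenerate chain
`a = 0, b = 1` has no unique stationary law, so the oracle returns missing
values there with a warning.

### Default cohort parameters

`cohort_spec()` defaults describe a 28 left- / 28 right- / 47 non-biased
screening cohort:

| class | a | b | stationary R% | turns/min |
|---|---|---|---|---|
| non-biased | 0.65 | 0.35 | 50 | 3.0 |
| right-biased | 0.72 | 0.72 | 72 | 2.4 |
| left-biased | 0.28 | 0.28 | 28 | 3.0 |

Non-biased fish are alternation-dominant with no marginal bias — the typical
spontaneous search strategy.  Lateralized fish carry an i.i.d. side bias,
which mechanically raises `llll`/`rrrr` and depresses the alternation words,
reproducing the qualitative biased-class signature (more repetition, less
alternation); the right-biased class also turns more slowly, reproducing the
lower-turn-count contrast.  Per-fish parameters jitter uniformly (±0.03 on
`a`, `b`; ±15% on rate) so the classes are distributions, not point masses.
These are qualitative emulations chosen once: no attempt is made to fit the
original cohort, whose raw data are not deposited.

With these defaults a fish makes ~150–200 turns/h, the binomial SD of its
session bias is ~3.5–4 percentage points, and the class means sit 8–12
points from the 60% threshold — so end-to-end label recovery above 95% is a
property of the study conditions, not of a tuned test.

## Avoidance conditioning

The schedule encodes the assay timeline: 30-min habituation with the two
base patterns swapping tank sides every 5 min, a 10-min baseline, nine
1.5-s CS+ presentations each followed by a shock (metadata only — the US is
never modelled) and an 8.5-s CS− inter-trial interval, then a 1-min probe
with CS+ and CS− at opposite ends, swapping at 30 s.

*Preference* is the time-weighted fraction of a phase spent in the CS+
vicinity, which we define as the CS+ half of the tank's length axis split at
the midline — no vicinity radius is established for this assay, and a half
split makes baseline and probe directly comparable (the split point is an
argument).  Each inter-sample interval is cut at the scheduled side changes,
so a fish sitting still through the probe swap scores exactly 0.5.  We let
the 5-min side alternation continue through the baseline; since scoring is
side-schedule-aware, this only determines which half counts as CS+ in each
block.  Sampling gaps longer than a tolerance (default 1 s) are excluded
from the covered time with a warning, never imputed.  Habituation data are
parsed but never scored.

The conditioning generator is a reflected 1-D walk with zero drift until a
CS+ side exists, then a constant drift (cm/s) away from the scheduled CS+
side, tracking the mid-probe swap.  Strength 0 is the null (probe equals
baseline in expectation); increasing strength monotonically depresses probe
preference.  By default the walk starts at the baseline phase because
habituation never enters scoring; `include_habituation = TRUE` emits the
full timeline.

## Novel tank

Endpoints from paired front/top camera views of a 5-min trial in a
30 × 15 × 12 cm tank: thirds occupancy (three equal 5-cm slabs of the height
axis, scored from the front view), total distance (summed Euclidean step
lengths, top view), immobility, and thigmotaxis.  Each sample owns the
interval to the next sample, so thirds times partition the covered time
exactly.

Immobility and thigmotaxis need thresholds the assay descriptions leave to
the tracking software.  Ours are explicit configuration with defaults:
immobility is time inside runs where top-view speed stays below 0.5 cm/s for
at least 2 s (the duration gate keeps momentary tracking jitter from
fragmenting genuine freezing); thigmotaxis is time within 2.4 cm — 20% of
the tank width — of any wall in the top view.

The tank generator is a reflected Gaussian walk; depth preference is a
mean-reversion term toward a preferred depth, wall attraction a drift toward
the nearest wall.  With zero biases the stationary occupancy is uniform, so
thirds converge to 1/3 each — the symmetry the tests exploit.

## Numerical and degenerate-input conventions

* Zero turns: bias, scores and label are *missing*, never zero; such
  subjects are excluded and listed.
* Fewer than 4 turns: tetragram counts are zero and relative frequencies
  missing.  Fewer than 2 usable bins: consistency statistics missing.
* Bin edges are half-open; a turn exactly at the session end joins the last
  bin (the only closed boundary).
* Out-of-bounds trajectory samples are clipped to the tank, not dropped, so
  occupancy time is conserved; the clip count is surfaced for QC.
* All generators take an explicit seed and restore the caller's RNG state;
  identical seeds give byte-identical output, and the pipeline manifest
  records the seed used.

## What the simulations do and do not show

The generators reproduce the *statistical structure the metrics assume*:
first-order sequential dependence, stationary bias, exponential turn timing,
diffusive tank motion.  Real fish show non-stationarity within sessions,
higher-order sequential structure, wall-following inside the maze and
tracker noise none of which are modelled — so green recovery tests validate
the pipeline's arithmetic and its behaviour under the stated model, not the
biology of any particular cohort.  The published group contrasts for the
conditioning and tank assays depend on the original animals and are covered
only qualitatively (direction of effects), not numerically.

Problem sizes used by the test suite — 10,000-turn oracle comparisons, a
103-fish default cohort, 100 recovery seeds, 200 avoidance replicates, 1,000
null repeats for the permutation test's type-I error — were chosen to make
the binomial/Monte-Carlo margins small relative to the effects being
checked.

## Known limitations

* The turn model is first-order; metrics sensitive to longer memory (e.g.
  tetragram structure beyond what pairs induce) are validated only against
  the first-order oracle.
* Permutation contrasts replace the mixed-model inference a full analysis
  of repeated-bin data would use; they test group exchangeability of
  per-subject summaries and do not model within-subject time structure.
* The CS+ "vicinity" is a half-tank split; rigs that score a narrower zone
  will get systematically larger preference fractions here.
* Trajectory endpoints assume the two camera views are frame-synchronous;
  mismatched time bases are rejected rather than resampled.
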