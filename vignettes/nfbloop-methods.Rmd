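---
title: "Closed-loop neurofeedback scoring and simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop neurofeedback scoring and simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfbloop)
```

# The problem

In real-time fMRI neurofeedback a participant watches a display that is
driven, once per repetition time (TR), by the BOLD signal of a region of
interest (ROI) in their own brain, and tries to move that signal toward a
cued target. `nfbloop` implements the complete scoring chain of such an
experiment for a block-design motor paradigm with three display modalities —
a continuous thermometer-style bar (`cFB`), a categorical face display
(`aFB`), and a no-feedback transfer condition (`noFB`) — together with a
synthetic cohort generator that makes every stage testable without scanner
data.

# The paradigm

A session consists of two runs. Each run opens with an 8-TR stabilization
period (excluded from all scoring) and then presents 27 blocks: the full
crossing of 3 modalities x 3 cued levels x 3 repeats, shuffled without
replacement per run. A block is an 8-TR baseline, a 12-TR regulation period
initiated by a numeric level cue, and a 2-TR outcome phase (TR = 2 s). The
default run is therefore 8 + 27 x 22 = 602 TRs. TR windows are 0-based and
half-open, and the level cue is modeled as coincident with the first
regulation TR, since the design allocates no separate cue TRs.

`make_schedule()` draws the block order from a stream seeded by
`(master seed, participant, run)` via a stable string hash, so cohorts are
reproducible and independent of generation order. "Shuffle of the fully
crossed cell multiset" is the only reading of a 27-block
randomized-without-replacement run that also yields 18 blocks per modality
per participant over two runs, which the aggregation stage relies on.

# The feedback signal

For every regulation TR the ROI mean is converted to a percent signal
change relative to the mean of the block's own immediately preceding
8-TR baseline,

$$\mathrm{psc}(t) = 100\,\frac{x(t) - \bar{x}_{\mathrm{base}}}{\bar{x}_{\mathrm{base}}},$$

then normalized by the participant's calibration maximum (the display's
100% point) and clipped to the display scale:

$$S(t) = \mathrm{clip}_{[0,100]}\left(100\,\frac{\mathrm{psc}(t)}{\mathrm{psc}_{\max}}\right).$$

Three a priori bands partition the scale: level 1 `[10, 40)`, level 2
`[40, 70)`, level 3 `[70, 100]`. The categorical display shows the band's
face, with a neutral face (level 0) below 10 — the display assigns
expressions only from 10 upward, so the sub-band region maps to the
baseline face. Negative signal change clips to an empty display at 0.

**Success rule.** A block succeeds when at least 50% of its 12 regulation
TRs are hits, i.e. at least `ceiling(0.5 * 12) = 6`. The default hit rule
is *met-or-exceeded* — `S(t)` at or above the cued band's lower bound —
following the success criterion's wording; a *within-range* rule is a
first-class configuration switch because the continuous occupancy metric
uses within-band semantics. The two rules differ only when the signal
overshoots the cued band (e.g. `S = 80` under a level-1 cue), and reports
should state which rule was used. An optional number of initial
regulation "grace" TRs can be excluded from hit counting to discount the
hemodynamic rise; the default of 0 keeps the literal 12-TR rule.

When a TR's value is invalid (non-positive baseline reference), the
display holds the last valid state and the held value still counts toward
classification, mirroring how the real-time display behaves during data
dropouts.

# Continuous performance metrics

Binary success discards information, so two continuous per-block measures
are computed with within-band semantics regardless of the success rule:

* **occupancy** — the fraction of regulation TRs with `S(t)` inside the
  cued band (level 3's upper boundary never contributes, as the scale
  clips at 100);
* **distance-to-range** — per TR, 0 inside the band, otherwise the
  absolute distance to the nearest band boundary; summarized per block by
  its median (precision) and n−1 SD (stability), with mid-point
  interpolation for even-count medians.

`occupancy = 1` if and only if both distance summaries are 0, which the
property tests assert.

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes; it
is first-class, tested code.

**Hemodynamics.** Effort (dimensionless, 0 = rest) drives a canonical
double-gamma hemodynamic response function — gamma densities with modes at
6 s (peak) and 16 s (undershoot), undershoot ratio 1/6 — sampled at the TR
and normalized to unit sum, so sustained unit effort converges exactly to
the participant's `gain` (percent signal change; cohort default range
1.5–4.5, matching the spread of peak motor responses across adults at 3T
and 7T). AR(1) Gaussian noise (default innovation SD 0.3, lag-1
coefficient 0.3) and optional linear drift are added. No cardiac,
respiratory, or motion structure is simulated, so passing tests show
correctness of the scoring chain under well-behaved noise, not robustness
to physiological artifacts.

**Behavior.** Each participant holds a per-level effort set-point,
initialized at the value whose plateau lands on the cued band's midpoint
given their gain and calibration, so baseline success is mid-range rather
than floor or ceiling. At block onset the set-point is perturbed by
Gaussian effort noise truncated at zero (default SD 0.70 effort units) —
untrained participants are poor at open-loop force scaling, and this
block-to-block variability is the dominant failure source. During
regulation the modality's tracking rate corrects effort each TR against
the perceived error: `(S − band midpoint)/100` for the continuous bar,
`(displayed level − cued level)/3` for the face display, 0 for the
transfer condition (defaults 0.05 / 0.03 / 0 per TR). After a successful
block — and only then — the modality's learning rate multiplicatively
shrinks that modality's effort noise and nudges the set-point toward the
realized mean effort (precision learning). Defaults confine learning to
the continuous modality (0.25 vs 0), reflecting the qualitative pattern
the package is designed to recover: a positive run-2 success-rate delta
specific to continuous feedback. Learning acts on noise rather than gain
because the behavioral signature of interest is higher success, not
larger amplitudes.

These behavioral constants are free configuration with no quantitative
empirical counterpart; the defaults were fixed once, by forward
simulation, at an operating point with mid-range first-run success
(~60%), a clearly positive continuous-feedback learning delta, and
flat deltas for the other modalities, and recovery checks are qualitative
pattern checks only.

**Localizer.** A 4D grid with a planted set of active voxels carrying the
HRF-convolved task boxcar times the gain, independent AR(1) noise
everywhere. The ground-truth mask supports exact-recovery tests.

**Latency.** Per-volume transfer latency is lognormal (default median
454 ms, log-SD 0.294, giving an IQR of about 181 ms), replaced with
probability `outlier_prob` by a heavy-tail draw above 2000 ms; tail
events are confined to 7T sessions by default, since in practice all
extreme transfer delays occurred there. Processing time is normal
truncated at zero (default mean 296.8 ms, SD 72.9 ms). The summaries
report a normal-theory 99% CI for the mean, appropriate for the very
large per-study volume counts, and documented as approximate.

# Localizer GLM, ROI selection, and calibration

The streaming GLM maintains the running cross-products
$X'X$, $X'y$ and $\sum y^2$, so after any number of volumes the estimates
are *identical* to batch least squares (tested to 1e-8 relative). The
design is the HRF-convolved task boxcar plus intercept and linear trend;
the contrast is the task coefficient, with
$t = c'\hat\beta / \sqrt{\hat\sigma^2\, c'(X'X)^{-1}c}$ and
$df = n - \mathrm{rank}(X)$. Residual variance is floored at 1e-12 so
noise-free fixtures yield large finite t values.

ROI selection thresholds the t map and clusters suprathreshold voxels by
face adjacency (6-connectivity); the ROI is the cluster containing the
global peak t — "most significant" is read as peak-containing, not
largest. Ties break by larger cluster, then lexicographic peak
coordinate. An optional prior mask stands in for the anatomical
constraint of a real session; synthetic grids have no anatomy. Voxel
volume defaults to 2 x 2 x 3 mm³ = 0.012 cm³ for size bookkeeping.

The calibration maximum is the largest *block-mean* percent signal change
across localizer task blocks, each referenced to its preceding rest
block. A single-TR peak would let one noise spike define the 100% point;
the block mean is the stable choice, and the alternative readings (fitted
GLM amplitude, raw peak) were deliberately not used.

# Inference

Learning is tested with the exact paired two-sided Wilcoxon signed-rank
test: zero differences discarded (the classical procedure, exposed as an
explicit argument), mid-ranks for ties, $W = \min(W^+, W^-)$, and
$p = \min(1,\, 2\,P(W^+ \le W))$ under the exact null distribution,
accumulated by convolution over doubled ranks so mid-ranks stay exact.
Above `exact_cutoff = 20` effective observations a normal approximation
with tie and continuity corrections takes over. Effect sizes are Cohen's
$d_z = \bar{d}/s_d$. The Friedman test uses within-subject mid-ranks with
the standard tie-correction factor. The binomial GLMM sometimes used for
the overall modality effect is out of scope; the Friedman test is the
supported omnibus comparison.

# Numerical and degenerate-input choices

* All-zero difference vectors: degenerate, `p = 1`, `W = 0`, flagged.
* Zero-SD differences: `cohens_dz()` errors rather than returning Inf.
* Fully tied Friedman input: tie-correction factor 0, statistic defined
  as 0 (`p = 1`).
* Latency tail flags use strict inequality above the 2000 ms threshold;
  TR exceedance is a separate flag. Quantiles use linear interpolation.
* Empty suprathreshold set: `select_roi()` errors so the caller can lower
  the threshold, as an experimenter would interactively.
* Percentages are stored at full precision; rounding (1 d.p. for rates,
  2 d.p. for small percentages) happens only at display.

# Problem sizes used by the test suite

The oracle-equivalence checks run 500 random difference vectors (n ≤ 12)
against full $2^n$ enumeration, 100 random volume streams against batch
least squares, and 1000 random blocks against brute-force hit counting
and metric recomputation. Behavioral recovery simulates 200 nine-
participant, two-run cohorts; the no-learning null for the Wilcoxon
type-I check uses 1000 replicates of binomial draws on the study's own
block counts; localizer operating characteristics use 500 null grids of
4 x 4 x 4 voxels. These sizes give stable Monte-Carlo estimates for the
qualitative claims being checked while keeping the default suite fast.

# Known limitations

* The behavioral model is a deliberately simple set-point controller;
  it produces the qualitative learning signature, not participant-level
  realism (no fatigue, strategy switching, or attention lapses).
* The forward model omits physiological noise and motion, so localizer
  type-I calibration holds for white/AR(1) noise only.
* The latency model is a two-component parametric stand-in; real
  reconstruction queues have burst structure it does not capture.
* The worked-example fixture tables are synthetic by construction
  (their file names say so): they reproduce group-level marginals
  exactly but are not participant-level data.
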