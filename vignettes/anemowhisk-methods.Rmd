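---
title: "Methods: quantifying whisker-mediated wind sensing"
author: "anemowhisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying whisker-mediated wind sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anemowhisk)
```

## Overview

Rats carry roughly 300 facial whiskers, and these differ sharply in how
they respond to airflow. The long supra-orbital whisker (lSO) above the
eye — long, unusually thin for its length, dorsally exposed — behaves
like a wind antenna: it is displaced most by weak airflow, its follicle
has the most closed ring-wulst, its cortical representation responds
most strongly to wind, and silencing it degrades spontaneous turning
toward airflow stimuli. `anemowhisk` implements the quantitative
analyses needed to establish such a pattern, in four stages, together
with a seeded synthetic-data generator that emulates the statistical
structure those analyses assume:

1. **Kinematics** — whisker-tip displacement from pose-tracking tables,
   omnibus and post hoc comparisons across whiskers, high/low wind
   displacement ratios, ex vivo bending angles, wind-trace rise times.
2. **Morphometrics** — length/diameter ratios, ring-wulst aperture
   angles, correlations, fold changes against lSO, and a permutation
   test over spatial arrangements of the whisker pad.
3. **Ephys** — peri-stimulus spike binning, z-scoring, Poisson-GLM
   response classification, response-percentage time courses, latency,
   and stimulus mutual information.
4. **Behavior** — contingency and rank tests of anemotaxic turning.

## Kinematics

### The displacement statistic

For a tracked tip position $(x_t, y_t)$ at 100 frames/s, displacement is
the distance to the coordinate-wise median position,

$$ d_t = \sqrt{(X - x_t)^2 + (Y - y_t)^2}, \qquad
   X = \mathrm{median}(x), \; Y = \mathrm{median}(y). $$

On an anesthetized (static) head the median is the resting tip position,
so $d_t$ isolates airflow-driven jitter. The statistic is invariant to
translation and equivariant under uniform scaling, which the test suite
checks as properties. Medians of even-length series are the midpoint of
the two central order statistics (the standard convention). Pixel-to-cm
calibration is an explicit scalar (default 1, i.e. unit passthrough)
because tracking tables arrive in pixels with an unknown, rig-specific
scale. Tracking-likelihood filtering is off by default and available as
a threshold argument.

### Comparisons

`compare_whiskers()` pools per-frame displacement values by whisker and
applies a tie-corrected Kruskal–Wallis test (the per-frame pooling
matches the very large sample sizes this design produces; per-animal
aggregation is available by summarising first). Post hoc options are
Dunn's rank z-test (written here, with optional p-adjustment) and
Tukey's HSD on the raw values via `stats::TukeyHSD`. The H statistic is
verified in tests against a from-the-definition oracle, including tie
correction; on tiny instances the exact permutation distribution of H
is enumerated as a cross-check. At such small n the chi-square tail is
only an approximation of the exact permutation p, so tests compare the
statistic exactly and the p-value only qualitatively.

`displacement_ratio()` forms per-whisker high/low ratios of displacement
centers and applies a signed-rank test against 1. Zero differences are
dropped (Wilcoxon convention); an all-ratios-equal-one input therefore
returns p = 1 rather than NaN.

### Geometry and wind traces

`bending_angle()` locates the point at a fraction (default 0.75) of
total arc length along each polyline by linear interpolation and
returns the unsigned angle at the base between the two radii. It is
exactly invariant under rigid motion applied to both shapes and
symmetric in its arguments. `wind_rise_time()` estimates the
steady-state speed as the mean over a trailing window (default the
final 20% of the trace) and reports the first threshold crossing with
linear interpolation; a never-crossed threshold is reported as `NA`
("not reached") rather than an error.

## Morphometrics

The length/diameter ratio is dimensionless: length (mm) divided by base
diameter (µm) after unit conversion. Ring-wulst "aperture" is
operationalized geometrically: polar angles of the ring points about
the hair-shaft center are sorted and the largest angular gap (including
the wrap-around) is the aperture. A closed ring of dense points gives a
small aperture; a C-shape gives a large one. This is one defensible
formalization of a manual protractor-style measurement, and it is
isolated behind a single function so an alternative definition can be
swapped in.

### The arrangement shuffle test

Whether a scalar whisker property is spatially organized is tested by
comparing, for a candidate arrangement (partition) of the pad, the mean
within-group sample variance against a permutation null. Per-group
variance uses the unbiased estimator (n − 1); groups with fewer than two
valued members are skipped, because a singleton's sample variance is
undefined. The null permutes the assignment of values to the valued
positions uniformly at random (replicate blocks travel together), and
the one-sided p-value is the add-one proportion

$$ p = \frac{1 + \#\{\text{null} \le \text{observed}\}}{1 + B}, $$

which avoids p = 0 at finite B (default B = 10{,}000). When the number
of distinct valued whiskers is small enough that all assignments fit in
an enumeration budget (720 by default), the test switches to exhaustive
enumeration and reports the exact proportion instead — this is what
makes the small-instance oracle comparisons in the test suite exact
rather than approximate. Six standard arrangements are generated from
the grid layout (arcs; rows, with straddlers pooled into the row they
flank; distance bands from A1; 45° and 135° diagonals; distance bands
from E4); the layout ships as an editable YAML resource, and custom
arrangements are supported. Ties in the observed statistic across
arrangements resolve to the declared scheme order.

## Ephys

### Binning and z-scoring

Spike counts are taken in half-open 1-s bins $[t, t+1)$ spanning −4 to
+4 s around each wind-epoch onset; the onset sits at the left edge of
the first post-onset bin, and a spike exactly on an edge belongs to the
later bin. Epochs must be spaced so the peri-stimulus windows do not
overlap. Z-scores are computed per bin from the trial-averaged counts
against the mean and SD of the four pre-onset baseline bins; a unit
whose baseline SD is zero (e.g. a silent unit) is flagged degenerate and
excluded downstream instead of producing infinite scores.

### Poisson-GLM classification

Per-epoch per-bin counts are regressed on a five-level period factor
(baseline = the four pre-onset bins, reference level; post-onset seconds
1–4) with a log-link Poisson GLM. Each post-onset second is labeled
`excited` or `inhibited` when its Wald z-test against baseline is
significant at α (default 0.05, uncorrected across the four bins) with
positive or negative coefficient, and `none` otherwise. Complete
separation — most commonly a fully suppressed period with all-zero
counts — makes the Wald statistic degenerate (the Hauck–Donner effect),
so such periods fall back to a likelihood-ratio test against the model
with that period merged into baseline; this preserves the intended
classification in the extreme-inhibition case. Units whose fit fails
outright are flagged and excluded from response percentages. Simulated
null units recover the nominal false-positive rate and tripled-rate
units are detected essentially always; both checks run in the test
suite at 500 and 100 simulated units respectively.

### Latency

Latency is the post-onset bin (1–4) where the z-score is maximal,
provided that maximum surpasses 2 baseline SDs; ties break to the
earliest bin, and degenerate or sub-threshold profiles return none.
The rule is deliberately applied verbatim, including the tie and
exactly-at-threshold cases.

### Mutual information

For one wind condition, the stimulus variable S is binary
(condition-wind vs no-wind) and the response R is the 1-s spike count,
capped at a configurable maximum (default 10, pooling the tail) to
limit plug-in bias. For each post-onset second the samples are that
second's counts over the condition's epochs (S = wind) pooled with the
baseline-bin counts of the same epochs (S = no-wind), and the plug-in
MI in bits is computed from the empirical joint table via the entropy
decomposition $I(R;S) = H(R) + H(S) - H(R,S)$. MI is nonnegative,
bounded by $H(S) \le 1$ bit, and invariant to relabeling of count
symbols; the implementation is checked exhaustively against a
conditional-probability double-sum oracle on all small tables.

A baseline ("bias floor") MI is needed to normalize: between −4 and 0 s
there is only the no-wind class, so the same estimator is applied per
baseline second with that second playing the pseudo-stimulus role
against the remaining baseline seconds (leave-one-bin-out). This keeps
the true MI at zero and the sample sizes close to the post-onset
estimate, so the floor captures estimator bias at matched conditions,
and it is fully deterministic. Normalized MI is the per-second MI over
the mean baseline MI; the population-level test compares normalized MI
against 1 per second with a two-tailed signed-rank test at a
Bonferroni-style α (default 0.003).

## Behavior

Turning responses are scored per trial as toward / away / none relative
to the stimulus side. Four analyses:

- **Direction bias** — one-df chi-square goodness-of-fit of toward vs
  away counts against equal expectation, no continuity correction,
  no-reaction trials excluded (a three-category table can be formed by
  the caller if desired).
- **Stimulus strength** — two-sided Fisher exact test on the 2×2 table
  of toward vs not-toward across two stimulus types, with the standard
  "sum of tables no more probable than observed" two-sided convention.
- **Group comparison** (e.g. wind-responsive vs control trimming) —
  Mann–Whitney rank-sum on per-animal toward-fractions; the sampling
  unit is the animal.
- **Paired comparison** (e.g. lidocaine vs Ringer at the supra-orbital
  follicles) — Wilcoxon signed-rank on paired per-animal fractions,
  zeros dropped, plus the count of animals showing a decrease.

The rank tests are the package's exact small-sample implementations:
for small n the null distribution is built by complete enumeration
(sign patterns via a generating-polynomial convolution over doubled
midranks; group assignments via combinations), which remains exact
under ties, where the usual exact algorithms refuse; larger samples use
tie-corrected normal approximations with continuity correction. In the
tie-free regime the exact p-values reproduce `stats::wilcox.test`
exactly, which the tests verify.

## The synthetic-data generator

The generator exists so every analysis can be exercised, calibrated and
power-checked end to end with known ground truth. All randomness flows
from one integer seed through per-generator substreams; identical
configurations give identical outputs. Defaults encode the study
conditions the analyses assume:

- **Trajectories**: 26 whiskers (rows A–E × arcs 1–4, straddlers
  α–δ, lSO, sSO), 6{,}000 frames at 100 fps (one minute of video).
  Tips jitter isotropically (Gaussian) about fixed base points — an
  anesthetized head moves only with the wind — with jitter SD given by
  a per-whisker amplitude at 0.5 or 1.5 m/s. The low-wind profile makes
  lSO maximal (0.30 cm), followed by α, β and A1 (0.15 cm); the
  wind-responsive subset roughly triples at high wind while the rest
  barely change. Active whisking is deliberately not modeled.
- **Morphometry**: correlated Gaussian records (clipped at physical
  bounds), four replicates per whisker. Length–diameter correlation
  targets 0.83; the ring-wulst aperture couples to the standardized
  length-minus-diameter contrast (a linear proxy for the log ratio)
  with target −0.66. The lSO means are shifted — slightly longer (+2 mm
  on a 25 mm mean), markedly thinner (diameter × 0.55) and with a
  120° more closed aperture — so lSO carries the extreme configured
  ratio and the most closed ring-wulst. Apart from lSO the generator is
  spatially homogeneous: it does not emulate the gradual spatial
  gradients of real pads, so arrangement-shuffle p-values on default
  synthetic morphometry are null-calibrated (≈ uniform), and the
  spatial-structure recovery tests construct structured values
  explicitly.
- **Spike trains**: a balanced randomized block sequence of low-,
  high- and no-wind epochs (10 s each, 10 per speed — the recordings
  this emulates delivered 12–30 wind events per animal — separated by
  10-s gaps so the 4-s pre-onset windows fit). Units are inhomogeneous
  Poisson: baseline 5 Hz; excited units multiply the baseline by a
  per-second gain profile during post-onset seconds 1–4, inhibited
  units divide by it, null units stay constant. The default profile
  (2, 3, 2, 1.5) is submaximal in second 1 — the wind itself takes
  about 1.5 s to reach 80% of its mean — peaks in second 2 and decays,
  which is what makes modal latency and the MI peak land in second 2.
  40 units per region; the supra-orbital region has 30% excited / 10%
  inhibited units at full gain, the pad region 10% / 10% with gain
  deviations attenuated to 30% ("mixed weak"). Unit counts and rates
  are not printed quantities anywhere; they are chosen as realistic
  for anesthetized cortical recordings with modern probes.
- **Behavior**: multinomial toward/away/none draws per trial, balanced
  stimulus sides, 16 trials per session (sessions in this paradigm run
  13–20). Condition probabilities come from the printed group outcomes:
  hand-flap (0.31, 0.07, 0.62), cardboard (0.48, 0.10, 0.42), trimming
  20% vs 29% toward, lidocaine 18% vs Ringer 23%. Unpaired designs get
  an independent cohort per treatment; paired designs give every animal
  both treatments.
- **Wind traces**: first-order exponential rise plus white turbulence
  noise. The time constant τ = 1.5/ln 5 ≈ 0.93 s places the noise-free
  80% crossing at 1.5 s. A single first-order system cannot also put
  the 95% crossing at 2.5 s (it lands at 2.8 s); the 80% point was
  chosen as the calibration anchor, and the discrepancy is accepted as
  a limitation of the one-parameter rise model.

What passing the recovery tests shows — and what it does not: the
pipeline correctly recovers rankings, response fractions, effect
directions and calibrated error rates from data whose generating model
matches the analysis assumptions (Gaussian jitter, Poisson spiking,
multinomial choices). Real recordings add tracking error, slow drifts,
bursting and overdispersion, correlated trials and spatial morphometric
gradients, none of which the generator emulates; conclusions about
robustness to those features require real data.

## Numerical and design choices

- Permutation p-values use the add-one convention when sampled and the
  exact proportion when exhaustive.
- Exact signed-rank and rank-sum enumerations switch to tie-corrected
  normal approximations above n = 16 retained differences /
  2×10⁵ assignments; two-sided exact p is `min(1, 2·min(tails))`.
- With all per-animal paired differences at the printed 18% vs 23%
  toward-rates and 20 trials per session, per-animal binomial noise
  (SD ≈ 0.13 per difference) leaves the sample median difference
  negative in only ≈ 80% of replicate studies; the recovery test
  asserts a bound derived from that model rather than near-certainty.
- The GLM treats counts as the response and period as the categorical
  predictor — the only reading consistent with a Poisson GLM on
  peri-stimulus histograms.
- MI response discretization is the raw capped count; cap 10 bounds the
  joint table at 22 cells and keeps plug-in bias manageable at tens of
  epochs. No further bias correction is applied.
- Test and acceptance problem sizes (e.g. 500 null units for the size
  check, 200 datasets × 1{,}000 shuffles for permutation uniformity,
  50 replicate studies for end-to-end recovery, 300–6{,}000 frames per
  trajectory) were chosen to make Monte-Carlo bounds comfortably
  discriminating at desk scale.

## Limitations

- The aperture definition is one formalization of a manual measurement;
  others (e.g. arc-fraction coverage) would need their own validation.
- The plug-in MI estimator is biased upward at small samples; the
  baseline floor normalization compensates on average but is itself an
  estimate.
- The behavior generator draws i.i.d. trials; sequential effects
  (habituation, side biases drifting over a session) are not modeled.
- Displacement pools frames as if independent; frame-to-frame
  autocorrelation inflates the effective sample size of the pooled
  Kruskal–Wallis test, which is why per-animal summaries are also
  provided.
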