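---
title: "Models and methods for multi-word reading experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-word reading experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiword)
```

## The scientific problem

Text-selective regions of left ventral occipito-temporal cortex (pOTS-words,
mOTS-words, mFus-words — collectively the "visual word form area") respond
more strongly the more words a trial contains, and respond more strongly to
low- than to high-frequency words. A central question is whether two words
flashed *simultaneously* are processed the way two words flashed in rapid
*sequence* are. The experimental paradigm this package implements holds
visual stimulation constant — every trial shows three 183 ms frames with two
character strings each, most of them illegible false-font fillers — and
varies only how many legible words appear and when: none, one, two in
sequence, or two at once. The package provides the full computational
machinery around that paradigm: the counterbalanced trial-design generator,
evidence-accumulation models that predict BOLD responses, the eye-tracking
quality-control pipeline, the single-trial mixed-effects analyses, a power
analysis for the paired sequential-vs-simultaneous contrast, and synthetic
generators that make every stage testable against known ground truth.

## Evidence-accumulation models

Each word's neuronal activation rises linearly at `slope` (evidence/ms)
until it reaches a recognition threshold or the next frame interrupts
processing; the predicted BOLD response for a trial is the integral of
activation over time summed over words. Low-frequency words carry a higher
threshold (`theta_low` ≥ `theta_high`), so they are processed longer and
produce a larger area — the lexical frequency effect.

The per-frame processing window is the stimulus onset asynchrony,
183 + 50 = 233 ms: processing of a frame's words ends when the next frame
(or the frame-3 post-mask) arrives. By default activation *resets* to zero
at threshold, so a completed word contributes area $\theta^2 / (2s)$; a
plateau variant (activation held at threshold until the window ends) is
kept as an option because schematic illustrations of such models do not fix
this choice. Both variants preserve the qualitative orderings below.

Four model variants differ only on simultaneous trials:

* **Serial** — word 2 starts when word 1 crosses threshold and is truncated
  at the window end. The frequency effect survives but shrinks: with the
  defaults the sequential effect is 156 a.u. and the simultaneous effect
  54.6 a.u.
* **Limited-capacity parallel** — both words accumulate for the full window
  at `slope / kappa`. When the reduced slope cannot reach either threshold
  within the window, the areas are threshold-independent and the
  simultaneous frequency effect is *exactly zero*.
* **Unlimited-capacity parallel** — simultaneous words are processed
  exactly like sequential ones; it predicts identical tables across
  presentation conditions and is the pattern the behavioral data reject.
* **Hybrid parallel-then-serial** — sublexical evidence for both words
  rises in parallel to half threshold; lexical completion is serial, with
  word B's activation silent (evidence retained) while word A completes,
  then reinstated. Both word areas equal $\theta^2/(2s)$, so the
  simultaneous total equals the sequential total.

### Parameter defaults

`slope = 0.01`/ms, `theta_high = 1.0`, `theta_low = 1.6`: sequential words
complete well inside the window (crossings at 100 and 160 ms < 233 ms). The
interference factor default is `kappa = (slope * window / theta_high)^2 =
5.43`. Two constraints drive it: the reduced slope must fail to reach even
the high threshold within the window (`0.01/5.43 * 233 = 0.43 < 1`), which
zeroes the simultaneous frequency effect, and the simultaneous totals should
land near the sequential high-frequency total, the second signature pattern
of this model. A smaller factor (e.g. 2.5) also satisfies the first
constraint but puts the simultaneous totals (217 a.u.) closer to the
sequential *low*-frequency total (256 a.u.) than the high one (100 a.u.),
reversing the intended pattern; all package functions accept any
`kappa >= 1`.

The hybrid concretization deserves a note: a variant in which word B's
activation *holds* at the sublexical level h while word A completes cannot
produce equal word areas — the hold adds $h(\theta - h)/s > 0$ to B's area
for any $0 < h < \theta$. The silent-hold form used here is the one that
satisfies both stated constraints (equal areas; simultaneous total equals
sequential total) exactly.

Model areas have closed forms; every `accumulate()` trace embeds its
breakpoints in the time grid (duplicating the reset discontinuity as a
zero-width segment) so trapezoid integration of the trace reproduces the
closed form to < 1e-9 relative error, which the test suite exploits as an
independent oracle.

A caveat on monotonicity: with reset semantics the area is *not* monotone in
`kappa` — as the effective slope rises past the crossing point the area
switches from $sT^2/2$ (increasing) to $\theta^2/(2s)$ (decreasing). Under
the plateau variant area is monotone in slope, hence antitone in `kappa`.

## The design generator

A default session is 8 runs of 64 trials: 128 trials per condition, all
counts exact rather than in expectation. One-word trials cross frame (1 or
2) with location (top or bottom), 32 trials per cell; two-word sequential
trials counterbalance the first word's location; two-word simultaneous
trials counterbalance the frame. A blank of 4, 6 or 8 s (uniform) follows
every block of five trials, including the last.

Word lists: the 768-word lexicon is split into four condition groups sized
(128, 128, 256, 256) — exactly the number of legible slots needed by the
one-word and two-word conditions, with the zero-word group supplying coded
false-font items. Groups are balanced on standardized log frequency and
orthographic neighborhood by seeded random assignment followed by
hill-climbing pairwise swaps until the largest pairwise gap in group means
is below 0.05 (standardized units); six distinct lists are produced from
six random starts. Every legible word appears at most once per session.
Because a session has 3072 string slots but only 768 words, false-font
fillers are sampled *with reuse* from the words never shown legibly in that
session — legibility, not mere appearance, is what "presented exactly once"
protects.

Trial timing is stored in integer milliseconds; total stimulus time is
3 × 183 + 2 × 50 = 649 ms (a figure sometimes rounded to 650 ms); the
response period is 3651 ms after the final frame.

## Eye-tracking quality control

The pipeline order is fixed: run gate → trial gate → drift correction →
event detection.

| rule | threshold | convention |
|---|---|---|
| run gate | median pre-onset 2-D SD > 1° | strict (exclude) |
| pre-onset window | 250 ms | — |
| trial gate | ≥ 80% acceptable samples | inclusive |
| plausibility | > 10° from fixation mark | strict (bad) |
| drift-correction gate | ≥ 90% acceptable pre-onset | inclusive |
| fixation break | > 1.5° for ≥ 100 ms | strict distance, inclusive time |
| blink | pupil 0 for ≥ 100 ms | inclusive |
| saccade velocity | outside 4 × median-SD ellipse for ≥ 6 ms | inclusive time |
| saccade amplitude | > 1° and < 15° | strict both ends |
| word fixation | ≥ 50 ms cumulative in bounding box | inclusive |

Velocities use the standard 5-sample moving-window central difference; the
median-based SD is $\sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$ per
component, floored at 1e-6 (a degenerate floor on both axes flags the trial
and suppresses detection rather than dividing by zero). Supra-threshold
runs separated by less than 4 ms are merged. Duration thresholds convert to
sample counts by rounding toward inclusion, so decisions are unchanged
across sample rates (250–1000 Hz) on noise-free inputs. Two genuinely open
conventions are resolved as: the run gate uses the pooled radial SD
$\sqrt{\mathrm{var}(x) + \mathrm{var}(y)}$; when drift correction finds no
qualifying trial the run is analyzed against the raw fixation mark and
flagged.

## Single-trial statistics

Every trial's stimulus is coded as one item string: concatenated words
(frame order for sequential, top-then-bottom for simultaneous — the
presentation-order choice), the single word, or a sampled frame-1/2 filler
suffixed `_ff` for zero-word trials. This gives each trial a unique item
for the stimulus random effect.

`fit_mixed()` fronts `lme4` with the conventions fixed: Gaussian models by
ML (so BIC comparisons are coherent), binomial by Laplace `glmer`; a
convergence ladder (full random slopes → diagonal covariance → intercepts
only) with the reduction recorded; and all F tests computed as Wald tests
from the fitted covariance with denominator degrees of freedom
`n_observations - n_fixed_effects`. Accuracy models use reference dummy
coding with the zero-word condition as reference. RTs are measured from the
critical frame (frame 2 except for simultaneous pairs in frame 1); trials
with two words in frame 1 or one word in frame 1 are excluded from RT
analysis, zero-word trials retained. FDR correction is Benjamini–Hochberg
across regions at q = 0.05. `bayes_factor_bic()` is a labelled BIC
approximation, not a replication of toolbox Bayes factors computed on
trial-averaged data.

## Synthetic generators

`gen_betas()` is the generative inverse of the mixed models: beta =
intercept + subject intercept + item effect + (slope + subject slope) × W −
(suppression + subject suppression) × [simultaneous] + frequency term +
residual. ROI presets carry the published single-trial estimates as
generating truth — number-of-words slopes 0.116 (pOTS-words), 0.100
(mOTS-words), 0.109 (mFus-words) psc/word and the corresponding
sequential-minus-simultaneous differences — while the variance components
are the package's own defaults: subject intercept SD 0.1, subject slope SD
0.05, item SD 0.05, residual SD 0.4 psc, chosen to reproduce standard
errors of realistic magnitude (e.g. a slope SE near 0.015 at 20 subjects).
The subject-level suppression SD (0.05) exists because the suppression
model's by-subject random slope presumes such variability; its size follows
from the reported suppression standard errors (≈ 0.01 at n = 20 implies a
subject SD near 0.045). Without it, null simulations of the suppression
contrast run conservative because the slope variance is estimated at the
boundary.

Behavioral presets: per-condition accuracies (0.95, 0.89, 0.91, 0.86) and
lognormal RTs ordered zero < sequential < one < simultaneous are
order-of-magnitude choices — the corresponding empirical means are only
published graphically — and errors on simultaneous trials report "one word"
94% of the time (a missed second word). The optional model linkage scales
simultaneous accuracy by how far the chosen accumulator model lets word 2
rise toward threshold, guaranteeing the simultaneous deficit whenever word
2 is left unfinished.

`gen_gaze()` emulates fixation noise as white Gaussian jitter with injected
raised-cosine saccades, blinks and square-wave excursions, all recorded in
a truth table for detector scoring. Real gaze has autocorrelated drift,
smooth pursuit and asymmetric noise that white jitter does not capture, so
detector performance on these traces bounds idealized, not field,
behavior.

## Power analysis

The paired design assumes a single-word mean of 0.32 psc with SD 0.2; the
sequential mean exceeds the simultaneous mean by the suppression effect
delta. Because the effect size behind the original sample-size choice is
unpublished, `suppression_delta` is a required input rather than a default.
As a calibration exercise: a target of 18 subjects at 90% power and alpha
0.05 corresponds to a standardized paired effect d ≈ 0.82
(`minimal_n_closed_form(0.82)` = 18), i.e. delta ≈ 0.82 × 0.2 × √2 ≈ 0.23
psc under independent condition draws. The Monte-Carlo estimator draws
paired differences directly (SD = sd × √2), tests with a two-sided paired
t, and smooths power by a running maximum over n before applying the
minimal-n rule; the noncentral-t closed form serves as its oracle.

## Problem sizes and numerical choices

The test suite exercises full-scale designs (512 trials) where cheap, and
reduced mixed-model problems elsewhere: slope recovery uses 20 replicates
of 15–20 subjects × 384 trials; type-I calibration uses 200 replicates of
20 subjects × 64 trials per condition; detector scoring uses 100 trials per
setting; power checks use 4000–5000 Monte-Carlo replicates. The FDR oracle
samples 0.01-grid p-vectors up to length six rather than enumerating all
101^6 of them. Closed-form/trapezoid agreement is asserted at 1e-9 relative
error on a 0.1 ms grid. All generators are exactly reproducible under their
seeds; seeded scopes restore the caller's RNG state.

## Known limitations

* The accumulator models are deliberately unfitted, qualitative mechanisms;
  no hemodynamic convolution or quantitative parameter estimation is
  attempted, mirroring their proof-of-concept role.
* `bayes_factor_bic()` approximates; it will not reproduce toolbox values.
* Gaze generation does not model slow drift, pursuit, or EyeLink parsing;
  native ASC files must be converted to the long CSV schema upstream.
* The degrees-of-freedom convention (n_obs − n_fixed) is anticonservative
  relative to Satterthwaite-style corrections when subject-level variance
  dominates; it is used deliberately, as the convention under study.
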