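---
title: "Measuring segmentation agreement on dynamic choropleth maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring segmentation agreement on dynamic choropleth maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmap)
```

## The problem

When people watch an animated thematic (choropleth) map — regions of a
fixed outline whose colours change over time — they spontaneously divide
the stream into discrete events, just as they do for films or everyday
activities. The standard paradigm asks each viewer to press a key whenever
one meaningful unit ends and another begins. The scientific questions are
(a) whether viewers agree with each other above chance on *when* those
boundaries occur, and (b) how that agreement depends on the depicted data
trend, on conceptual framing (e.g. a declining *endangered* species versus
a spreading *invasive* one), and on the perceptual salience of the change
direction (colour-scale class, or whether the changing regions are
spatially clustered).

`segmap` implements that entire measurement and inference chain as
reproducible, seeded code: stimulus generators, a synthetic-participant
simulator, the scaled agreement measure with its permutation null and
specificity contrasts, and the factorial mixed models with marginal
effects and power simulation.

## The agreement measure

Per trial, presses are **debounced** (a press under 0.5 s after the last
*retained* press is discarded — chaining is greedy, relative to the
retained press, not the raw predecessor) and **binned** into one-second
half-open bins `[b, b+1)`; a press at exactly the stimulus end clamps into
the last bin. The binary series $x$ is correlated with the **group norm**
$p$, the per-bin proportion of all *other* participants who pressed there
(proportions rather than percentages — correlation is scale-invariant).
Because $r_{obs} = \mathrm{cor}(x, p)$ depends mechanically on the number
of presses $k$, it is rescaled by the extreme correlations attainable at
that $k$:

$$\textit{agreement} = \frac{r_{obs} - r_{min}}{r_{max} - r_{min}} \in [0, 1],$$

where $r_{max}$ ($r_{min}$) places the $k$ ones on the $k$ largest
(smallest) norm values. At fixed $k$ the correlation is an increasing
affine function of $\sum_{x_b = 1} p_b$, so these placements are the exact
extrema — the package's tests verify them against exhaustive enumeration
over all $\binom{n}{k}$ placements up to $n = 12$. Ties in the top-$k$ /
bottom-$k$ selection are broken by the earliest bin index; the tie-break
cannot change the attained correlation, only the reported placement.
Trials with $k = 0$, $k = n$, or a constant norm have no defined
agreement; they are excluded *and counted* in an exclusion audit, never
silently dropped.

## Chance level and specificity

The null hypothesis of randomly timed presses is simulated by permuting
every participant-by-stimulus binary vector independently (press counts
preserved, placement randomized) and recomputing all agreements with
leave-one-out norms from the permuted data; the iteration statistic is the
mean sample agreement (default 10000 iterations). The two-tailed p is the
symmetric tail mass around the null mean, $P(X \le \mu - d) + P(X \ge \mu
+ d)$ with $d = |obs - \mu|$, each tail estimated with add-one smoothing,
so the smallest attainable value is $2/(\text{iterations}+1)$. (A
published variant of this formula reads as $P(X < \mu - d) + (1 - P(X >
\mu + d))$, which evaluates near 1 as written; we treat it as a
typographical variant of the symmetric-tail definition and document the
discrepancy rather than resolve it.)

Above-chance agreement alone could reflect generic strategies (avoid the
first seconds, spread presses out). The **cross-stimulus contrast**
therefore scores every response against the norms of each *other*
stimulus — 15 stimuli yield 14 cross records per trial — and the
**cross-group contrast** scores it against the other experimental group's
full norm. Whether the original analysis excluded the focal participant's
own response to the *other* stimulus is not stated; we apply leave-one-out
uniformly. Agreement is always computed within an experimental group;
grouping is an explicit column, never inferred.

## Stimulus generators

All series are defined on integer-second keyframes (61 for a 60-s
stimulus, 31 for 30 s); the 24-fps rendering of the original displays is
linear interpolation between keyframes and is out of analysis scope, since
the analysis bins at 1 s.

* **Random piecewise-linear dynamics** (60 s): the global value starts at
  0 and each second advances by the current slope, drawn uniformly from
  $[-1, 1]$; the slope changes at 5–10 distinct interior seconds (drawn
  without replacement, sorted). The global series is min-max rescaled to
  $[0,1]$, per-region Gaussian noise (sd 0.1) is added independently per
  region *and second*, and the full matrix is rescaled again — so its
  minimum is exactly 0 and its maximum exactly 1. Whether the original
  region noise was i.i.d. per second, smoothed, or a static offset is not
  stated; i.i.d. is the default and a moving-average option
  (`smooth_noise`) is exposed rather than guessed at.
* **Linear-trend factorial** (30 s): the nominal trend lies on the 8-point
  grid $-1.00, -0.71, \dots, 1.00$; the start value is uniform on the
  feasible interval $[\max(0, -t), \min(1, 1-t)]$, so a trend of $-1$
  forces a start of 1. Noise is added as above but values are *truncated*
  to $[0,1]$, never rescaled, preserving the trend manipulation. With the
  0.1 noise the truncation bias of the realized trend is below 0.02
  (verified by Monte-Carlo).
* **Spatial-pattern factorial** (30 s): 3 or 4 of the 10 regions carry the
  trend (grid $-1, -0.5, 0.5, 1$) from a shared feasible start; the
  remaining regions hold constant baselines plus noise. Changing regions
  are selected starting from a uniformly random region, then grown under
  a connectivity constraint (clustered) or an independence constraint
  with a random fallback when no non-adjacent region remains
  (distributed). Stable baselines are drawn uniformly from $[0.2, 0.8]$ —
  unstated in the original materials; this range keeps truncation rare.
  We draw one baseline per stable region rather than one per stimulus:
  distinct levels make the changing subset less conspicuous, which is the
  point of the 3-vs-4 masking factor.

Region geometry is a Voronoi tessellation of 10 uniform points in the
outline, computed by half-plane clipping; adjacency is read off the
surviving bisector edges *before* cosmetic border noise (a symmetric
midpoint displacement, at most 2% of the outline diameter, keyed on the
region pair so both sides move identically and the partition stays exact).
Strongly non-convex outlines are not supported; the default outline is the
unit square.

Every generator draws from sub-streams derived deterministically from one
root seed per stimulus (geometry, start value, noise, selection), so any
stage can be regenerated independently and runs are bit-reproducible.

## The response model

No participant model exists in the source literature; the simulator is an
artifact convention whose only job is to produce logs with the statistical
structure the analysis assumes. Per second,

$$h_t = \mathrm{clip}\big(\textit{base} + \gamma\,|\Delta g_t| +
\kappa\, c_t,\; 0, 1\big),$$

with $\Delta g_t$ the one-second change of the global series, $c_t =
|\Delta g_t|$ when the stimulus' trend direction is congruent with its
framing (invasive–rising, endangered–falling) and 0 otherwise, and
$\gamma$ halved for low-salience stimuli (hue scales, distributed change).
Participants get a multiplicative log-normal intercept (sd 0.4); presses
are Bernoulli draws per second, placed uniformly within the second, then
thinned to a 0.5-s refractory gap. Defaults (`base_rate` 0.05,
`change_gain` 1.5, `congruence_gain` 0.75) give roughly 3–4 presses per
30-s trial, matching the press frequency of the factorial experiments;
they are conventions, not estimates of human behaviour. The linear-clipped
(rather than logistic) hazard keeps parameter recovery transparent:
regressing simulated per-bin press proportions on $|\Delta g_t|$ returns
the change gain within 10%.

The congruence term is what lets the inference stage exhibit a
trend-by-framing-by-salience interaction on synthetic data. What passing
tests show is therefore that the *pipeline* detects such structure when it
is present and stays calibrated when it is absent — not that human viewers
behave this way; conclusions about people need the original (or new)
response data, which the I/O layer can ingest from CSV logs.

`make_paper_fixture()` reproduces the two factorial datasets' exact trial
accounting — 117 × 31 trials with 267 empty and 11 post-video-only logs
(3349 analyzable), and 176 × 32 with 395 and 13 (5224) — by designating
defective trials seed-randomly and guaranteeing every other trial at least
one press.

## Mixed models, marginal effects, power

Models are fit by REML with Satterthwaite degrees of freedom
(`lmerTest`) and Wald 95% intervals, treatment coding with references
*endangered*, *hue*, *distributed*, and *cross-stimulus*; trend stays
numeric on its natural scale. Boundary (zero-variance) random effects are
reported, not hidden; rank-deficient fixed effects raise an error naming
the aliased terms. The standardized effect $d$ divides a coefficient by
the square root of the summed random-effect and residual variances — the
original reports do not define their $d$, so this is a documented
convention, not a claim of equivalence.

The marginal effect of trend in a framing × salience cell is the sum of
the active trend coefficients, with a delta-method standard error; for
this linear model it equals the averaged numeric derivative of the
population predictions to machine precision, and both routes are computed
and compared in the tests.

`power_simulation()` draws per-participant random-effect vectors from the
published variance components (intercept/slope SDs 0.0911, 0.0310, 0.0028,
0.0142 with their correlation matrix; residual SD 0.1777), sets every
fixed effect to zero except the three-way interaction, refits the full
model per replicate, and reports the rejection fraction with an exact
binomial CI. Non-convergent replicates count as non-rejections and are
reported separately (conservative and auditable). At effect 0 the
rejection rate sits at the nominal level.

**A documented tension:** the published a-priori power claims (0.80 at
n = 125, 0.85 at n = 175, effect 0.02) are not reachable under these
fitted components. The fitted model's own interaction standard error was
0.019 at n = 117; scaling by $\sqrt{n}$ gives ≈ 0.017 at 125 and ≈ 0.012
at 175, hence power ≈ 0.2–0.4 at an effect of 0.02. Reaching 0.80 at
n = 125 would need a residual SD near 0.07 — far below the fitted 0.178 —
so the original simulations must have assumed a much less noisy process;
those assumptions were not published. The package reports what the stated
components actually imply rather than tuning toward the published number.

## Problem sizes and numerical choices

The test suite simulates at reduced but fully stated sizes, chosen as the
package's own trade-off between Monte-Carlo resolution and runtime:
calibration uses 100 replicate cohorts of 20 participants × 5 stimuli
(30-s stimuli) with 1000-iteration nulls; Wald coverage uses 500
replicates of a small random-intercept design; power runs use 200
replicates. Degenerate inputs follow explicit rules spelled out above
(k = 0 / k = n trials, constant norms, constant outcomes, zero-area
outlines, stranded clustered selections), each either an audited
exclusion or a named error — never a silent fallback.

## Known limitations

* The Voronoi construction assumes a convex (or near-convex) outline.
* The simulator omits latency shifts, fatigue, repeated viewing and
  attention-check behaviour by design.
* Count outcomes (press frequency) are modelled linearly, mirroring the
  original analyses, not with count families.
* The permutation null treats bins as exchangeable within a trial; the
  0.5-s refractory period induces a slight negative serial dependence
  that the null ignores. At realistic press rates the effect is
  negligible (the calibration test bounds it empirically).
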