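---
title: "Modelling first lactations and comparing them across gestation-length categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling first lactations and comparing them across gestation-length categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactshape)
```

## The question and the data

A primiparous cow that calves after a short gestation — spontaneously or
following an abortion — begins lactating with a mammary gland that had
less time to develop, since most parenchymal growth happens in late
pregnancy. The analysis this package implements asks how the *shape* of
the first lactation, not just its total, varies with gestation length
(GL), using only data that ordinary herd management software records:
daily milk weights keyed by herd, animal and days in milk (DIM), and
reproduction events (birth, last insemination, calving).

The pipeline has five stages: validity filtering of daily records,
assembly of per-animal lactations, per-lactation curve fitting, GL
categorization, and mixed-model comparison of the derived traits.

## Validity filters and lactation assembly

Daily records are kept when `1 ≤ DIM ≤ 305` and the daily yield lies in
`[1.0, 70.0]` kg; all bounds are inclusive, and every removal is tallied
by rule so that retained + dropped always reconstructs the input. DIM is
anchored so that the day of calving is DIM 0 and the first recordable
milking DIM 1, which makes the filter's "beyond 305" cut coincide with
the model's time axis and the 305-day integral.

GL is the whole-day difference between calving and last insemination;
values outside 150–297 d mark the record excluded (they are flagged, not
errors, because out-of-window intervals are expected in raw data; a
calving dated before its insemination, by contrast, is a data error). A
lactation enters the analysis when its *last retained milking falls at
DIM ≥ 10*. We read the minimum-data rule as a requirement on reach into
the lactation rather than on record count; the alternative reading (at
least 10 records) is available as `min_dim_rule = "n_records"` since
sparsely recorded herds make the two differ. Age at first calving (AFC)
is stored in days and displayed in months (days/30.4375). One lactation
per animal: a duplicate reproduction record raises an error rather than
silently overwriting.

## The MilkBot curve and its closed-form traits

Daily yield is modelled as

$$y(t) = a\left(1 - \tfrac{1}{2}e^{(c-t)/b}\right)e^{-dt}$$

with scale $a$ (kg/d), ramp $b$ (d), offset $c$ (d) and decay $d$ (1/d).
The first factor is a saturating ramp: at $t = c$ production is exactly
half of its potential, and it approaches the full potential with time
constant $b$. The second factor is exponential senescence. For
$t < c - b\ln 2$ the raw model is negative; we return the raw value
(fitting needs it) and clamp only in display utilities.

Three traits derive in closed form:

* $t_{peak} = c - b\,\ln\!\frac{2bd}{1+bd}$, the curve's stationary
  point. It is a usable within-lactation peak only when $bd < 1$;
  at $bd \ge 1$ it falls at or before the offset and the curve is
  effectively monotone over the biological range, so the trait is
  flagged `peak_defined = FALSE` rather than reported. At $d = 0$ no
  finite peak exists and `NA` is returned with the flag.
* peak yield $= y(t_{peak})$.
* cumulative yield
  $\int_0^{T} y\,dt = \frac{a(1-e^{-dT})}{d}
  - \frac{ab\,e^{c/b}}{2(1+bd)}\left(1-e^{-T(1/b+d)}\right)$, with
  $T = 305$ giving M305. For $d < 10^{-12}$ the analytic limit
  $aT - \tfrac12 ab\,e^{c/b}(1-e^{-T/b})$ is used; the switch point is
  far below any biologically plausible decay, and the test suite checks
  continuity across it.

These closed forms are validated property-style against independent
numeric oracles — adaptive quadrature for the integral (agreement within
0.01 kg over 1,000 random admissible parameter sets) and golden-section
maximization for the peak (within $10^{-4}$ d) — rather than against any
single worked example.

## Fitting

Each lactation is fitted independently by ordinary (unweighted) least
squares on its daily yields, using bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) inside the box $a \in (0, 120]$ kg/d,
$b \in [1, 120]$ d, $c \in [-30, 30]$ d, $d \in [0, 0.02]$ /d — generous
envelopes around primiparous Holstein values, configurable in
`milkbot_control()`. The deterministic start is
$a_0 = 1.1\,\max(\text{yield})$, $b_0 = 25$ d, $c_0 = 0$, $d_0 = 0.0015$
/d; four further starts jitter these (relative log-normal jitter for
$a, b, d$; additive for $c$, whose sign is meaningful), and the best
converged attempt wins. Convergence tolerances are $10^{-12}$ on relative
objective and parameter change, at most 500 iterations per start. The
jitter stream is seeded per animal from the control seed, so cohort fits
are reproducible and independent of fitting order. Fits with fewer than
10 points are refused explicitly rather than attempted.

Weighting was left ordinary because the observation noise of daily
weights is approximately homoscedastic on the kg scale, and because
per-lactation weighted schemes would change the meaning of the residual
sum of squares reported downstream.

## Gestation-length categories

Five ordered categories C-I…C-V are defined by four cut-points, either
data-driven or fixed. The fixed reference scheme uses 243/267/275/283 d;
interval membership is lower-exclusive/upper-inclusive exactly as those
boundaries are conventionally printed (a GL of 243 is C-I, 244 is C-II,
297 is C-V), with C-I additionally closed at 150. Data-driven cut-points
are the empirical quantiles at probabilities 0.01/0.05/0.25/0.75 (type-7,
linear interpolation of the empirical CDF), giving nominal shares
1/4/20/50/25%.

Quantile cut-points are deliberately *not* rounded to whole days by
default. GL distributions concentrate several percent of a cohort on
single modal days (a normal bulk with SD ≈ 5.5 d puts ≈7% of animals on
the modal day), so flooring a cut-point can move a category's share by
several points and defeat the purpose of quantile categorization;
`round = "floor"` is provided for workflows that require whole-day
cut-points and accept the share distortion. Categories are computed after
all exclusions (the cohort actually analysed defines its own quantiles);
computing them earlier is possible by calling `gl_quantile_scheme()` on
any GL vector.

## The trait comparison model

For each trait in turn (M305, scale, ramp, decay, time to peak, peak
yield) we fit

```
trait ~ category + calving_month + calving_year + afc + (1 | herd_id)
```

by REML (`lme4::lmer`). Month and year enter as unordered factors without
interaction; AFC is a linear continuous covariate. Factors that are
constant in the data are dropped with a message (simulated cohorts often
have no calendar variation), a single-herd dataset falls back to a fixed
effects model with a warning, and a rank-deficient fixed design (e.g. a
calendar level perfectly confounded with a category) raises an error
naming the aliased columns before any fitting happens.

LS-means per category are estimated marginal means at equal weights over
the calendar factors and at the sample mean of AFC (`emmeans`); all ten
pairwise contrasts are reported unadjusted, since the letter superscripts
conventionally reported for this analysis encode unadjusted pairwise
tests (a Tukey adjustment is one argument away). p-values use the
large-sample normal reference by default: the intended cohorts have
thousands of lactations and dozens of herds, where denominator-degree
of-freedom refinements are immaterial; `df_method = "satterthwaite"` is
available for small samples. Significance is declared at p < 0.05 and a
tendency at 0.05 ≤ p < 0.10 — the boundary value 0.05 counts as a
tendency, so the two classes partition cleanly.

The compact letter display assigns letters by insert-absorb: start from
one all-inclusive group, split any group containing a significantly
different pair, absorb subsets, and letter the surviving groups (the
maximal mutually-non-significant sets) in order of their first member.
The test suite checks the resulting letters against brute-force subset
enumeration on up to five levels.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, and its
defaults are the study conditions under which the package's checks run:

* **GL**: a truncated normal bulk (mean 279 d, SD 5.5 d, truncated to
  150–297) mixed with a uniform short-GL component on 158–243 d at weight
  0.01 — so roughly 1% of animals have a distinctly short gestation, and
  GLs below 210 d occur at about 0.6%. The short component's support
  matches the range where short gestations and late abortions occur.
* **Curve parameters**: category-level means for scale 31.5→35.0 kg/d,
  ramp 29.8→29.3 d and decay 0.00125→0.00138 /d from C-I to C-V (offset
  mean 2.5 d), i.e. shorter gestation ⇒ lower scale, slightly slower ramp
  and higher persistency. Between-animal SDs (a: 3.0, b: 2.5, c: 1.5, d:
  2×10⁻⁴) imply a within-herd M305 SD of roughly 800 kg, and the herd
  effect on scale (SD 1.7 kg/d) roughly 400 kg — realistic magnitudes for
  primiparous cohorts.
* **Observation**: daily yield = true curve + Gaussian noise (SD 2 kg),
  clipped to the recordable range [1, 70] kg at the recording step only;
  truths are stored unclipped. Calving dates are uniform over a
  configurable month/year window (2013–2018 default) and AFC ≈ N(730,
  60²) d.

Ground truth (per-animal parameters and traits, herd effects, true
category trait means) is returned alongside the tables, so recovery is
checkable end-to-end: fitting noiseless simulated lactations returns the
true parameters to ~10⁻⁴ relative error or better, and with 2 kg noise
the median error is about 1.4% on scale and 0.3% on M305 (recomputed by
`scripts/acceptance.R` at every run).

What the generator does **not** emulate: milking-system artefacts,
multi-day recording gaps beyond independent missingness, health events,
seasonal calving waves, multi-parity careers, or any dependence of GL on
herd. Passing recovery tests therefore demonstrates correctness of the
estimation machinery under the stated noise model, not robustness to
every failure mode of field data.

`simulate_trait_table()` is a shortcut for mixed-model studies: it draws
per-animal trait values directly (category mean + herd effect + residual)
so that calibration experiments with hundreds of model fits — contrast
coverage of a known 600 kg deficit, type-I error of the pairwise
contrasts under the null — run in seconds. The problem sizes used by the
checks (50 herds × 40 animals and 100 replicates for coverage; 10 herds ×
20 animals and 400 replicates for type-I error; 1,000 parameter draws for
the closed-form properties) were chosen to make the Monte-Carlo error of
each check small relative to what it asserts.

One empirical caveat the checks surface deliberately: with the default
category parameter means, the true M305 gaps between C-III, C-IV and C-V
are only ≈85–110 kg. At realistic cohort sizes the pairwise tests
resolve such gaps with intermediate power, so the letter display settles
on the clean two-block pattern (C-I, C-II vs the rest) only in a minority
of replicates; the acceptance suite records the observed rate rather than
forcing it.

## Degenerate inputs and numerical edges

* Empty milking files parse to empty collections, and an empty cohort
  categorizes to zero counts — neither is an error.
* Filtering never fails and is idempotent.
* `d = 0` (no senescence): the cumulative integral switches to its
  analytic limit; time to peak is `NA` with `peak_defined = FALSE`.
* `b·d ≥ 1`: the stationary point exists but precedes the offset; it is
  returned with `peak_defined = FALSE` so downstream models can exclude
  the trait rather than ingest a meaningless value.
* Ties in GL: assignment at a cut-point goes to the lower category,
  making boundary behaviour exactly reproducible.
* The pipeline asserts row conservation (input = retained + dropped) at
  every stage and records the tallies in `report.json`; two runs with the
  same configuration and seed produce byte-identical outputs.

## Limitations

Only first lactations are handled; a second calving record per animal is
an error by design. Only the MilkBot family is implemented — no Wood,
Wilmink or spline alternatives — because the derived-trait algebra (exact
integral, closed-form peak) is specific to this parameterization.
Abortion event codes are not interpreted; short gestations are
identified purely by the insemination-to-calving interval. The mixed
model treats lactations as exchangeable within herd; repeated measures
within animal never arise because each animal contributes exactly one
lactation.
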