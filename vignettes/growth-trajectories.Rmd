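---
title: "Modelling early growth trajectories in matched case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early growth trajectories in matched case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headgrow)
```

## The scientific question

Head circumference (HC) in the first years of life is a cheap, routinely
recorded proxy for brain volume, and the early-overgrowth hypothesis of
autism predicts that children later diagnosed with autism show larger HC
or faster HC growth during the first two years. Testing this with
well-baby clinic records requires handling irregular visit timing,
variable visit counts, matched case-control structure, and a growth model
whose parameters separate *size at birth*, *asymptotic size*, and *growth
rate*. `headgrow` implements that analysis chain end to end, driven by a
synthetic cohort generator so every stage is testable without access to
clinical records (which are never deposited publicly for such studies).

## The growth model

Each child's trajectory for each measure is modelled as a negative
exponential approach to an asymptote:

$$y(x) = \alpha + (\beta - \alpha)\, e^{-\gamma x},$$

with age $x$ in weeks; $\alpha$ is the asymptote (cm, or kg for weight),
$\beta$ the size at birth ($y(0) = \beta$), and $\gamma > 0$ the weekly
rate of approach. The curve is strictly increasing whenever
$\alpha > \beta$ and $\gamma > 0$, which matches anthropometric growth in
this age range. The model is deliberately not hierarchical: it is fitted
independently per child, and group inference is done on the fitted
parameters with Welch t-tests. A mixed-effects formulation would borrow
strength across children but would not yield the per-child $R^2$ that is
the fit-quality criterion here.

Fitting is ordinary least squares on the child's **raw measurement
points**, never on interpolated values — interpolation would fabricate
observations and inflate the apparent sample size. At least 4 points are
required for a 3-parameter fit.

### Numerical choices

* Optimizer: Levenberg–Marquardt (`minpack.lm::nlsLM`), stopping when the
  relative change in the residual sum of squares falls below $10^{-10}$ or
  after 500 iterations.
* Initialization: $\beta_0$ = first measured value; $\alpha_0$ = last
  measured value plus 2% of the observed range; $\gamma_0$ from the slope
  of $\log(\alpha_0 - y)$ against age (the model is log-linear in that
  transform), clamped to $[10^{-4}, 1]$, defaulting to $0.03$/week when
  the regression is degenerate.
* Bounds: $\gamma \in (10^{-6}, 1]$, $\alpha \in (\beta_0, 3\alpha_0]$.
  These exclude decreasing or runaway solutions without constraining any
  plausible trajectory in this age range.
* A fit is reported as converged only if the optimizer converged *and*
  the estimates satisfy $\alpha > \beta$, $\gamma > 0$. Nonconverged fits
  are excluded listwise from parameter comparisons only; the child's
  binned data still enter the group comparisons.
* $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ with TSS about the child's own
  measurement mean, so it is invariant under affine rescaling of the
  value axis. Tests verify this and cross-check the optimizer against an
  independent `nls` port-algorithm fit.

## Age handling, interpolation, and binning

Ages are continuous weeks with birth at 0. Month-labelled quantities (the
visit schedule, the 3-month bins) are converted at the mean calendar month
of $52.1775/12 \approx 4.348$ weeks.

Each child's series is linearly interpolated onto integer weeks from the
ceiling of the first measured age to the floor of the last — no
extrapolation in either direction; downstream stages treat out-of-span
weeks as missing. Fractional measurement ages are used exactly; only the
output grid is integer.

Binning produces one value per child per 3-month age point from birth to
24 months:

* **Bin 0** is the raw birth measurement (recorded at age 0 by a midwife).
  Height has no bin 0 because height is not measured at birth in Israel.
* **Bin $m$** ($m \ge 3$ months) averages the weekly values in a 13-week
  window centred on the integer week nearest $m \times 4.348$, intersected
  with the child's measured span. Bins whose window misses the span are
  absent, and children missing a bin are excluded from that bin only
  (pairwise deletion maximizes data use).

A window *mean* rather than a point value at the centre week was chosen
because it uses all interpolated information in the interval while keeping
the point labels; for a locally linear trajectory the symmetric-window
mean equals the centre value, so the choice is immaterial exactly where
the trajectory is smooth (tests verify this identity on linear curves).

Group tests per bin are two-tailed two-sample t-tests with unequal
variances (Welch), with the Welch–Satterthwaite degrees of freedom.
Degenerate inputs follow fixed conventions: two zero-variance samples
with equal means give $t = 0$, $p = 1$. p-values are deliberately **not**
corrected for multiple comparisons — the design favours sensitivity over
specificity for this negative-result-style analysis — and an optional
flag appends Benjamini–Hochberg columns without altering the primary
report. Module-stratified comparisons (toddler / module 1 / module 2)
always use the full control group as the reference.

## The synthetic cohort generator

The generator emulates the study conditions, not any particular dataset:

* 66 matched pairs, 6 female per group; pairs share sex and a birth-date
  offset drawn uniformly in ±30 days.
* Visit schedule: birth plus months 1, 2, 4, 6, 9, 12, 15, 18, 24. The
  birth visit is always measured (HC and weight only); each later visit is
  attended independently with probability 0.82, chosen so the expected
  visit count is $1 + 9 \times 0.82 \approx 8.4$, matching the reported
  means of 8.3–8.42 visits per child; attendance patterns below 4 visits
  are resampled. Non-birth visit ages get Gaussian jitter (SD 1 week),
  truncated to keep ages positive and strictly ordered.
* Mean growth parameters per measure are the frozen least-squares fit of
  the model to the published control-group trajectory means
  (`default_growth_params()`); e.g. HC: $\alpha \approx 49.1$ cm,
  $\beta \approx 35.2$ cm, $\gamma \approx 0.031$/week.
* Between-child parameter SDs (HC: 1.4 cm on $\alpha$, 1.2 cm on $\beta$,
  0.004/week on $\gamma$) were chosen once so the ±1 SD band at 24 months
  spans roughly ±1.5 cm, consistent with the visual spread of published
  individual curves; no individual-level SDs are printed in the source
  material, so these are free, documented defaults. Weight
  (0.9 kg, 0.35 kg, 0.003/week) and height (3.0 cm, 2.0 cm, 0.002/week)
  use the same logic scaled to each measure's range.
* Measurement noise: 0.3 cm (HC), 0.15 kg (weight), 0.5 cm (height) —
  the scale of inter-observer error for trained nurses.
* Additive group effects (default zero: a null cohort) and male sex
  effects (HC +0.9 cm asymptote / +0.5 cm birth; analogous for weight and
  height) shift the parameter means. Because pairs are same-sex, the sex
  effect never biases case-control contrasts.
* ADOS metadata for cases: module assigned with probabilities 14/65,
  36/65, 15/65 (the study's strata); total score uniform on 7–26,
  calibrated severity score uniform on 4–10, independent by default, or
  rank-correlated with the child's latent HC asymptote through a Gaussian
  copula when `severity_hc_corr` is nonzero.

### What the generator does *not* emulate

Real records include occasional extra (sick-visit) measurements — the
reported range of 4–12 visits exceeds the 10 scheduled ones — seasonal
and secular trends, prematurity exclusions, sibling structure, and
correlated measurement errors within a visit. The generator caps visits at
the 10 scheduled ones and draws noise independently. Consequently, green
tests demonstrate that the *pipeline* is calibrated and faithful (type-I
error at nominal level on null cohorts, directional sensitivity to
injected effects, parameter recovery), not that any particular published
group difference is reproduced: the published group means, t and p values
depend on undeposited clinical records and are emulated structurally,
not numerically.

## Power analysis

The two-sample power uses the noncentral t distribution exactly:
$df = 2n - 2$, noncentrality $d\sqrt{n/2}$. For the study design
($n = 66$ per group, $d = 0.5$, $\alpha = 0.05$) the one-tailed power is
0.8873 — the directional one-tailed reading ("detecting *larger* HC in
the case group") is adopted because the two-tailed value (0.814) is
clearly incompatible with the published 0.88, while 0.8873 matches it at
two-decimal truncation. Both options are exposed via the `tails`
argument. A 100,000-replicate Monte-Carlo simulation cross-checks the
analytic value in the tests.

## Problem sizes used in the test suite

The suite exercises the pipeline at the study's own scale (66 pairs) for
structure, fit-quality and calibration checks; 100–300 pairs where a
single draw must estimate a rate or recover a parameter; and 200 null
cohorts for the type-I calibration of binned Welch tests and severity
correlations. These sizes give Monte-Carlo standard errors comfortably
inside the asserted bands while keeping a full run to a couple of
minutes.

## Known limitations

* The negative exponential model has no inflection; it cannot represent
  early growth spurts, and $\alpha$ is an *in-window* asymptote, not adult
  size.
* Linear interpolation underestimates curvature between sparse late
  visits; since both groups are processed identically this biases group
  contrasts toward zero, not toward false positives.
* Pairwise deletion per bin assumes coverage is unrelated to group after
  matching; informative missingness is not modelled.
* Height's birth intercept $\beta$ is an extrapolation below the first
  measured age (3 months) and should be interpreted cautiously.
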