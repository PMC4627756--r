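---
title: "Robustness triangulation for correlation meta-analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness triangulation for correlation meta-analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarange)
```

# The problem

A meta-analytic mean correlation — in personnel selection, the *validity*
of a predictor such as a conscientiousness score for job performance — is
only as trustworthy as it is stable under reasonable perturbations of the
evidence base. Two perturbations dominate practice: removing individual
studies (outliers, influential samples) and correcting for publication
bias (the selective absence of small, nonsignificant effects).
`metarange` implements a battery of such sensitivity analyses and then
*triangulates*: instead of electing one adjusted estimate as true, it
reports the set of adjusted estimates, condenses the set into two range
statistics, and classifies the practical difference they imply.

# Models and procedures

## Pooling

Studies arrive as Pearson correlations `r` with sample sizes `n`.
Pooling operates by default on the Fisher z scale (`z = arctanh(r)`,
sampling variance `1/(n - 3)`), where the sampling distribution is
close to normal with a variance free of the parameter. The
random-effects model assumes `z_i ~ N(mu + u_i, v_i)` with
`u_i ~ N(0, tau^2)`; `tau^2` is estimated by the DerSimonian–Laird
moment estimator, the long-standing default of mainstream meta-analysis
software in this literature (REML is available via `tau2_method`).
Heterogeneity is summarised by Cochran's Q, I² = max(0, (Q − df)/Q), and
τ. The 90% prediction interval uses `mu ± t(k−2) sqrt(tau² + se²)`, the
usual t-based convention for the plausible range of a *new* study's true
effect. Results are back-transformed to the correlation metric for
reporting; the back-transform `tanh` is strictly monotone, so intervals
transform coordinate-wise.

Raw-correlation pooling (used for influence diagnostics, where the
reporting metric matters) uses the large-sample variance
`(1 − r²)²/(n − 1)`. An `se` column in the input table overrides either
analytic variance, study by study.

## Influence and outliers

`one_sample_removed()` recomputes the pooled mean k times with one study
deleted and reports the minimum, median and maximum — the coarsest but
most interpretable robustness check. `influence_diagnostics()` computes
the standard leave-one-out case diagnostics for the intercept-only
random-effects model on raw correlations: externally standardised
deleted residuals, DFFITS, Cook's distance, covariance ratios, τ²- and
Q-with-deletion, leverages (hat values, which sum to one), percentage
weights and leave-one-out means. Every quantity comes from an actual
deletion refit, so the records agree exactly with re-pooling the reduced
data; the implementation is verified in the test suite against the
reference implementation in `metafor` to eight decimals.

`flag_outliers()` calls a study an outlier when its deleted residual is
extreme *and* at least one influence criterion fires
(DFFITS > 3·sqrt(1/(k−1)), Cook's distance above the median of χ²(1), or
leverage above 3/k). For the residual criterion we default to the
Bonferroni-adjusted two-sided value `qnorm(1 − .05/(2k))` rather than
1.96: k residuals are screened per dataset, and at k = 30 an unadjusted
1.96 flags at least one study in well over 10% of perfectly homogeneous
datasets — a family-wise error rate no screening rule should have. The
unadjusted convention remains one argument away (`rstudent_crit = 1.96`).

## The publication-bias battery

Seven procedures, each probing a different observable consequence of
suppression. Scale conventions follow the field: trim-and-fill,
selection models and p-uniform on Fisher z; PET-PEESE and the funnel
coordinates on raw correlations.

**Contour-enhanced funnel data** (`funnel_contours()`): study effects
against precision with two-sided significance contours at p = .05 and
.10. Asymmetry that hugs the significance boundary — rather than tracking
precision alone — is the visual signature of suppression.

**Trim-and-fill** (`trim_and_fill()`): the rank-based L0 estimator of
the number of suppressed studies. The implementation iterates
fixed-effect centring, average-rank computation of
`L0 = (4·Tn − k(k+1))/(2k−1)`, and re-trimming until the count
stabilises, then imputes the k0 trimmed effects' mirror images and
re-pools everything under random effects (fixed-effect trimming with a
random-effects final estimate is the conventional pairing). Ties in the
absolute deviations are rank-averaged, so exactly symmetric inputs yield
k0 = 0 identically. With `side = "auto"` the deficient side is taken
opposite the skew of the deviations from the fixed-effect centre. Two
behaviours of the estimator matter for interpreting output: it is noisy
under heterogeneity, and *estimating* the side on null data then counting
imputations on that side is a selection effect that imputes a handful of
studies about half the time even when nothing is missing — which is why
the package's own calibration tests fix the side when checking null
behaviour, and why a small k0 on one dataset is weak evidence by itself.

**A-priori selection models** (`selection_model()`): weighted maximum
likelihood on the z scale in (μ, τ²), with the probability that a study
is observed a *fixed* step function of its one-tailed p-value. The
moderate and severe one-tailed weight vectors of the Vevea–Woods
framework are built in (`vevea_woods_weights()`, 14 intervals with
cut-points at .005, .01, .05, .10, .25, .35, .50, .65, .75, .90, .95,
.99, .995, 1); both cut-points and weights are overridable. Each study
contributes `log w(p_i) + log φ((z_i−μ)/s_i) − log Σ_j w_j P_ij` with
`s_i² = v_i + τ²` and `P_ij` the model probability of interval j. With
all weights 1 the model reduces to ordinary random-effects ML (verified
in the tests, as is agreement with `metafor::selmodel` under fixed
weights). Because the weights are held fixed, the model *assumes* its
severity scenario: applied to data with no suppression at all it is
conservative, pulling the mean slightly below the naive estimate. That
is a property of the method, not a defect of the fit, and it is why a
battery is triangulated rather than any single method trusted. A fit is
reported not-applicable when the optimiser fails or the variance
component leaves the plausible range (τ² ≥ 1 on the z scale), mirroring
the "n/a" convention of published robustness tables.

**PET-PEESE** (`pet_peese()`): weighted least-squares regressions of raw
correlations on their standard errors (PET) or sampling variances
(PEESE), weights 1/SE²; the intercept estimates the effect of an
infinitely precise study. PEESE's intercept is reported as the adjusted
estimate when the one-tailed PET intercept test is significant at .05,
PET's otherwise — the conditional rule used in published tables.
Standard errors are evaluated at the *pooled* correlation,
`(1 − r̄²)/sqrt(n−1)`, not at each study's own r: the analytic SE of a
correlation contains the correlation itself, and that mechanical
coupling alone tilts an effect-on-SE regression (simulations during
development showed a spurious mean PET slope of about −0.37 on unbiased
corpora with study-specific SEs, collapsing to about −0.05 with pooled
ones). An `se` column overrides this choice.

**p-uniform** (`p_uniform()`): uses only studies significant at the
one-tailed .05 threshold and estimates the mean effect as the value under
which their conditional p-values are uniform, via the moment condition
`Σ −ln q_i(μ) = k_sig` (each −ln q is unit-exponential at the truth, so
the sum is Gamma(k_sig, 1); the confidence bounds solve the
corresponding 2.5%/97.5% quantile equations). The moment sum is strictly
decreasing in μ, so the roots are found by safeguarded bisection with
bracket expansion. The estimator assumes a common true effect;
under between-study heterogeneity it overestimates — reproduced in the
test suite at τ = 0.09 — which is why p-uniform is excluded from the
default triangulation set and joins only on request.

**Test of excess significance** (`excess_significance()`): compares the
observed count O of two-sided-significant studies with the expected
count E = Σ power_i, evaluating each study's power at an assumed
population correlation (by default the random-effects mean, the
self-consistent choice). The statistic
`A = (O−E)²/E + (O−E)²/(k−E)` is referred to χ²(1); probabilities below
.10 conventionally mark a non-credible set. Both the significance count
and the power use two-sided α = .05 — the source procedure states only
"the .05 level", so the two-sided reading is flagged here as an
assumption. O = E yields p = 1; the degenerate boundaries E = 0 and
E = k report the boundary probability rather than a statistic.

**Cumulative meta-analysis by precision**
(`cumulative_by_precision()`): studies enter largest-n first (ties by
id) and the random-effects mean is recorded at each step. Drift toward
larger means as small studies enter is the small-study signature; the
final step equals the full-data pooled result by construction.

## Triangulation

`collect_estimates()` assembles the adjusted-estimate set: the
random-effects and fixed-effects means, the one-sample-removed
minimum/median/maximum, the trim-and-fill mean, the moderate and severe
selection-model means, and the PET-PEESE selected estimate — nine
members, with not-applicable members carried as missing and excluded
from the scans. The test of excess significance never joins (it is a
probability, not an effect size); p-uniform joins only when explicitly
requested, given its behaviour under heterogeneity.

`triangulate()` reduces the set to the **baseline range estimate**
(BRE, the absolute difference between the random-effects mean and the
member farthest from it) and the **maximum range estimate** (MRE, the
spread between the lowest and highest members), expresses both as
percentages of the random-effects mean (the base, 100%), and classifies
each: below 20% negligible, 20% up to 40% moderate, 40% and above
large. The written convention in the source literature says "larger
than 40%" for large while its own tables label exactly 40% as large;
the tables win here, so the boundary is ≥ 40. Estimates are rounded to
the reporting precision (two decimals) *before* ranges and percentages
are formed — this is what makes every published range row reproducible
from its printed triple — and the unrounded percentages are retained
alongside. `range_conclusion()` renders the pair of classes as the
familiar "Negligible to moderate difference" strings.

`utility_difference()` converts a validity difference into dollars with
the classic linear utility model
`ΔU = n_hired · years · SDy · Δvalidity · selectee_z`, where SDy
defaults to 40% of salary and the selectee standard score to 1.0364
(the 85th-percentile z, to four decimals). Both conventions behind the
headline "millions of dollars" arithmetic are parameters, since the
literature sometimes uses z = 1.

# The synthetic-data generator

No study-level dataset ships with the package, so every stage is
exercised on generated corpora with known truth
(`simulate_meta_data()`). The generator draws a true effect
`θ ~ N(mu_z + offset, τ²)` on the z scale, a sample size from a floored
lognormal, an observed `z ~ N(θ, 1/(n−3))`, and retains the study with
the probability its one-tailed p-value earns under a step-function
selection mechanism — rejection sampling, so the retained count is exact
and the process mirrors authors shelving nonsignificant results. The
moderate and severe Vevea–Woods weight functions double as the
generator's suppression presets, keeping the data-generating and
analysis-side severity scenarios aligned.

Defaults emulate a large validity corpus: mean observed correlation
near .16, between-study SD 0.081–0.09 on the z scale, lognormal sample
sizes with median about 130 (the source corpus reports only k = 113 and
a total N of 19,625, i.e. a mean n near 174; a heavy-right-tailed
family with `sdlog = 0.76` matches that mean and gives the cumulative
analysis realistic large-study anchors). `simulate_validity_corpus()`
packages the full scenario: k = 113, τ = 0.09, a 60/40 split between a
`journal` subgroup under severe suppression and a `non_journal` subgroup
under moderate suppression, and the true mean fixed at `mu_z = 0.122` —
calibrated once, by simulation over a grid, so the *suppressed* corpus
pools to about .16; a frame-of-reference moderator is attached
independently (80/20) so moderator crossings can be exercised.

What the generator does *not* emulate: dependent effect sizes (multiple
correlations per sample), time-lag or outcome-switching bias,
psychometric artefacts (measurement error, range restriction), and any
systematic link between sample size and true effect other than the one
suppression itself induces. Passing tests therefore show that the
battery behaves correctly under one-tailed step-function suppression of
independent correlations — not that it corrects every bias a real
literature may carry.

# Numerical choices and degenerate inputs

* Optimisation of the selection-model likelihood runs in (μ, log τ²)
  with `nlminb`, started from the DerSimonian–Laird fit; τ² is bounded
  away from overflow, and interval probabilities are computed from
  normal CDF differences with a hard floor against zero denominators.
* p-uniform roots use `uniroot` at tolerance 1e-9 after stepwise bracket
  expansion; conditional probabilities are computed on the log scale
  (`pnorm(..., log.p = TRUE)`) for stability far in the tails.
* I² is truncated at 0, τ² at 0 (the DL moment estimator), and k = 1
  datasets return their single effect with heterogeneity fields missing.
* Pooling with k < 3 refuses to produce a prediction interval; the
  battery records every such skip (`skipped_reasons`, pipeline log)
  rather than silently omitting a method.
* Bias procedures run only for distributions with at least `min_k = 10`
  studies (configurable), the conventional floor below which
  second-order sampling error makes bias statistics uninterpretable;
  smaller distributions keep their pooled and one-sample-removed columns,
  matching the blank-cell convention of published tables.
* Reports round correlations to two decimals and percentages to
  integers; unrounded values stay in the objects.

# Problem sizes used in the validation suite

The stochastic test suites run at: 500 unsuppressed corpora (k = 100)
for the null-calibration checks; 200 severely suppressed corpora
(k = 200, true r = .10, τ = 0.09) for parameter recovery; 1,000
homogeneous corpora (k = 30) for the false-flag rate; 10,000 simulated
homogeneous datasets for the τ² truncation property; and five preset
corpora for the end-to-end qualitative signature. These sizes put the
Monte-Carlo error of each checked mean well below the effect being
asserted.

# Known limitations

* The battery addresses *observed* correlations; psychometric
  corrections (reliability, range restriction) are out of scope, and no
  current bias procedure is designed for artefact-corrected effects.
* Fixed-weight selection models are scenario analyses: their estimates
  inherit the assumed weights, are conservative when no suppression
  exists, and should be read as bounds, not point identifications.
* Trim-and-fill misattributes heterogeneity-driven asymmetry to
  suppression; its credibility is highest within moderator-homogeneous
  sub-distributions, which is exactly how the pipeline deploys it.
* p-uniform is unreliable at the heterogeneity levels typical of this
  literature (I² near 50%) and is excluded from default conclusions.
* The SAMD statistic and multivariate outlier detection are not
  implemented; meta-regression beyond PET-PEESE is out of scope.
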