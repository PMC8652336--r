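---
title: "Moderated parallel mediation: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated parallel mediation: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmedpath)
```

## The model

`modmedpath` fits a parallel multiple-mediator path model in which the
independent variable X also moderates the second stage of each of its own
mediated pathways. With one mediator the structural equations are

$$M = a_0 + a_1 X + e_m$$
$$Y = b_0 + b_1 M + c_1' X + c_2' XM + e_y$$

and with k parallel mediators the outcome equation carries one mediator
slope $b_{1i}$ and one interaction coefficient $c_{2i}'$ per mediator, with
the mediator residuals allowed to covary. Substituting the first stage into
the second shows that the coefficient of X on Y is itself affine in X:

$$Y = (b_0 + a_0 b_1) +
  \big[(c_1' + a_0 c_2') + a_1 (b_1 + c_2' X)\big] X + \text{residual terms},$$

so the moderation is *quadratic* in X, not linear. Three derived quantities
drive the interpretation:

* **conditional indirect effect** through mediator i at moderator value x:
  $a_{1i}(b_{1i} + c_{2i}' x)$ — affine in x with slope $a_{1i} c_{2i}'$;
* **direct effect** $c_1' + \sum_i a_{0i} c_{2i}'$, which reduces to $c_1'$
  when the mediators are grand-mean centered (all $a_{0i} = 0$);
* **total effect** at x = 0: direct plus the sum of the conditional
  indirect effects, an identity that holds exactly for the fitted
  coefficients.

The motivating application is a survey of 2,133 college students in which
psychological capital (PsyCap, a 26-item questionnaire, scores 26–130)
predicts internet addiction (Young's 20-item IAT, scores 20–100) through
three adaptation mediators drawn from SACQ subscales: emotional (8 items,
8–40), learning (5 items, 5–25) and interpersonal (4 items, 4–20)
adaptation. All items are 5-point Likert responses; negatively worded items
are reverse-coded so higher scores mean better adaptation.

## Estimation: why per-equation least squares

The system is recursive and saturated: the mediator equations share the
single regressor X, and the outcome equation is an ordinary linear
regression in its seven observed predictors (X, three mediators, three
products). Under these conditions joint maximum-likelihood estimation with
free mediator residual covariances yields the same point estimates as
per-equation least squares — seemingly-unrelated equations with identical
regressors collapse to OLS — so the package solves each equation from the
correlation matrix instead of running an SEM optimizer:

* standardized slopes: $\beta = R_{pp}^{-1} r_{py}$;
* unstandardized: $\beta_j \cdot \mathrm{sd}(Y)/\mathrm{sd}(x_j)$;
* intercepts from the means.

This has a practical payoff: the model is fittable from a published
means/SD/correlation table alone. The packaged summary table of the
motivating survey is available as `survey_moments()`, and
`fit_from_raw(data)` is literally
`fit_from_moments(compute_moments(data))`, an equivalence the test suite
asserts to 1e-10.

```{r fit}
fit <- fit_from_moments(survey_moments())
fit
effect_decomposition(fit)
```

Conventions worth knowing:

* **Centering.** X and the mediators are grand-mean centered before the
  product terms are formed (`prepare_model_frame()`); product columns are
  exact elementwise products of the centered factors, so the mean of each
  product column equals the covariance of its factors up to the n vs n−1
  factor. Centering makes the lower-order coefficients interpretable at
  the sample mean and removes needless collinearity.
* **Denominators.** SDs and correlations use n−1 throughout. Slopes are
  invariant to this choice (it cancels in the correlation ratios);
  only reported SDs and product-column means are affected.
* **Standardization of product terms.** Products are treated as observed
  variables and standardized by their own observed SD, matching how
  summary tables report them.
* **Standard errors.** Classical homoskedastic least-squares SEs, computed
  from the moment-implied residual variance. Published SEs from an ML SEM
  fit can differ slightly; the bias-corrected bootstrap is the
  authoritative uncertainty source for the derived effects, which are
  products of coefficients and not normal in finite samples.
* **Moderator evaluation points.** Conditional effects default to
  $\{-\mathrm{SD}(X),\, 0,\, +\mathrm{SD}(X)\}$ with the sample SD of X
  (13.111 in the packaged survey table); any grid can be supplied.
  Percentage shares of the total indirect effect are computed from
  unrounded estimates.

## The bias-corrected bootstrap

`bootstrap_model()` resamples respondents (rows, i.i.d. with replacement,
size n), refits the entire pipeline on each resample — recentering and
reforming the products inside the resample — and recomputes every
estimand. Intervals are bias-corrected (BC) percentile intervals, without
an acceleration term:

* $z_0 = \Phi^{-1}\big(P(\hat\theta^* < \hat\theta)\big)$, ties counted
  with half weight;
* endpoints at the $\Phi(2 z_0 + z_{\alpha/2})$ and
  $\Phi(2 z_0 + z_{1-\alpha/2})$ empirical quantiles of the replicates,
  with linear interpolation between order statistics.

Numerical edge cases are handled explicitly rather than silently: if no
(or every) replicate falls below the point estimate, $z_0$ is clamped via
the continuity correction $1/(2B)$ with a warning; an all-identical
replicate vector returns the degenerate interval $[v, v]$ with a warning.
When the replicate distribution is symmetric about the point estimate,
$z_0 = 0$ and BC coincides with the plain percentile interval.

Two further choices:

* **Frozen SD.** The $\pm$SD moderator values are fixed at the full-sample
  SD of X across all replicates, so every replicate estimates the same
  functional.
* **Failure policy.** A resample whose predictor cross-product matrix is
  singular is dropped and counted; more than 5% of drops aborts the run.
  Defaults are B = 1,000 and a 99% level, the settings of the motivating
  analysis; the resampling unit is the respondent (the survey's cluster
  structure is not resampled, matching the original analysis).

`contrast_mediators()` forms replicate-wise pairwise differences of the
per-mediator conditional indirect effects at a common x, with BC intervals
and bootstrap SEs. `sobel_se()` provides the delta-method baseline
$\sqrt{a^2 SE_b^2 + b^2 SE_a^2}$ for comparison only.

## The synthetic-data generator

The raw survey responses are not distributed with the package, so
`synthetic_spec()` / `simulate_raw()` generate respondent-level data with
the statistical structure the analysis assumes:

* centered $X \sim N(0, \mathrm{sd}_X^2)$;
* mediators $M_i = a_{1i} X_c + e_{mi}$ with jointly Gaussian residuals
  whose covariance is solved from the target inter-mediator correlations
  (0.262, 0.371, 0.381 by default) minus the X-induced common component;
* the outcome equation with a Gaussian residual whose variance is solved
  from the target SD of Y, using the closed-form product moments of a
  Gaussian vector ($\mathrm{Var}(X M_i) = \mathrm{Var}(X)\mathrm{Var}(M_i)
  + \mathrm{Cov}(X, M_i)^2$, and the Isserlis identity for
  $\mathrm{Cov}(X M_i, X M_j)$).

Defaults are the published path coefficients, means and SDs at n = 2,133,
so the default simulation target is the study population itself.
`implied_moments()` returns the exact population moments of the
generating model; sample moments of `simulate_raw()` output converge to
them as n grows, a property the tests check at n = 200,000.
`simulate_items()` goes one level deeper and emits item-level Likert
responses: for each respondent and instrument it samples uniformly among
all integer compositions of the (rounded, range-clamped) score across the
instrument's items, using a dynamic-programming count table, and emits
reverse-coded items in reversed polarity — so the scoring pipeline
round-trips the scores exactly.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: Likert sums are bounded integers with
possibly skewed, heaped distributions, whereas the generator draws
continuous Gaussians (rounded only in item mode); the observed product-term
SDs of a real survey reflect that non-normality, so they are matched only
approximately; the class-cluster sampling design and any
missing-not-at-random structure are absent; and the severity prevalence of
the outcome depends on the shape of the real IAT distribution, which a
Gaussian cannot reproduce. Fitting needs none of these distributional
assumptions — the published-table fit uses the printed moments as-is.

## Scale scoring choices

* Severity bands for the IAT partition $[20, 100]$ half-open on the left:
  none $[20,40)$, mild $[40,60)$, moderate $[60,80)$, severe $[80,100]$.
  Published cut-offs overlap at 40/60/80; the half-open convention is
  standard practice and makes the bands a true partition.
* The learning subscale has 5 items and the interpersonal subscale 4: the
  published score ranges (5–25 and 4–20) pin the item counts, and the
  scoring code treats ranges as load-bearing.
* Missing responses are handled by listwise deletion before scoring; no
  imputation. No survey weights are applied (resampling respondents and
  weighting do not combine cleanly).
* Cronbach's alpha uses the covariance formula
  $\frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_{\text{total}}^2\bigr)$ with
  n−1 denominators; a zero total-score variance is reported as `NA` with a
  warning, never silently as 0.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: scale
statistics against hand-computed covariance arithmetic on fixed toy
tables; moment computation against brute-force summation; the fitter
against `lm()` and explicitly assembled normal equations on random small
datasets; the BC interval against a hand-walked evaluation of the formula
on a fixed replicate set; and the full pipeline against parameter recovery
on simulated data (n = 100,000 for relative accuracy of the sizeable
coefficients; n = 2,133 for consistency within sampling error). Interval
calibration is checked by Monte Carlo: 500 datasets of n = 500 with B =
500 bootstrap replicates each, requiring 99% BC intervals to cover the
generating indirect effects in at least 97% of runs, and to exclude zero
in at most 3% of runs under a null with all first-stage slopes zero.
These sizes keep the full suite under a few minutes on one core while
leaving Monte-Carlo error well below the margins being asserted.

## Known limitations

* Coefficients that are genuinely near zero (the learning-adaptation
  interaction is 0.002 in the motivating analysis) cannot be recovered to
  tight *relative* accuracy from any realistic sample — the sampling SE at
  n = 100,000 is two orders of magnitude larger than 2% of such a value —
  so recovery of near-null coefficients is meaningfully assessed only on
  the SE scale, not the relative-error scale.
* The package fits observed-variable path models only: no latent
  measurement models, no FIML for missingness, no global SEM fit indices.
* The BC interval omits the acceleration term (it is BC, not BCa), and
  the index of moderated mediation $a_{1i} c_{2i}'$ is reported through
  the affine slope of the conditional effects rather than separately
  inferenced.
* Johnson–Neyman regions and survey-design corrections are out of scope.
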