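---
title: "Quantile trajectories of the Frailty Index in mortal cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile trajectories of the Frailty Index in mortal cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtyq)
```

## The problem

Panel studies of ageing measure the Frailty Index (FI) — the proportion of
health deficits an individual has accumulated, a number in [0, 1] —
repeatedly, roughly every two years. Describing how frailty *progresses*
with age from such data faces three entangled obstacles:

* **Heterogeneity.** Mean-trajectory models describe the average person.
  Clinicians and epidemiologists care at least as much about the frail tail:
  the 90th centile of FI at a given age behaves very differently from the
  median, so the natural object is the family of conditional quantile
  trajectories (reference curves, as in paediatric growth charts).
* **Death.** Frail individuals die sooner. A model that treats death like
  any other missing value implicitly describes an "immortal cohort" and
  understates frailty progression, most severely in the upper quantiles.
* **Intermittent non-response.** Between entry and death, individuals skip
  interviews, and frailer individuals skip more often. Complete-case
  analysis therefore over-samples the healthy.

`frailtyq` implements a mortal-cohort quantile analysis: conditional
quantiles of FI given age and covariates are estimated *among those alive*,
with stabilized inverse-probability-of-observation weights correcting the
interview process among the living. Death is handled by restricting the
estimand, not by imputing the dead.

## The trajectory model

For individual $i$ at occasion $j$, with $A_{ij}$ age (centered at 65),
$S_i$ sex (1 = female), $E_i$ education in years (centered at the sample
mean), and $BA_i$ age at study entry (centered at 65), the conditional
$\tau$-quantile of the FI is modeled linearly in age:

$$Q_\tau(FI_{ij} \mid x_{ij}) = \beta_0^\tau + \beta_s^\tau S_i +
\beta_e^\tau E_i + \beta_{ba}^\tau BA_i + \beta_a^\tau A_{ij} +
\beta_{as}^\tau A_{ij} S_i + \beta_{ae}^\tau A_{ij} E_i +
\beta_{aba}^\tau A_{ij} BA_i$$

The `cohort` variant adds a birth-cohort indicator $Bo_i$ (1 = born 1946 or
later) and its interaction with age. Estimation minimizes the weighted
check loss $\sum w_{ij}\,\rho_\tau(FI_{ij} - x_{ij}'\beta)$, with
$\rho_\tau(u) = u(\tau - 1\{u<0\})$, pooling all observed person-waves
under an *independence working assumption*: within-person correlation is
ignored for point estimation and is instead absorbed by the resampling
scheme used for standard errors. This is the marginal (population-averaged)
analogue of a GEE with independence working correlation; no
working-correlation machinery is implemented, and none is needed for
consistency of the point estimator.

Quantile levels are fitted independently; crossing of fitted quantile
planes is possible in principle and is reported by comparing fits, never
"corrected", because each $\tau$ is a separate estimand.

## Stabilized observation weights

Let $R_{ij}$ indicate an interview and $Al_{ij}$ vital status. Among the
alive at waves $2,\dots,J$, two logistic response models are fitted:

* a **denominator (MAR) model** for
  $P(R_{ij}=1 \mid Al_{ij}=1, x_{ij}, \overline{FI}_{ik})$ with regressors
  sex, a study-entry indicator, the FI at the previous visit when
  available, an indicator of having been observed at the previous visit,
  and the lagged-FI-by-sex interaction;
* a **numerator (MCAR) model** for
  $P(R_{ij}=1 \mid Al_{ij}=1, x_{ij})$ with sex and the entry indicator
  only.

The stabilized weight of an observed record is the ratio of the fitted
numerator to denominator probabilities; entry-wave records carry weight 1.
Under the *unconditional* missing-at-random assumption — the probability of
being observed does not depend on survival time given the recorded history
— weighting the check loss by $w^*_{ij}$ removes the selection that the
interview process induces among the living.

Design choices a user should know about, all configurable:

* **Lagged FI.** "FI at the previous visit (if available)" is read as the
  most recent *observed* FI before wave $j$ (`lag_mode = "last_observed"`);
  a stricter previous-wave-only variant (`"previous_wave"`) imputes
  whenever wave $j-1$ itself was missed. When no prior FI exists the value
  is imputed with the sample mean of first-interview FI, and flagged.
* **Study-entry indicator.** Defined as wave $j$ being the first
  post-entry interview opportunity ($j = $ entry wave $+ 1$); first-wave
  response is structurally 1 and belongs to no response model.
* **Probability clipping.** Fitted probabilities are clipped to
  [0.01, 0.99] before the ratio (`clip = NULL` disables) and clip counts
  are reported. Small synthetic cohorts occasionally produce near-zero
  denominator probabilities; clipping trades a negligible bias for bounded
  weights.
* **Education in the weight models.** `include_education = TRUE` switches
  to the sensitivity specification (education main effect and
  lagged-FI-by-education interaction in the MAR model).
* **Unknown vital status.** The estimator needs an alive-set definition.
  Individuals whose status after their last interview is unknown should be
  coded `alive = 1, observed = 0` through the last wave: they then
  contribute to the response models as non-respondents. The synthetic
  generator produces fully known status; no masking option is provided
  because the analysis layer never uses the distinction.
* **Degenerate response.** If every alive person-wave is observed, the
  response models are unidentifiable but the weights are trivially 1;
  `estimate_weights()` short-circuits to exactly that, while
  `fit_observation_models()` called directly still raises the
  degenerate-outcome error. Separation raises an error pointing to
  `penalize = TRUE` (a lightly ridge-penalized logistic fit).

## Solving the weighted quantile regression

Since $\rho_\tau$ is positively homogeneous, the weighted problem equals
the unweighted problem on row-scaled data $(w_i y_i, w_i x_i)$. Its LP dual
is a box-constrained linear program solved by a Mehrotra
predictor-corrector primal-dual interior point method (the Frisch–Newton
approach): each iteration costs one $p \times p$ solve, so fits with tens
of thousands of rows take milliseconds. Numerical specifics:

* duality-gap tolerance $10^{-10}$, at most 100 iterations, step length
  0.9995 of the distance to the boundary;
* a final **vertex polish**: the solution is refit exactly through the $p$
  observations with the smallest absolute residuals and kept if the loss
  does not increase. In non-degenerate problems this lands exactly on the
  optimal basic solution, which is why the solver's loss matches an exact
  enumeration oracle to $10^{-6}$ and better in the test suite;
* **degeneracy and ties**: when the minimizer set is a face rather than a
  point (possible with discrete data), any vertex of that face is a valid
  answer; tests therefore compare losses, not coefficients, on such
  instances. The subgradient bracket — weighted share of strictly negative
  residuals $\le \tau \le$ weighted share of non-positive residuals — is
  asserted for every fit;
* a smoothed IRLS fallback (`method = "irls"`) is used automatically if
  the interior point fails to converge, and is available directly;
* rank-deficient designs are refused with the collinear columns named.

## Inference: the longitudinal bootstrap

Within-person correlation is real (the synthetic generator induces it
explicitly; see below), so observation-level resampling would understate
uncertainty. `cluster_bootstrap()` resamples *individuals* with
replacement, keeping each sampled individual's entire wave history
together; duplicates get distinct replicate-local ids so clustering stays
well defined. Per replicate, the education centering is recomputed and —
by default — the response models and stabilized weights are re-estimated
from the replicate's own sample, so the weight-estimation step contributes
its share of variance (`weighting = "fixed"` freezes the point-estimate
weights for quick smoke runs; the package default treats weight estimation
as part of the estimator). All $\tau$ are fitted on the same resample
within a replicate; the per-replicate differences then carry the
covariance needed by `cross_quantile_test()`, whose SE is the standard
deviation of those differences. Replicates whose solver or response model
fails are dropped and counted (never redrawn, keeping the draw sequence
seed-stable); more than 20% failures aborts with advice.

Wald p-values use the normal approximation with bootstrap SEs, matching
the robust-SE reporting convention for these models; percentile intervals
are used only for curve bands, where the quantity is a prediction rather
than a coefficient. The conventional replicate count is $B = 200$; tests
and examples use less where only mechanics are being exercised.

## The synthetic cohort and what it does (not) show

`sim_config()` encodes the study conditions the package is validated
under, emulating a large European biennial ageing panel:

* $n = 2000$ individuals (the default validation scale), 6 waves 2 years
  apart, entry at 65+ with a realistic entry-age mix (pre-1946 cohort
  centered at 74.5 years, the small 1946+ cohort entering near 66);
* latent FI from the location-scale model
  $FI_{ij} = x_{ij}'\beta + (\sigma_0 + \gamma A_{ij})\,\epsilon_{ij}$
  with right-skewed standardized errors (centered exponential) by default;
  the location coefficients default to published weighted-median estimates
  for this outcome so the synthetic effects live on a realistic scale
  ($\beta_a = 0.0067$ per year, $\beta_{ae} = -0.0004$, ...);
* because scale is linear in age, the true $\tau$-quantile coefficients
  are available in closed form: intercept shifted by
  $\sigma_0 q_\epsilon(\tau)$ and age slope by $\gamma q_\epsilon(\tau)$
  (`true_quantile_coefficients()`); with $\gamma > 0$ the true age slope
  increases strictly in $\tau$ — the "fan" that makes the frail tail
  progress faster;
* errors are equicorrelated within individual through a Gaussian copula
  (default correlation 0.5), which preserves every marginal quantile
  exactly — so the closed-form truth is unaffected — while making the
  cluster bootstrap genuinely necessary;
* per-wave logistic mortality on current FI and age, calibrated by
  forward simulation so that about 21–22% of the cohort dies within six
  waves; per-wave logistic interview probability among the alive driven
  negatively by the *previous wave's latent* FI (about 0.6 on average,
  with roughly a quarter of the cohort contributing only one or two
  interviews). Using the latent rather than the observed lagged FI is
  deliberate: the estimator can only see observed history and must impute,
  exactly the gap real panels present;
* latent FI is clamped to [0, 1]; defaults keep the clamped fraction
  around 0.4% (reported per panel as `clamp_frac`) so the closed-form
  truth holds to well within Monte-Carlo tolerance.

What passing the recovery and correction tests shows: the estimator
pipeline is internally consistent, recovers known truth on clean data, and
the weighting reduces the attrition bias of the upper-quantile age slope
under the encoded missingness mechanism, lifting the frail-tail reference
curve at older ages — the qualitative signature of mortal-cohort
correction. What it does not show: robustness to misspecified response
models, to missingness that is not at random, to measurement error in the
deficit items, or to trajectory shapes that are non-linear in age. The
generator also leaves mortality selection itself uncorrected — the
weighted estimand is the quantile among the alive, so even the weighted
fit is not expected to hit the immortal-population truth exactly, and the
tests accordingly compare *relative* bias of weighted versus unweighted
fits at the defaults.

## FI construction

`apply_item_spec()` + `compute_fi()` implement the deficit-accumulation
FI: declarative per-item coding rules (threshold or category-map,
fractional scores allowed) produce deficit scores; the FI of a person-wave
is the mean of its non-missing scores, computed only when at least
`min_valid` of `n_items` items are valid (defaults 35 of 40). The
denominator is the number of non-missing items — the standard
deficit-accumulation convention — so an item gone missing changes the
validity count but never re-weights the remaining items. A synthetic
40-item battery ships in `inst/extdata/` for end-to-end exercises; it is
labelled synthetic and mimics no particular instrument.

## Problem sizes used by the tests

The packaged validation suite runs at desk scale, chosen once: parameter
recovery on $n = 2000 \times 6$ waves with bootstrap SEs at $B = 150$;
the mortal-cohort correction averaged over 20 simulated cohorts at the
default conditions; test size/power for the cross-quantile test over 100
(size) and 25 (power) cohorts of $n = 250 \times 4$ waves at $B = 100$;
coverage checks at reduced $n$ with binomial tolerances. These sizes give
stable Monte-Carlo behaviour while keeping a full run to a few minutes.

## Known limitations

* Linear-in-age trajectories only; no splines or penalized fits.
* The response models condition on a single lagged FI summary; richer
  time-varying covariates are out of scope.
* No survey design features (country strata, sampling weights).
* Normal-approximation p-values from bootstrap SEs; no studentized or
  percentile-t refinements.
* The education offset $\beta_a^\tau / |\beta_{ae}^\tau|$ is a ratio of
  estimates; its uncertainty is not propagated (report it alongside the
  coefficient table, not instead of it).
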