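---
title: "Methods: attributable health care costs from behavioural and socioeconomic risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable health care costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costpaf)
```

## The problem

Smoking, unhealthy alcohol consumption, poor diet and physical inactivity
are leading causes of morbidity, and health surveys individually linked to
administrative cost records make it possible to estimate how much of a
public health care budget those behaviours — and socioeconomic position —
account for. `costpaf` implements that analysis as a pipeline: exposure
scoring of raw survey responses, sex- and sector-specific negative
binomial cost regression over a stepped covariate ladder, factor-deleted
counterfactual population attributable fractions (PAFs), expenditure
attribution with CPI inflation, an avoided-cost counterfactual holding the
baseline-year PAF fixed, and three sensitivity analyses. Because real
linked survey/cost data are access-restricted, the package ships a
synthetic cohort generator whose generating parameters are known exactly,
so every stage can be validated against enumerable ground truth.

## Exposure scoring

Raw responses are mapped deterministically to analytic categories:

* **Smoking** — heavy (current daily, ≥ 20 cigarettes/day), light
  (current daily < 20, or current occasional with ≥ 100 lifetime
  cigarettes), former heavy / former light by the same 20/day threshold
  on the former daily amount, and non-smoker (never, or occasional with
  fewer than 100 lifetime cigarettes).
* **Alcohol** — heavy is bingeing (five or more drinks on a day in the
  previous week, or weekly bingeing in the previous month) or more than
  21 (men) / 14 (women) drinks per week; at-or-below the threshold with
  no bingeing is moderate; no alcohol in 12 months is non-drinking.
* **Diet** — an index starting at 2 points, plus one point per average
  daily fruit/vegetable serving capped at 8 additional points, minus 2
  points each for juice servings above one, no carrot consumption, and
  potato servings above 1 (men) / 0.7 (women); negatives floored at 0,
  maximum 10. Poor < 2.5, fair [2.5, 5), adequate [5, 10]. The index
  description does not pin down whether serving points are integer-only;
  we award fractional points for fractional servings (one point per
  serving before capping), which reproduces the stated maximum of 10 and
  keeps the score continuous in intake.
* **Physical activity** — MET-hours/day summed over reported leisure
  activities as (sessions/week ÷ 7) × hours/session × MET, using
  low-intensity MET values; inactive < 1.5, moderately active [1.5, 3),
  active ≥ 3.
* **Deprivation** — material and social quintiles of the respondent's
  dissemination area crossed into 25 cells; both quintiles ≤ 2 is low
  (4 cells), both ≥ 4 is high (4 cells), otherwise moderate (17 cells).

All "X to < Y" ranges are left-closed/right-open and ≥/≤ thresholds are
inclusive. A missing raw field needed by a rule yields the explicit
category `missing`, which is retained as a model level — rows are never
dropped for item non-response, and counterfactual recoding never turns a
missing exposure into an assumed one.

## Cost models

For each sex and each sector (hospital, drugs, community care) we fit a
negative binomial GLM with log link on total sector cost over follow-up
(rounded to whole dollars so the count likelihood is well defined) with
an offset of log person-years, so coefficients are log annual cost
ratios against the reference levels (non-smoker, moderate drinker,
adequate diet, active; post-secondary, income ≥ $80k, owned home, low
deprivation). Follow-up is one to four years.

Covariates enter along a pre-specified nested ladder: (1) age and the
four behaviours; (2) + immigrant status, education, marital status;
(3) + income, home ownership, urban residence, deprivation, ethnicity,
stress, flu vaccination — the *primary attribution model*; (4) + health
status indicators (BMI, hypertension, diabetes, heart disease, cancer,
stroke, dementia), which may mediate behaviour effects; (5) + fragility,
the over-adjusted model. With five steps and three sectors this is 15
models per sex. The grouping of variables into steps follows the
standard confounder/mediator reading of the ladder; where the step
membership of a variable was genuinely ambiguous (ethnicity could sit
with basic sociodemographics or with the wider attribution set) we
placed it in step 3 with the other area- and resource-related factors.

Fitting uses `MASS::glm.nb` (maximum likelihood, per-model dispersion,
IRLS convergence checked; a non-converged fit is an error carrying the
sex/sector/step context). By default fits are **unweighted** and survey
weights enter only at the PAF prediction stage, where predictions are
applied to the weighted survey cycle; a `weighted_fit` flag switches to
survey-weighted pseudo-likelihood fitting. Zero-variance covariates are
excluded from the design with a message rather than failing the fit.

## Population attributable fractions

The factor-deleted PAF for a risk R, sector s and survey cycle c is

$$\mathrm{PAF} = \frac{\sum_i w_i \hat\mu_i - \sum_i w_i \hat\mu_i^0}
                     {\sum_i w_i \hat\mu_i}$$

where $\hat\mu_i$ is the model-predicted expected annual cost of person
*i* under observed exposures, and $\hat\mu_i^0$ the prediction after
recoding every non-reference, non-missing level of R's variables to the
reference (for smoking: current *and* former smokers become
non-smokers). This is g-computation / model-based standardization with
the cohort's own covariate distribution. Both sexes' weighted
predictions are pooled before the ratio, so province-level PAFs come
from sex-specific models. PAFs may be negative when the reference is
not cost-minimal — notably for alcohol, where the reference is the
*moderate* drinker, so the default counterfactual also recodes
non-drinkers upward; a `heavy_only` switch restricts recoding to heavy
drinkers. The combined-behaviour PAF recodes all four behaviours
simultaneously; the socioeconomic equity gap recodes education, income,
home ownership and deprivation to their lowest-cost levels.

Cycle PAFs are anchored to the first fiscal year of each field period;
years between cycles get the arithmetic mean of the nearest preceding
and succeeding cycle estimates (no extrapolation outside the span).

## Dollars

Annual sector expenditures (nominal) are inflated to 2014 dollars with
a general CPI series; the expenditure table is tagged with a
currency-year attribute and a second inflation is an error, so money
flows through inflation exactly once. Attributable cost is PAF ×
expenditure per (risk, sector, year); the `other` sector (system
operating and capital costs with no person-level records) borrows the
community-care PAF. Avoided costs hold the baseline-year PAF fixed:
the counterfactual budget is $C_t = B_t (1-\mathrm{PAF}_t) /
(1-\mathrm{PAF}_0)$ — the only reading under which "the baseline PAF
did not change" pins a counterfactual budget to observed spending —
and avoided(t) = $C_t - B_t$, positive exactly in years where the PAF
fell below baseline. The baseline PAF is the total-budget PAF
(budget-share-weighted across sectors) by default; a sector-wise
variant is available by running the calculation per sector.

## Sensitivity analyses

1. **Ladder bounds** — the step-1 (minimally adjusted) and step-5
   (over-adjusted) PAFs bracket the step-3 primary estimate; the
   ordering upper ≥ primary ≥ lower typically holds but is recorded,
   not enforced.
2. **High-cost-user exclusion** — removing the top 5% of users by total
   cost across all sectors (ceiling(0.05 n) persons, ties broken by
   stable person-id order with a warning), then comparing
   age-standardized cost ratios. The standard population is the
   survey-weighted age distribution of the full two-sex cohort; age
   groups with an empty stratum are dropped from both sums
   symmetrically with a warning.
3. **IPW** — a multinomial logistic propensity model for the exposure
   given the primary-attribution covariates; stabilized weights
   (marginal level probability ÷ fitted probability), truncated at the
   99th percentile by default, with near-zero propensities reported as
   non-overlap warnings. On correctly specified data the IPW cost
   ratios agree with the GLM ratios; under confounding they move the
   crude ratio toward the truth.

## The synthetic cohort generator

`default_generator_config()` describes the study conditions the
pipeline is validated under: six biennial cycles (2003–2013), 14
five-year age groups from 25–29 to 90+, 45.6% male, behaviour and
socioeconomic prevalences chosen to resemble an Ontario adult survey
population (heavy smoking ~11% of men, declining across cycles; BMI
uses realistic normal-dominant prevalences), 1%
behaviour item non-response, survey weights log-normal, follow-up
mostly four years (83%), and per-sector annual costs from a log-link
negative binomial model with known coefficients (e.g. heavy smoking log
cost ratio 0.40 for hospital care, baseline $1200/year, dispersion
θ = 0.6; sectors are generated independently given covariates, the
simplest model consistent with sector-wise fitting). Raw survey
responses are generated so that re-scoring them reproduces the sampled
categories (a round-trip property tested at > 99.9%). Confounding is a
single log-odds tilt making risky behaviour levels more likely at lower
education; an oversampling option makes weights informative by tilting
the sampling rate by exposure level and absorbing the inverse tilt into
the design weights.

`true_paf()` computes the generating model's PAF by **exact
enumeration** over the discrete covariate distribution — a weighted sum
of μ and μ⁰ over roughly 1.2 million cells — with no sampling error,
and `true_paf_mc()` cross-checks it by Monte Carlo. What the generator
does *not* emulate: survey design effects (strata, clusters, replicate
weights), cross-sector cost correlation, linkage error, and
within-category exposure heterogeneity; passing tests therefore
validate the estimator's logic and statistical behaviour, not the
survey-variance properties of real data.

## Numerical choices and test scale

* NB fits: `MASS::glm.nb`, IRLS with `maxit = 100`; convergence is
  checked and failure is an error, not a silent warning.
* Costs are rounded to whole dollars before fitting ($1 granularity is
  the least-distorting way to make dollar costs a count outcome).
* PAF equality with its per-person brute-force oracle is asserted to
  1e-10 relative; closed-form homogeneous cases to 1e-10.
* Validation runs use cohorts of roughly 5,000–20,000 respondents:
  parameter and PAF recovery at ~20,000 (combined-behaviour PAF within
  0.015 of enumerated truth), 95% Wald coverage over 200 replicates of
  5,000, dispersion recovery within 25% — sizes at which the asymptotic
  behaviour is clearly visible while the full suite runs in minutes.
* Share tables are rounded to integer percent; ties in the top-user
  exclusion break by person id so results are reproducible.

## Known limitations

Self-reported exposures, the absence of two-part (zero-inflated) cost
models, no survey-bootstrap variance for PAFs (uncertainty is expressed
through the model ladder instead of sampling variance), and the
`other` sector's reliance on the community-care PAF are all inherited
design properties of the analysis this package implements. The
generator's independence assumptions (sectors independent given
covariates; extra covariates independent of behaviours) make recovery
tests cleaner than real data would be.
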