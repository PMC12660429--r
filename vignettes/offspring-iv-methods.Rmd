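---
title: "Offspring BMI as an instrument for parental BMI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offspring BMI as an instrument for parental BMI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioiv)
```

## The problem

Observational estimates of the effect of body mass index (BMI) on long-term
sick leave are distorted by two mechanisms that act in opposite directions.
Shared lifestyle and socioeconomic confounders tend to inflate the hazard
ratio per unit of BMI, while reverse causation — chronic illness that lowers
body weight while raising the risk of sick leave — deflates it and bends the
categorical dose-response curve into a J shape at the underweight end.

`trioiv` implements the offspring-as-instrument design for this problem.
Offspring BMI is associated with parental BMI through shared genetic and
environmental factors, but it cannot be altered by the parent's later
illness, so an estimator driven only by the offspring signal is insulated
from reverse causation.  The trade-off is that any confounder transmitted
across generations (education, class, behaviour) still reaches the
instrument; the package therefore ships the diagnostics needed to judge that
residual path, not just the estimator.

## The estimator

For each sex the pipeline fits, on the age time axis with delayed entry at
the baseline age:

* the **conventional** model: a Cox regression of first long-term sick leave
  on the parent's own BMI z-score;
* the **reduced form**: the same Cox regression on the offspring's BMI
  z-score, giving a log hazard ratio $\hat\beta_{ZY}$;
* the **first stage**: a linear regression of parental z on offspring z with
  the same adjustment, giving the mean difference $\hat\beta_{ZX}$ (SD of
  parental BMI per SD of offspring BMI).

The single-instrument ratio (Wald) estimate is
$\hat\beta_{IV} = \hat\beta_{ZY}/\hat\beta_{ZX}$, reported as
$\exp(\hat\beta_{IV})$, the hazard ratio per SD of own BMI.  Its standard
error uses the first-order Taylor (delta-method) expansion for a ratio of
independent estimates,
$$\mathrm{se}_{IV} = \sqrt{\frac{\mathrm{se}_{ZY}^2}{\hat\beta_{ZX}^2} +
\frac{\hat\beta_{ZY}^2\,\mathrm{se}_{ZX}^2}{\hat\beta_{ZX}^4}},$$
and the 95% CI is $\exp(\hat\beta_{IV} \pm 1.96\,\mathrm{se}_{IV})$.
Numerator and denominator are computed from the same sample, but the
covariance term is omitted from the variance, as is conventional for this
estimator; a parametric-bootstrap oracle in the test suite confirms the
approximation is within a few percent when the instrument is strong.  The
package deliberately does not implement two-stage least squares, Fieller
intervals or multi-instrument methods: the design has exactly one
instrument, and the ratio form keeps the numerator interpretable as an
ordinary Cox coefficient.

Instrument strength is summarized by the partial $R^2$ and partial $F$ of
the offspring z-score in the first stage.  `iv_ratio()` refuses a
denominator within one SE of zero and warns below $|\hat\beta_{ZX}|/\mathrm{se} = 10$
(roughly $F = 100$); the estimate is still reported down to weak instruments
because a flagged estimate is more useful than a refusal, but the warning is
prominent.  With an intercept-only reduced model the partial $F$ equals the
squared t-statistic of the instrument coefficient exactly, which the tests
assert to $10^{-8}$.  The single-instrument identity
$F = \frac{r^2}{1-r^2}(n - p)$ is exposed as `partial_f_from_r2()`; applied
to published first-stage tables it reproduces unadjusted $F$ values to a
fraction of a percent with $p = 11$ (intercept, instrument, wave indicator,
and the four spline columns within each of two waves).  For *adjusted*
first stages the published $F$ values are typically not exactly recoverable
from the rounded $R^2$ and $n$ because the residual degrees of freedom
depend on how many covariate dummies the fitted model carried; the package
documents this rather than guessing a convention.

## z-scores

Adult BMI is standardized within age category (&lt;30, 30–39.9, 40–49.9,
≥50 years at measurement), sex and survey wave; boundaries are half-open on
the left, so an age of exactly 40 falls in 40–49.9.  Strata are fitted on
the pooled adult participants (parents and adult offspring together), the
way a survey cohort in which both generations are participants standardizes
its baseline measurements; per-stratum SDs use denominator $n-1$, and
degenerate strata (fewer than two records, zero variance) are an error
rather than a silent NA.  Offspring under 18 (exactly 18 counts as adult)
are standardized with the LMS method,
$z = \frac{(\mathrm{BMI}/M)^L - 1}{LS}$, with the log-limit branch engaged
below $|L| < 10^{-12}$; $L$, $M$ and $S$ are interpolated linearly in exact
age within sex, the standard practice when the reference grid spacing is
unknown.  The bundled LMS table is synthetic — smooth, adolescent-shaped,
clearly labelled — because the IOTF reference coefficients are licensed;
real analyses supply their own table via `read_lms_reference()`.

## Adjustment

All models adjust for a 5-knot restricted cubic spline of baseline age
interacted with survey wave (wave main effect plus wave-specific spline
blocks, i.e. a separate age curve per wave — the parameterization that makes
the "age-by-wave interaction" unambiguous; the choice is recorded in the
report metadata).  Knots sit at the 5th, 27.5th, 50th, 72.5th and 95th
percentiles of baseline age, the standard 5-knot placement.  The spline
basis is the truncated-power natural spline: first column the age itself,
dimension 4, linear beyond the boundary knots; the tests verify the
boundary second derivatives vanish and that the basis spans the same fits
as `splines::ns`.  The full adjustment appends treatment-coded dummies for
education (6 levels), EGP occupational class (8 levels, class VIII
collecting military/unknown), smoking (4), alcohol frequency (6) and
physical activity (4) — 23 columns.  Ties in event ages use the Efron
approximation (ages recorded at day resolution tie often); with distinct
event ages Efron and Breslow agree to $10^{-8}$ and the suite checks that
too.  Confidence intervals are Wald throughout, matching the
estimate-(95% CI) presentation convention of the field.

## Diagnostics

**Bias component table.**  For each measured covariate the package pairs the
unadjusted association with the parent's own z (logistic for binary
covariates, linear for continuous) against the instrumental version — the
association with offspring z divided by the unadjusted first-stage slope,
its CI from the same Taylor formula.  Each pair is rescaled by the absolute
magnitude of its larger member, so components lie in $[-1, 1]$, are
proportional to the omitted-covariate bias, and are comparable only within a
pair — the export keeps one row per covariate and never totals across rows.
Categorical covariates are dichotomized at fixed cut-points: education below
university (ordinal levels 1–4), EGP class ≥ III, current smoker (daily or
occasional), alcohol at least 2–3 times a week, and physical activity below
3 h light with no hard activity.  Log-odds, not odds ratios, enter the
scaling for binary covariates; since each pair is scaled by its own larger
member the qualitative conclusion is identical either way.  Pairs whose
larger member is within twice its SE of zero are flagged `negligible`
rather than scaled up into spurious prominence.

**Proportional hazards.**  Follow-up is episode-split at the median
time-to-event among events; one model with an exposure-by-period
interaction yields early and late hazard ratios and a Wald z for their
difference.  An event exactly at the split time belongs to the early period
(the split is closed on the right).  Under data generated with exact
proportional hazards the test holds its size (checked over 100 replicates);
note that when strong unobserved frailty is present — as in the default
generator with the illness mechanism on — the *marginal* exposure effect is
genuinely time-varying even though the conditional model is proportional,
and the split test correctly reports that.

## The synthetic generator

Registry linkage data of this kind cannot be shipped, so every stage is
validated against `simulate_trios()`, whose causal structure is known by
construction: a standard-normal familial factor $G$ loading on both
generations' BMI z-scores, a standard-normal confounder $U$ loading on the
parent (and optionally the offspring — setting that loading to zero gives a
valid instrument), and a latent illness $D$ that lowers parental BMI while
raising the hazard.  Residual variances are solved so both z-scores have
unit variance, and configurations that make this impossible are rejected.
Event times are exponential given covariates — the simplest model that
satisfies proportional hazards exactly, so recovery tests are not
confounded by baseline-hazard misspecification.  Covariates are drawn
through proportional-odds links in $X_p$ and $U$, which makes every
dichotomized log-odds equal to the configured coefficient; default signs
reproduce the cohort pattern (smoking inversely associated with own BMI but
positively through the shared factor; low education, lower-status class and
low activity positively associated; frequent alcohol inversely).

Default parameters are the package's one-time choices for a realistic
mid-Norway cohort: instrument-exposure slope 0.23 (familial loading
$\sqrt{0.191}$ plus confounder loadings 0.30 × 0.13), true causal log HR
0.15 per SD, confounder log HR 0.30, illness prevalence 8% shifting BMI by
−1.2 SD and multiplying the hazard by $e^{1.4} \approx 4$, baseline rate
0.085 events per person-year, entry ages 25–60, administrative censoring
after 10 years and an age-65 bound.  These yield all-cause incidence near
95–110 per 1000 person-years, mean follow-up around 6 years, first-stage
partial $R^2$ of 5–6% with $F$ in the hundreds, a visibly J-shaped
conventional categorical curve and a monotone offspring-based curve — the
qualitative fingerprint of the design.  The empirical correlation structure
*among* the covariates is not calibrated to any cohort (no such summary is
generally published); only the marginal levels and the signs of their BMI
associations are.

What passing tests on this generator do **not** show: robustness to
non-proportional baseline hazards, to measurement error in covariates, to
family clustering (both parents sharing one offspring are simulated as
independent families), or to selection into survey participation.  Real
analyses must weigh those separately.

## Numerical behaviour and known limitations

Because the numerator is a Cox coefficient, the ratio estimator targets a
marginal hazard ratio and is not exactly collapsible: with the default
event fraction (roughly 60% over follow-up) and strong unobserved frailty,
the reduced form is attenuated while survivor selection through the illness
mixture pushes it the other way.  Over 200 replicates at 20,000 families
the mean IV estimate is within Monte-Carlo error of the generating 0.15
while the conventional estimate is biased to about 0.117 — reverse
causation dominating the positive confounding — which is precisely the
contrast the design exists to reveal.  The Taylor CI attains 95.6–95.8%
empirical coverage at strong instruments (500 replicates per effect size at
6,000 families, chosen so every replicate's partial $F$ clears 100).  At
weak instruments the ratio distribution grows heavy tails and the delta
interval undercovers; that regime is guarded, not supported.

Other deliberate simplifications: competing events (death, disability) are
treated as censoring; there is no Fine–Gray model, no frailty term and no
clustered standard errors.  Missing covariate data are handled by
complete-case exclusion only, with an exclusion tally whose sum plus the
retained count always equals the input count.

## Problem sizes used in the checks

The bundled validation uses 20,000 families × 200 replicates for parameter
recovery, 6,000 × 500 per effect size for CI calibration, 60,000 for the
categorical-curve shape, and toy risk sets of 2–8 subjects for the
partial-likelihood grid oracle — sizes at which every Monte-Carlo tolerance
in the suite is meaningful while the whole suite runs in minutes on one
core.
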