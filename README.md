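# trioiv

Offspring BMI as an instrumental variable for the effect of parental BMI on
long-term sick leave.

## The problem

Conventional Cox regression of sick-leave risk on own body mass index (BMI)
is biased in two directions at once: shared lifestyle/socioeconomic
confounding inflates the hazard ratio, while reverse causation — illness
that lowers weight and raises sick-leave risk — deflates it and bends the
categorical dose-response into a J shape at the underweight end.  Because a
parent's later illness cannot change their offspring's BMI, the offspring's
BMI can serve as an instrument that is insulated from reverse causation.
`trioiv` is for epidemiologists and biostatisticians who want that design as
a tested, reusable pipeline: z-score construction (adult strata and LMS for
under-18 offspring), left-truncated Cox models on the age time axis with
restricted-cubic-spline-by-survey adjustment, the single-instrument ratio
estimator, and its diagnostics.

## The estimator

With $\hat\beta_{ZY}$ the log hazard ratio of sick leave per SD of offspring
BMI (reduced form) and $\hat\beta_{ZX}$ the mean difference in parental BMI
z per SD of offspring BMI (first stage, same adjustment), the Wald ratio
estimate is

$$\widehat{HR}_{IV} = \exp\!\left(\hat\beta_{ZY}/\hat\beta_{ZX}\right),
\qquad
\mathrm{se}_{IV} = \sqrt{\mathrm{se}_{ZY}^2/\hat\beta_{ZX}^2 +
\hat\beta_{ZY}^2\,\mathrm{se}_{ZX}^2/\hat\beta_{ZX}^4},$$

with Wald 95% CIs on the log scale.  Instrument strength is reported as the
first-stage partial R² and partial F; a bias component table contrasts the
relative confounding of the conventional and instrumental estimates
covariate by covariate; a split-follow-up test checks proportional hazards.
Every stage is validated against a synthetic family-trio generator with
known causal structure (shared confounding, latent-illness reverse
causation), so the whole pipeline is testable without registry access.

## Worked example

```r
library(trioiv)

cfg <- simulation_config(n_families = 30000, seed = 7)
trios <- simulate_trios(cfg)
report <- run_all(trios, adjustment = "minimal")
report
#> trioiv analysis report (minimal adjustment, sensitivity none)
#>   30000 records analysed of 30000 input
#>   F all             conv HR 1.12 (1.09-1.14)  IV HR 1.36 (1.25-1.48)  96/1000 PY
#>   F musculoskeletal conv HR 1.12 (1.08-1.15)  IV HR 1.29 (1.15-1.46)  43/1000 PY
#>   F mental          conv HR 1.14 (1.08-1.20)  IV HR 1.37 (1.12-1.66)  16/1000 PY
#>   M all             conv HR 1.11 (1.08-1.13)  IV HR 1.38 (1.24-1.53)  95/1000 PY
#>   M musculoskeletal conv HR 1.11 (1.08-1.15)  IV HR 1.49 (1.27-1.74)  43/1000 PY
#>   M mental          conv HR 1.12 (1.06-1.19)  IV HR 1.59 (1.23-2.04)  16/1000 PY

report$instrument_strength
#>   sex     n        md       md_se     md_lo     md_hi partial_r2 partial_f
#> 1   F 16763 0.2408590 0.007432622 0.2262911 0.2554269   5.898883 1050.1265
#> 2   M 13237 0.2113974 0.008115421 0.1954912 0.2273036   4.880007  678.5426
```

Reading this: the first-stage mean difference (`md`, ~0.22–0.24 SD of
parental BMI per SD of offspring BMI, partial F in the hundreds) says the
instrument is strong.  The conventional hazard ratios (~1.10–1.14 per SD)
are *smaller* than the IV ones because the generator's latent-illness
mechanism drags the conventional estimate down — the reverse-causation bias
the design removes.  The IV column exceeds the generating causal HR
(exp(0.15) ≈ 1.16) here because this configuration also transmits part of
the confounder to the offspring; set `loading_confounder_offspring = 0` for
a valid instrument and the IV estimate centres on the truth (the test suite
does exactly that over 200 replicates).

The ratio arithmetic is also available directly from printed summary
statistics:

```r
iv_from_summary(num_hr = 1.05, num_ci = c(1.02, 1.08),
                den_md = 0.22, den_ci = c(0.21, 0.24))
#> IV HR 1.248 (95% CI 1.095-1.423)
#>   numerator log HR 0.0488 (SE 0.0146); denominator MD 0.2200 (SE 0.0077)
```

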