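# riskclass

Population health surveys such as the Behavioral Risk Factor Surveillance
System (BRFSS) carry dozens of correlated dichotomous health indicators —
risky behaviors, diagnosed conditions, health care access problems, unused
preventive services. Regressing an outcome on all of them at once invites
collinearity; picking a handful invites confounding by the ones left out.
`riskclass` implements the standard two-stage alternative for
epidemiologists and survey analysts:

1. **Latent class analysis per domain.** Within each of four health
   domains (5 risky behaviors, 8 health conditions, 5 access items, 6
   preventive-service items; all 24 indicators coded 1 = adverse state),
   respondents are modeled as a finite mixture of *K* latent classes. Given
   class membership *c*, items are independent Bernoulli draws, so the
   likelihood of response pattern *y* with design weight *w* is

   L = Σᵢ wᵢ · log Σ_c π_c ∏_{j ∈ obs(i)} ρ_cj^{y_ij} (1 − ρ_cj)^{1−y_ij}

   where π are class prevalences, ρ class-conditional endorsement
   probabilities, and obs(i) skips missing cells — both item nonresponse
   and *structural* missingness from sex/age eligibility gates (PSA asked
   only of men ≥ 40, mammogram only of women ≥ 40, Pap only of women with
   an intact cervix, endoscopy only at ≥ 50) are treated as missing at
   random. Estimation is by EM with multiple random starts; the number of
   classes is chosen by BIC = −2·loglik + p·log(n); classes are ordered by
   mean endorsement so class 1 is always the highest-risk class.

2. **Weighted logistic regression.** Each respondent's modal class per
   domain enters, with the low-risk class as reference, into
   design-weighted logistic regressions of two health-related
   quality-of-life outcomes — frequent physical and frequent mental
   distress (≥ 14 of the past 30 days physically / mentally unhealthy) —
   adjusting for age group, sex, race/ethnicity, education and employment.
   Robust (sandwich) variances give odds ratios with 95% CIs.

Because the microdata such analyses run on are confidential, the package
ships a seeded synthetic survey generator with known ground-truth latent
structure (`population_spec()` / `simulate_survey()`), which is how every
stage is tested end to end.

## Worked example

```r
library(riskclass)

run <- run_pipeline(population_spec(n_respondents = 4786, seed = 1),
                    k_max = 4, n_starts = 10, seed = 1)
print(run)
```

```
<pipeline_run> n = 4786
  chosen class counts:
    risky_behavior      K = 2
    health_condition    K = 2
    health_care_access  K = 2
    preventive_service  K = 2
  odds-ratio table:
# A tibble: 8 × 6
  domain             level or_ci_physical   p_physical or_ci_mental     p_mental
  <chr>              <chr> <chr>                 <dbl> <chr>               <dbl>
1 risky_behavior     low   1 [Reference]    NA         1 [Reference]   NA
2 risky_behavior     high  1.37 (1.09-1.71)  0.00594   2.19 (1.79-2.6…  1.83e-14
3 health_condition   low   1 [Reference]    NA         1 [Reference]   NA
4 health_condition   high  1.76 (1.36-2.27)  0.0000188 1.79 (1.40-2.2…  3.49e- 6
5 health_care_access low   1 [Reference]    NA         1 [Reference]   NA
6 health_care_access high  1.62 (1.24-2.10)  0.000325  1.77 (1.34-2.3…  6.70e- 5
7 preventive_service low   1 [Reference]    NA         1 [Reference]   NA
8 preventive_service high  1.11 (0.92-1.33)  0.269     0.94 (0.78-1.1…  4.85e- 1
```

Reading the output: respondents in the high-risk behavior, health
condition and limited-access classes have significantly elevated odds of
frequent distress, while the preventive-services classes show no
association — the qualitative pattern the generator's outcome model
encodes. Note BIC chose two classes per domain here: the default synthetic
profiles are only moderately separated, and at n ≈ 4800 BIC conservatively
merges the weakly identified intermediate class. With well-separated
profiles the three-class truth is recovered reliably:

```r
ds <- default_domain_specs()
ds$health_condition <- separated_domain_spec(J = 8)
svy <- simulate_survey(population_spec(n_respondents = 4800, seed = 1,
                                       domain_specs = ds,
                                       item_missing_rate = 0))
ind <- derive_indicators(svy)
sel <- lca_select(ind$health_condition, svy$respondents$design_weight,
                  k_max = 4, n_starts = 20, seed = 1)
tidy(sel)
#> # A tibble: 4 × 5
#>   n_classes  loglik n_params    bic chosen
#>       <int>   <dbl>    <dbl>  <dbl> <lgl>
#> 1         1 -25677.        8 51421. FALSE
#> 2         2 -21460.       17 43064. FALSE
#> 3         3 -21073.       26 42366. TRUE
#> 4         4 -21059.       35 42415. FALSE
```

Each fitted object has `tidy()` / `glance()` methods and an `autoplot()`
(class profile lines, BIC curves, OR forest plots); `write_survey()` /
`read_survey()` round-trip data as CSV plus a YAML codebook, and
`write_run()` emits all report tables and a reproducibility manifest.

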