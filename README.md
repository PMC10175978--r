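# bzdbp

Doubly robust estimation of the effect of incident short- and long-term
benzodiazepine / z-drug (BZD) management on systolic and diastolic blood
pressure (SBP/DBP) from longitudinal primary-care records.

Sedatives are commonly prescribed long-term despite guidance to the
contrary, and their vasorelaxant properties may lower blood pressure —
a plausible contributor to falls in older patients. Quantifying that effect
from electronic health records requires more than a regression: incident
exposure episodes must be constructed from raw script streams under a
new-user design, outcome windows differ by exposure class, baseline blood
pressure is missing for a fifth of patients, patients cluster within
practices, and prescribing is heavily confounded by indication. `bzdbp`
packages that entire workflow for epidemiologists working with
general-practice EHR extracts, together with a ground-truth synthetic data
generator used to validate every stage.

## The estimator

Treatment is three-valued: `none`, `short_term`, `long_term` (first 2017
episode; long-term means ≥ 3 scripts within 180 days of the first script
with the second script more than 28 days after it, the episode ending at a
≥ 180-day script-free gap). For level *t*, with p̂ₜ(x) from a
multinomial-logit treatment model and m̂ₜ(x) from per-level linear outcome
models,

    μ̂ₜ = (1/n) Σᵢ [ 1{Tᵢ=t} (Yᵢ − m̂ₜ(Xᵢ)) / p̂ₜ(Xᵢ) + m̂ₜ(Xᵢ) ]
    ATEₜ = μ̂ₜ − μ̂₀   (mmHg)

— augmented inverse-probability weighting (AIPW), consistent when either
nuisance model is correct. Standard errors aggregate influence
contributions within practices (CR1 cluster sandwich, t(G−1) intervals).
Missing confounders are handled by chained-equation multiple imputation
with Rubin's-rule pooling of per-imputation ATEs; crude and
covariate-adjusted OLS comparators, age-stratified (18–64 / 65+) and drug
half-life sensitivity analyses mirror the full analysis plan.

## Worked example

```r
library(bzdbp)

# classify one patient's script stream
classify_first_episode(as.Date("2017-03-10") + c(0, 40, 100))
#> <exposure_episode> long_term start 2017-03-10 end 2017-06-18 scripts 3

# a synthetic population with known effects, and the full pipeline
cfg <- synth_config(n_practices = 60, patients_per_practice = 400,
                    true_ate_long_sbp_65plus = -2.5,
                    true_ate_long_dbp_65plus = -1.0, seed = 42)
bundle <- run_pipeline(cfg, impute = imputation_spec(m = 5, n_cycles = 5),
                       analyses = c("overall", "age_stratified"))
bundle
#> <results_bundle> 20 pooled estimates; incidence short 3.08%, long 0.48%
#>        analysis stratum      level     outcome estimator         ate        se
#>         overall     all short_term outcome_sbp      aipw -0.07095571 0.3847060
#>         overall     all  long_term outcome_sbp      aipw -1.83264721 0.9869147
#>         overall     all short_term outcome_dbp      aipw  0.59328139 0.2254037
#>         overall     all  long_term outcome_dbp      aipw -1.37825893 0.4439346
#>  age_stratified   18-64  long_term outcome_sbp      aipw -1.10044415 0.9220310
#>  age_stratified  65plus  long_term outcome_sbp      aipw -3.36553448 1.2023816
#>  ...
bundle$flow
#>                          step     n
#>  patients_with_clinical_visit 23886
#>         in_eligible_practices 22662
#>        regular_adult_patients 20622
#>          no_baseline_year_bzd 20314
#>               with_outcome_bp 20314
```

Reading the output: the generator planted +0.4/+0.5 mmHg short-term and
−1.1/−0.1 mmHg long-term effects, strengthened to −2.5/−1.0 at age 65+.
At this deliberately modest size (~20,000 patients, ~100 long-term users)
the pooled AIPW estimates recover those magnitudes within their reported
uncertainty — e.g. long-term SBP −1.8 (SE 1.0) overall and −3.4 (SE 1.2)
in the 65+ stratum — and the flow table shows each eligibility filter
(practice data-quality, regular adult patients, washout-year exclusion,
outcome availability) doing its work. `write_results(bundle, dir)`
serialises `estimates.csv`, `flow.json` and `diagnostics.json`.

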