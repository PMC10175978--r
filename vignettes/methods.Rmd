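---
title: "Doubly robust estimation of sedative effects on blood pressure: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust estimation of sedative effects on blood pressure: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

`bzdbp` estimates average treatment effects (ATE) of incident short- and
long-term benzodiazepine / z-drug (BZD) management on systolic and diastolic
blood pressure (SBP/DBP, mmHg) from routinely collected general-practice
records: consultations, prescriptions, blood-pressure measurements, and
patient/practice attributes. Patients are clustered in practices; treatment
is three-valued (no BZD, short-term incident management, long-term incident
management); prescribing is heavily confounded by indication (sleep problems
and mental stress drive both prescribing and blood pressure).

The pipeline has six stages, each an exported module:

1. **Cohort** (`build_cohort`): practice-level data-quality filters (no gap
   longer than 6 weeks in data provision over the two years ending at the
   study close; max/min annual consultation ratio below 5), one clinical
   visit per patient-day (administrative contacts dropped), regular adult
   patients (at least one consultation in each of 2016, 2017 and 2018; aged
   18+ at the start of 2016), and a new-user washout (any BZD script in 2016
   excludes the patient).
2. **Exposure** (`classify_exposure`): the first 2017 BZD episode is
   *long-term* when at least three scripts fall within 180 days of the first
   2017 script *and* the second distinct script date is more than 28 days
   after it; the episode then accrues scripts while successive gaps stay
   below 180 days (possibly into 2018). Every other 2017 starter is
   *short-term*. Long-term episodes are subclassified by elimination
   half-life (long-acting > 24 h: diazepam, nitrazepam, clonazepam,
   clobazam, flunitrazepam; all others, including the z-drugs, are
   short-intermediate).
3. **Outcomes** (`derive_outcomes`): baseline BP is the 2016 componentwise
   median; the outcome is the 2017 median (unexposed), the first reading at
   least 28 days after the episode start (short-term), or the episode-window
   median (long-term).
4. **Imputation** (`chained_impute`, `rubin_pool`): chained-equation
   multiple imputation of missing confounders, Rubin's-rule pooling of
   per-imputation ATEs.
5. **Estimation** (`aipw_estimate` and friends): AIPW with a
   multinomial-logit treatment model and per-level linear outcome models,
   with practice-clustered influence-function variance, plus crude and
   adjusted linear-regression comparators.
6. **Reporting** (`run_pipeline`, `write_results`): orchestration, pooled
   estimates, exclusion-flow counts, diagnostics.

# The AIPW estimator

For treatment level $t \in \{0,1,2\}$ (none, short-term, long-term), with
$\hat p_t(X_i)$ the fitted multinomial-logit probability and $\hat m_t(X_i)$
the fitted per-level linear outcome regression, the potential-outcome mean is

$$\hat\mu_t = \frac1n \sum_{i=1}^n \left[
  \frac{\mathbf 1\{T_i = t\}\,(Y_i - \hat m_t(X_i))}{\hat p_t(X_i)}
  + \hat m_t(X_i) \right],
\qquad \widehat{\mathrm{ATE}}_t = \hat\mu_t - \hat\mu_0 .$$

The reciprocal of the treatment-model probability is the weight applied to
the outcome-model residual; the estimate is consistent when either nuisance
model is correctly specified (double robustness). Both models share the full
confounder design — age group, sex, Indigenous-status category, patient and
practice IRSAD (area-level socioeconomic index) groups, rurality, smoking
category, insomnia, mental stress, diabetes, antihypertensive flags, and
baseline SBP *and* DBP (both baselines enter both outcome models); the
treatment model additionally carries the 2017 consultation count, a
predictor of prescribing but not of the outcome given the rest.

**Variance.** The per-row influence contribution for the contrast $t$ vs $0$
is $\varphi_i = a_{it} - a_{i0} - \widehat{\mathrm{ATE}}_t$ with $a_{it}$ the
bracketed term above. Contributions are summed within practices (clusters
$c = 1,\dots,G$) and

$$\widehat{se}^2 = \frac{G}{G-1}\,\frac{\sum_c \big(\sum_{i\in c}
\varphi_i\big)^2}{n^2},$$

with $t_{G-1}$ critical values for 95% intervals. The CR1 small-sample
factor and $t$ reference distribution are the standard practice for
clustered sandwich inference (and what mainstream commercial software does
with clustered SEs); in 500-replicate calibration runs at $n = 2{,}000$ they
move empirical coverage of all four contrasts into 0.93–0.96. Nuisance
gradients are deliberately ignored (plug-in influence variance): at correct
specification AIPW is its own influence function, and the plug-in version is
the conservative, conventional choice. A nonparametric practice bootstrap
would be a straightforward cross-check and is intentionally not the default
(it multiplies cost by the bootstrap size).

**Numerical choices.** The multinomial logit is fit by full Newton iteration
with the analytic block Hessian and step-halving, stopping when the
Euclidean score norm drops below $10^{-8}$; an intercept-only fit therefore
reproduces sample proportions to machine precision, and a saturated fit the
within-stratum proportions. Aliased design columns are dropped (and
recorded) by QR pivoting, in both nuisance models. Linear predictors are
clamped at $\pm 30$ before exponentiation; fitted probabilities below
$10^{-3}$ are winsorised (floored, never dropped) before weighting, with the
floored count reported — overlap trimming is configurable
(`prob_floor`) and defaults to a floor rather than row deletion so the
estimand's population is untouched.

# Multiple imputation

Baseline BP is missing for around 18% of patients in the kind of data this
package targets (a patient simply has no 2016 reading); other covariates are
missing below 1%. Outcome BP is never imputed — patients without a
qualifying outcome reading are excluded and counted, because outcome
availability is an inclusion criterion, while baseline BP is a confounder
and is imputed.

`chained_impute` cycles per-variable conditional models (default 10 sweeps;
5 are used in the large validation runs, the long-standing default of
popular chained-equation implementations, as convergence of the chain is
reached well before that for this missingness pattern): continuous variables
use predictive-mean matching (Bayesian parameter draw, 5 nearest observed
donors, so imputed blood pressures are always observed, in-range values);
binary variables a logistic draw with a normal-approximation posterior;
multi-category variables a multinomial logit refit on a bootstrap resample.
Missing cells are initialised from observed marginals; observed cells are
never altered (a cell-level diff is part of the test-suite). Predictors are
the full confounder set plus two auxiliaries: the 2017 consultation count
and practice identity. Practice identity enters as a practice-level mean of
observed baseline SBP rather than as a several-hundred-level factor — a
deliberate compromise that keeps the conditional models well-posed with many
practices. Conditional-model failures (separation, non-convergence) fall
back to marginal draws and are logged in the diagnostics, never silent.

ATEs are estimated independently within each completed dataset and pooled at
the ATE level by Rubin's rules: $\bar q$ the mean point estimate, $w$ the
mean squared SE, $b$ the between-imputation variance,
$t = w + (1 + 1/m)\,b$, degrees of freedom
$\nu = (m-1)(1 + w/((1+1/m)b))^2$ (infinite when $b = 0$, where the interval
reverts to normal quantiles). The imputation model excludes the outcome,
mirroring the confounder-plus-auxiliaries description this design follows;
under the default MCAR missingness this costs nothing, and the MAR switch in
the generator exists precisely to probe that choice.

# What the synthetic generator emulates — and what it does not

`generate_population` is first-class, tested code, not a fixture. Its
defaults are the study conditions the analysis assumes:

* practice-clustered patients (default 100 practices, Poisson-250 patients
  each; validation runs use 250 × 400 ≈ 100,000) with practice-level random
  BP intercepts (SD 3 mmHg), patient-level intercepts (SD 8 mmHg) and
  measurement noise (SD 6 mmHg, DBP scaled to 60%);
* marginal exposure incidences calibrated numerically to 3.2% (short-term)
  and 0.5% (long-term) — class intercepts are solved by fixed-point
  iteration against the simulated confounder distribution, and infeasible
  targets are reported with the achieved rates;
* confounders that shift both prescribing log-odds (scaled by
  `confounding_strength`) and blood pressure: insomnia, mental stress, age,
  smoking, antihypertensive treatment, diabetes, and the *recorded* 2016
  median BP. Assignment conditions on the recorded baseline (what a
  prescriber sees), so a treatment model adjusting for measured baseline BP
  is correctly specified by construction;
* script streams built to realise the assigned class under the episode
  rules (a round-trip test demands at least 99% agreement; in practice it is
  100% up to rare boundary collisions), including same-day duplicates,
  administrative contacts, prior users, under-age patients, and
  data-provision defects that give every cohort filter real work;
* treatment effects injected into outcome-window readings only — baseline
  2016 BP is never affected, preserving the temporal ordering of the
  design; optional effect modification at age 65+ and per half-life
  subclass;
* missingness: baseline BP deleted for 18.4% of patients (MCAR by default;
  a MAR switch makes deletion depend on age and exposure at the same
  marginal rate), sparse (0.5%) deletion in smoking/IRSAD/Indigenous-status
  cells, and 59% missing BMI.

Dates live on a plain day grid over 2016-01-01..2018-12-31 — no time zones,
no calendar conventions beyond day arithmetic.

What it does **not** emulate: drug dose or days-supply (the data this
mirrors has none), free-text clinical notes, within-patient BP trends or
autocorrelation beyond a constant patient intercept (the intercept SD is a
parameter, not an assertion), visit-process dependence on BP, and
cross-practice record linkage. Passing recovery tests therefore show the
estimator handles confounded assignment, clustering and missingness of the
planted form — not that real prescribing data meets those assumptions.

# Validation design

The test-suite ties every stage to an independent oracle:

* **Saturated collapse**: with one binary covariate and saturated nuisance
  models, AIPW must equal the stratified g-formula estimate and a
  hand-evaluated application of the $\hat\mu_t$ formula to $10^{-10}$.
* **Double robustness**: at $n = 20{,}000$ with a confounder shifting SBP by
  5 mmHg and treatment log-odds by 1, the long-term SBP bias averaged over
  100 replicates must stay below 0.15 mmHg when either nuisance model omits
  the confounder, while omitting it from both must leave more than
  0.5 mmHg bias.
* **Coverage**: 95% intervals must cover truth in 93–97% of 500 replicates
  at $n = 2{,}000$ for both contrasts and both outcomes.
* **End-to-end recovery**: a 100,000-patient population with planted effects
  (+0.4/+0.5 short-term SBP/DBP; −1.1 SBP long-term; −2.5/−1.0 at 65+),
  18% missing baseline BP and $m = 5$ imputations must return pooled
  estimates within two SEs of the planted truth and reproduce the
  effect-modification sign pattern. (The planted values are inspired by the
  magnitudes this class of study reports; they are conditions of the
  simulation, not claims about any dataset.)
* **Cluster variance**: the clustered SEs must match direct cluster-sum
  sandwich oracles to $10^{-8}$ on a 5-cluster fixture, and a planted
  practice random effect must inflate clustered over naive SEs on average.
* **Determinism**: identical configuration and seed must reproduce
  `estimates.csv` byte for byte.

Problem sizes in the routine suite (tens of practices, a few hundred
patients each) are chosen so the whole battery, including the
100,000-patient recovery run, completes in minutes on one CPU; the
validation conclusions are insensitive to scaling the routine sizes up.

# Design choices where the design was genuinely open

* *Age reference date*: age is computed at 2016-01-01 from year of birth.
* *Gap rule window*: the practice gap/ratio rules are assessed over
  2017–2018 (the 24 months ending at the study close); configurable.
* *Rule boundaries*: "after 28 days" is strict (> 28); "within 180 days"
  inclusive; an episode-terminating gap is ≥ 180 days. All three are
  arguments with these defaults, since prose statements of such rules are
  rarely airtight; the same-day-duplicate convention (one date for the
  28-day test, all rows retained) treats duplicates as recording artifacts.
* *First episode only*: a patient whose first 2017 episode is short-term is
  never reassigned by later activity.
* *Componentwise medians*: SBP and DBP medians are taken independently, not
  as a jointly selected visit; even counts use the midpoint.
* *Multi-valued treatment in one model*: a single 3-level multinomial fit
  (and a single 4-level fit for the half-life analysis, which drops
  short-term rows), not separate binary fits.
* *Reference categories*: the first listed level of every categorical
  confounder is the reference; the coding is fixed in
  `bzdbp:::.factor_specs`.
* *BMI*: heavily missing in routine records, so it only enters the
  dedicated sensitivity analysis, with imputed BMI as the default flavour.

# Known limitations

Nuisance models are parametric (no machine-learning nuisances or
cross-fitting); treatment is a single incident episode, not a time-varying
regime; the imputation is single-level (no random-effects imputation), with
practice information reduced to a mean auxiliary; the generator's
missingness mechanisms are MCAR/MAR only — MNAR sensitivity is out of
scope; and the unexposed outcome window is the calendar year, so unexposed
patients have no index date, which is inherent to the design rather than a
software choice.
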