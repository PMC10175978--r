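#' Standard confounder formulas
#'
#' The confounder design shared by the treatment and outcome models: age
#' group, sex, Indigenous-status category, patient and practice area-level
#' socioeconomic (IRSAD) groups, rurality, smoking category, insomnia,
#' mental stress, diabetes and antihypertensive flags, and baseline SBP and
#' DBP (both baselines enter both outcome models). The treatment model
#' additionally carries the exposure-year consultation count, which is a
#' predictor of being prescribed but not a confounder of the outcome.
#'
#' @param include_bmi add BMI to both models (sensitivity analyses only).
#' @return List with \code{ps} (treatment-model RHS), \code{om}
#'   (outcome-model RHS) and \code{confounders} (character vector).
#' @export
analysis_formulas <- function(include_bmi = FALSE) {
  conf <- c("age_group", "sex", "indigenous_status", "patient_irsad",
            "practice_irsad", "rurality", "smoking", "insomnia",
            "mental_stress", "diabetes", "antihypertensive",
            "baseline_sbp", "baseline_dbp")
  if (include_bmi) conf <- c(conf, "bmi")
  list(ps = stats::reformulate(c(conf, "n_consults_2017")),
       om = stats::reformulate(conf),
       confounders = conf)
}

.factor_specs <- list(
  age_group = c("18-34", "35-49", "50-64", "65-74", "75plus"),
  sex = c("female", "male"),
  indigenous_status = c("no", "yes", "not_stated"),
  patient_irsad = c("advantaged", "middle", "disadvantaged"),
  practice_irsad = c("advantaged", "middle", "disadvantaged"),
  rurality = c("major_city", "inner_regional", "outer_remote"),
  smoking = c("nonsmoker", "smoker", "ex_smoker", "not_stated")
)

#' Assemble estimation-ready analysis rows
#'
#' Joins the cohort, exposure classification, derived outcomes, patient
#' attributes and exposure-year consultation counts into one row per
#' patient, with every categorical confounder coded as a factor with a
#' fixed, documented reference level (the first listed). Patients with a
#' missing outcome BP are dropped (outcome BP is an inclusion criterion,
#' never imputed) and counted.
#'
#' @param cohort a \code{\link{build_cohort}} result.
#' @param episodes a \code{\link{classify_exposure}} table.
#' @param outcomes a \code{\link{derive_outcomes}} table.
#' @param attributes the raw attribute table.
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame of analysis rows; attribute \code{"n_missing_outcome"}
#'   counts the dropped patients.
#' @export
build_analysis_rows <- function(cohort, episodes, outcomes, attributes,
                                config = cohort_config()) {
  stopifnot(inherits(cohort, "bzd_cohort"))
  ids <- cohort$patient_ids
  at <- attributes[match(ids, as.character(attributes$patient_id)), ,
                   drop = FALSE]
  ep <- episodes[match(ids, as.character(episodes$patient_id)), ,
                 drop = FALSE]
  ou <- outcomes[match(ids, as.character(outcomes$patient_id)), ,
                 drop = FALSE]
  age <- config$baseline_year - at$birth_year
  rows <- data.frame(
    patient_id = ids,
    practice_id = as.character(at$practice_id),
    treatment = factor(ifelse(is.na(ep$klass), "none", ep$klass),
                       levels = c("none", "short_term", "long_term")),
    half_life_subclass = ep$half_life_subclass,
    age = age,
    age_group = cut(age, c(18, 35, 50, 65, 75, Inf), right = FALSE,
                    labels = .factor_specs$age_group),
    age_band = factor(ifelse(age >= 65, "65plus", "18-64"),
                      levels = c("18-64", "65plus")),
    stringsAsFactors = FALSE
  )
  for (v in c("sex", "indigenous_status", "patient_irsad", "practice_irsad",
              "rurality", "smoking"))
    rows[[v]] <- factor(at[[v]], levels = .factor_specs[[v]])
  for (v in c("insomnia", "mental_stress", "diabetes", "antihypertensive",
              "sleep_apnea"))
    rows[[v]] <- at[[v]]
  rows$bmi <- at$bmi
  rows$baseline_sbp <- ou$baseline_sbp
  rows$baseline_dbp <- ou$baseline_dbp
  rows$outcome_sbp <- ou$outcome_sbp
  rows$outcome_dbp <- ou$outcome_dbp

  visits <- cohort$consultations
  yr <- as.integer(format(as.Date(visits$date), "%Y"))
  cnt <- table(as.character(visits$patient_id)[yr == config$exposure_year])
  rows$n_consults_2017 <- as.integer(cnt[rows$patient_id])
  rows$n_consults_2017[is.na(rows$n_consults_2017)] <- 0L

  keep <- !is.na(rows$outcome_sbp) & !is.na(rows$outcome_dbp)
  structure(rows[keep, , drop = FALSE],
            n_missing_outcome = sum(!keep))
}

# fit the treatment model once, then AIPW (and optional comparators)
# for several outcomes of the same rows
.aipw_multi <- function(rows, ps_formula, om_formula,
                        outcomes = c("outcome_sbp", "outcome_dbp"),
                        treatment = "treatment", cluster = "practice_id",
                        comparators = FALSE, prob_floor = 0.001) {
  ps <- fit_multinomial_logit(
    stats::update(ps_formula, paste(treatment, "~ .")), rows)
  est <- lapply(outcomes, function(oc) {
    om <- fit_outcome_models(rows, om_formula, oc, treatment)
    e <- aipw_ate(rows, ps, om, oc, treatment, cluster, prob_floor)
    if (comparators)
      e <- rbind(e, ols_comparators(rows, om_formula, oc, treatment,
                                    cluster))
    e
  })
  out <- do.call(rbind, est)
  attr(out, "propensity_diagnostics") <-
    list(converged = ps$converged, iterations = ps$iterations,
         score_norm = ps$score_norm, separation = ps$separation,
         dropped = ps$dropped)
  out
}

#' Long-term half-life subclass sensitivity analysis
#'
#' Re-estimates the long-term contrasts with the long-term arm split by
#' drug half-life subclass: a four-level treatment (none /
#' short-intermediate only / long-acting only / mixed) fit with a single
#' multinomial treatment model. Short-term patients are excluded from this
#' contrast. Subclasses with fewer than \code{min_subclass} patients are
#' reported with a small-sample warning; subclasses with no patients are
#' dropped from the treatment factor.
#'
#' @param rows analysis rows (must carry \code{half_life_subclass}).
#' @param ps_formula,om_formula model formulas (see
#'   \code{\link{analysis_formulas}}).
#' @param outcomes outcome column names.
#' @param cluster,prob_floor see \code{\link{aipw_ate}}.
#' @param min_subclass small-sample warning threshold (default 50).
#' @return \code{ate_estimates} data.frame (levels are the subclasses);
#'   attribute \code{"warnings"} lists small or empty subclasses.
#' @export
half_life_sensitivity <- function(rows, ps_formula, om_formula,
                                  outcomes = c("outcome_sbp", "outcome_dbp"),
                                  cluster = "practice_id",
                                  prob_floor = 0.001, min_subclass = 50) {
  rows <- rows[rows$treatment != "short_term", , drop = FALSE]
  sub <- ifelse(rows$treatment == "none", "none", rows$half_life_subclass)
  lv <- c("none", "short_intermediate_only", "long_acting_only", "mixed")
  present <- lv[lv %in% unique(sub)]
  warns <- character(0)
  for (s in setdiff(lv[-1L], present))
    warns <- c(warns, sprintf("subclass %s: no patients, skipped", s))
  tab <- table(sub)
  for (s in intersect(lv[-1L], present))
    if (tab[[s]] < min_subclass)
      warns <- c(warns, sprintf("subclass %s: only %d patients", s,
                                tab[[s]]))
  rows$treatment4 <- factor(sub, levels = present)
  est <- .aipw_multi(rows, ps_formula, om_formula, outcomes,
                     treatment = "treatment4", cluster = cluster,
                     prob_floor = prob_floor)
  attr(est, "warnings") <- warns
  est
}

#' Flag-exclusion sensitivity analysis
#'
#' Repeats the overall AIPW analysis on the subset of patients without a
#' given flag (canonically diagnosed obstructive sleep apnea). When the
#' flag column is absent, or no rows remain, the analysis is skipped with
#' a recorded reason.
#'
#' @param rows analysis rows.
#' @param flag flag column name (default \code{"sleep_apnea"}).
#' @inheritParams half_life_sensitivity
#' @return \code{ate_estimates} data.frame, or \code{NULL} with attribute
#'   \code{"skip_reason"} when not computable.
#' @export
exclusion_sensitivity <- function(rows, flag = "sleep_apnea", ps_formula,
                                  om_formula,
                                  outcomes = c("outcome_sbp", "outcome_dbp"),
                                  cluster = "practice_id",
                                  prob_floor = 0.001) {
  if (!flag %in% names(rows))
    return(structure(list(), skip_reason = paste("flag column absent:",
                                                 flag)))
  keep <- is.na(rows[[flag]]) | rows[[flag]] == 0
  sub <- rows[keep, , drop = FALSE]
  if (nrow(sub) == 0L || length(unique(sub$treatment)) < 3L)
    return(structure(list(),
                     skip_reason = "no (or degenerate) rows after exclusion"))
  .aipw_multi(sub, ps_formula, om_formula, outcomes, cluster = cluster,
              prob_floor = prob_floor)
}

# Rubin-pool a list of per-imputation ate_estimates tables
.pool_estimates <- function(per_imp) {
  m <- length(per_imp)
  stacked <- do.call(rbind, per_imp)
  key_cols <- intersect(c("level", "outcome", "estimator", "stratum"),
                        names(stacked))
  key <- do.call(paste, c(stacked[key_cols], sep = "\r"))
  out <- lapply(unique(key), function(k) {
    s <- stacked[key == k, , drop = FALSE]
    pe <- rubin_pool(s$ate, s$se^2)
    cbind(s[1L, key_cols, drop = FALSE],
          data.frame(ate = pe$qbar, se = pe$se, ci_lo = pe$ci95[1],
                     ci_hi = pe$ci95[2], df = pe$df, m = m, n = s$n[1L]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full estimation pipeline
#'
#' Orchestrates every stage: synthetic generation (or user tables), cohort
#' filters, incident-episode classification, outcome-window derivation,
#' chained-equation imputation, AIPW estimation with crude/adjusted OLS
#' comparators inside each completed dataset, Rubin pooling, and the
#' requested stratified and sensitivity analyses. Deterministic given the
#' configuration and seed.
#'
#' @param synth a \code{\link{synth_config}} (ignored when \code{tables}
#'   is supplied).
#' @param tables optional list with \code{consultations},
#'   \code{prescriptions}, \code{bp}, \code{attributes} (file mode).
#' @param cohort a \code{\link{cohort_config}}.
#' @param vocab a \code{\link{bzd_vocabulary}}.
#' @param impute an \code{\link{imputation_spec}}.
#' @param analyses subset of \code{"overall"}, \code{"age_stratified"},
#'   \code{"half_life"}, \code{"bmi_adjusted"},
#'   \code{"sleep_apnea_exclusion"}, \code{"complete_case"}.
#' @param prob_floor propensity winsorisation floor.
#' @param seed root seed for the imputation draws (the generator uses the
#'   seed inside \code{synth}).
#' @return A list of class \code{results_bundle}: \code{estimates}
#'   (pooled, one row per analysis x outcome x level x estimator),
#'   \code{flow} (telescoping exclusion counts), \code{incidence}
#'   (realised exposure-class proportions), \code{diagnostics},
#'   \code{analysis_patient_ids} (patients entering estimation), and, in
#'   synthetic mode, \code{truth} (the generator's per-patient ground
#'   truth, for recovery checks).
#' @export
run_pipeline <- function(synth = synth_config(), tables = NULL,
                         cohort = cohort_config(),
                         vocab = bzd_vocabulary(),
                         impute = imputation_spec(),
                         analyses = "overall",
                         prob_floor = 0.001, seed = NULL) {
  ok <- c("overall", "age_stratified", "half_life", "bmi_adjusted",
          "sleep_apnea_exclusion", "complete_case")
  stopifnot(all(analyses %in% ok), length(analyses) >= 1L)
  truth <- NULL
  if (is.null(tables)) {
    pop <- generate_population(synth)
    tables <- pop[c("consultations", "prescriptions", "bp", "attributes")]
    truth <- pop$truth
    if (is.null(seed)) seed <- synth$seed
  }
  if (is.null(seed)) seed <- 1L

  coh <- build_cohort(tables$consultations, tables$prescriptions,
                      tables$attributes, cohort, vocab)
  rx <- tables$prescriptions
  rx <- rx[as.character(rx$patient_id) %in% coh$patient_ids, , drop = FALSE]
  episodes <- classify_exposure(rx, patient_ids = coh$patient_ids,
                                vocab = vocab,
                                exposure_year = cohort$exposure_year)
  outc <- derive_outcomes(tables$bp, episodes,
                          patient_ids = coh$patient_ids,
                          baseline_year = cohort$baseline_year,
                          exposure_year = cohort$exposure_year)
  rows <- build_analysis_rows(coh, episodes, outc, tables$attributes,
                              cohort)
  flow <- rbind(coh$flow,
                data.frame(step = "with_outcome_bp", n = nrow(rows)))
  incidence <- c(short = mean(rows$treatment == "short_term"),
                 long = mean(rows$treatment == "long_term"))

  need_bmi <- "bmi_adjusted" %in% analyses
  fml <- analysis_formulas(include_bmi = FALSE)
  fml_bmi <- analysis_formulas(include_bmi = TRUE)

  # practice identity informs the imputation model through a practice-level
  # mean of observed baseline SBP (numeric auxiliary; robust to many
  # practices)
  pm <- tapply(rows$baseline_sbp, rows$practice_id,
               function(z) mean(z, na.rm = TRUE))
  pm[!is.finite(pm)] <- mean(rows$baseline_sbp, na.rm = TRUE)
  rows$practice_mean_bsbp <- as.numeric(pm[rows$practice_id])

  imp_cols <- c(fml$confounders, "n_consults_2017", "practice_mean_bsbp")
  if (need_bmi) imp_cols <- union(imp_cols, "bmi")
  predictors <- setdiff(imp_cols, "bmi")
  completed_cov <- chained_impute(rows[imp_cols], spec = impute,
                                  predictors = predictors, seed = seed)
  completed <- lapply(completed_cov, function(d) {
    r <- rows
    r[imp_cols] <- d
    r
  })

  diag <- list(imputation_events = attr(completed_cov, "events"),
               skipped = list(), warnings = list(),
               n_missing_outcome = attr(rows, "n_missing_outcome"),
               practice_exclusions = coh$practice_exclusions)
  res <- list()

  if ("overall" %in% analyses) {
    per <- lapply(completed, .aipw_multi, ps_formula = fml$ps,
                  om_formula = fml$om, comparators = TRUE,
                  prob_floor = prob_floor)
    diag$propensity <- attr(per[[1L]], "propensity_diagnostics")
    est <- .pool_estimates(per)
    est <- cbind(analysis = "overall", stratum = "all", est)
    res$overall <- est
  }
  if ("age_stratified" %in% analyses) {
    per <- lapply(completed, function(d) {
      parts <- lapply(levels(d$age_band), function(b) {
        sub <- d[d$age_band == b, , drop = FALSE]
        if (length(unique(sub$treatment)) < nlevels(d$treatment)) {
          diag$skipped[[paste0("age_stratified:", b)]] <<-
            "missing treatment level in stratum"
          return(NULL)
        }
        e <- .aipw_multi(sub, fml$ps, fml$om, prob_floor = prob_floor)
        e$stratum <- b
        e
      })
      do.call(rbind, parts)
    })
    if (!is.null(per[[1L]]))
      res$age_stratified <- cbind(analysis = "age_stratified",
                                  .pool_estimates(per))
  }
  if ("half_life" %in% analyses) {
    per <- lapply(completed, half_life_sensitivity, ps_formula = fml$ps,
                  om_formula = fml$om, prob_floor = prob_floor)
    diag$warnings$half_life <- attr(per[[1L]], "warnings")
    res$half_life <- cbind(analysis = "half_life", stratum = "all",
                           .pool_estimates(per))
  }
  if ("bmi_adjusted" %in% analyses) {
    per <- lapply(completed, .aipw_multi, ps_formula = fml_bmi$ps,
                  om_formula = fml_bmi$om, prob_floor = prob_floor)
    res$bmi_adjusted <- cbind(analysis = "bmi_adjusted", stratum = "all",
                              .pool_estimates(per))
  }
  if ("sleep_apnea_exclusion" %in% analyses) {
    per <- lapply(completed, exclusion_sensitivity, flag = "sleep_apnea",
                  ps_formula = fml$ps, om_formula = fml$om,
                  prob_floor = prob_floor)
    if (!is.null(attr(per[[1L]], "skip_reason"))) {
      diag$skipped$sleep_apnea_exclusion <- attr(per[[1L]], "skip_reason")
    } else {
      res$sleep_apnea_exclusion <- cbind(analysis = "sleep_apnea_exclusion",
                                         stratum = "all",
                                         .pool_estimates(per))
    }
  }
  if ("complete_case" %in% analyses) {
    cc <- rows[stats::complete.cases(rows[fml$confounders]), , drop = FALSE]
    if (length(unique(cc$treatment)) == nlevels(rows$treatment)) {
      e <- .aipw_multi(cc, fml$ps, fml$om, comparators = TRUE,
                       prob_floor = prob_floor)
      est <- data.frame(analysis = "complete_case", stratum = "all",
                        level = e$level, outcome = e$outcome,
                        estimator = e$estimator, ate = e$ate, se = e$se,
                        ci_lo = e$ci_lo, ci_hi = e$ci_hi, df = Inf,
                        m = 1L, n = e$n)
      res$complete_case <- est
    } else {
      diag$skipped$complete_case <- "missing treatment level in complete cases"
    }
  }

  estimates <- do.call(rbind, res)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, flow = flow,
                 incidence = incidence, diagnostics = diag,
                 truth = truth, analysis_patient_ids = rows$patient_id,
                 seed = seed),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>", nrow(x$estimates), "pooled estimates;",
      sprintf("incidence short %.2f%%, long %.2f%%\n",
              100 * x$incidence[["short"]], 100 * x$incidence[["long"]]))
  print(utils::head(x$estimates[x$estimates$estimator == "aipw", ], 12),
        row.names = FALSE)
  invisible(x)
}

#' Serialise a results bundle
#'
#' Writes \code{estimates.csv} (flat table of pooled estimates),
#' \code{flow.json} (exclusion cascade) and \code{diagnostics.json}.
#'
#' @param bundle a \code{\link{run_pipeline}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- bundle$estimates
  est$df <- ifelse(is.infinite(est$df), 1e9, est$df)
  utils::write.csv(format(est, digits = 10), file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$flow, file.path(dir, "flow.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(list(incidence = as.list(bundle$incidence),
                            diagnostics = bundle$diagnostics,
                            seed = bundle$seed),
                       file.path(dir, "diagnostics.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}
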