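#' Synthetic-population settings
#'
#' Parameters of the synthetic primary-care EHR generator. Defaults emulate
#' the statistical structure the estimation pipeline assumes: practice-
#' clustered patients attending over 2016-2018, incident short- and
#' long-term BZD management at marginal incidences of roughly 3.2\% and
#' 0.5\%, confounders (sleep problems, mental stress, age, smoking,
#' antihypertensive treatment, diabetes, recorded baseline BP) that shift
#' both the treatment log-odds and blood pressure, additive treatment
#' effects on outcome-window BP of +0.4/+0.5 mmHg (short-term SBP/DBP) and
#' -1.1/-0.1 mmHg (long-term), and 18.4\% missingness in baseline BP with
#' sparse (<1\%) missingness in other covariates.
#'
#' @param n_practices number of general practices.
#' @param patients_per_practice mean of the per-practice Poisson patient
#'   count.
#' @param true_ate_short_sbp,true_ate_short_dbp,true_ate_long_sbp,true_ate_long_dbp
#'   additive causal effects (mmHg) of each exposure class on
#'   outcome-window BP.
#' @param true_ate_long_sbp_65plus,true_ate_long_dbp_65plus optional
#'   effect-modified long-term effects for patients aged 65+ at baseline;
#'   when \code{NULL} the overall long-term effect applies at all ages.
#' @param confounding_strength unitless scalar multiplying every confounder
#'   coefficient in the treatment-assignment log-odds (0 = randomised).
#' @param practice_sd SD (mmHg) of the practice-level random intercept on
#'   SBP.
#' @param patient_sd SD (mmHg) of the patient-level random intercept on
#'   SBP.
#' @param resid_sd SD (mmHg) of measurement-level BP noise.
#' @param p_short_target,p_long_target target marginal incidences of the
#'   two exposure classes (intercepts are calibrated numerically to hit
#'   them given the confounder distribution).
#' @param miss_baseline_bp proportion of patients whose baseline-year BP
#'   readings are deleted (they then have no 2016 measurements).
#' @param miss_covariate proportion of cells deleted in smoking, patient
#'   IRSAD and Indigenous-status columns.
#' @param miss_bmi proportion of BMI cells deleted (BMI is heavily missing
#'   in routine records and only used in sensitivity analyses).
#' @param missing_mechanism \code{"MCAR"} (default) or \code{"MAR"}
#'   (baseline-BP deletion probability then depends on age and exposure,
#'   recalibrated to the same marginal rate).
#' @param regularity probability that a patient attends in all three study
#'   years (the complement lose all visits in one random year, giving the
#'   regular-patient filter work to do).
#' @param p_prior_user proportion of patients given a washout-year (2016)
#'   BZD script, to be excluded by the new-user filter.
#' @param p_gap_practice proportion of practices given a data-provision
#'   defect (a >6-week silent stretch or a skewed annual visit ratio), to
#'   be excluded by the practice filters.
#' @param p_underage proportion of patients younger than 18.
#' @param subclass_ate_sbp,subclass_ate_dbp optional named numeric vectors
#'   (names among \code{short_intermediate_only}, \code{long_acting_only},
#'   \code{mixed}) overriding the long-term effect by realised half-life
#'   subclass.
#' @param seed integer seed; identical config + seed reproduces the tables
#'   byte for byte.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_practices = 100, patients_per_practice = 250,
                         true_ate_short_sbp = 0.4, true_ate_short_dbp = 0.5,
                         true_ate_long_sbp = -1.1, true_ate_long_dbp = -0.1,
                         true_ate_long_sbp_65plus = NULL,
                         true_ate_long_dbp_65plus = NULL,
                         confounding_strength = 1,
                         practice_sd = 3, patient_sd = 8, resid_sd = 6,
                         p_short_target = 0.032, p_long_target = 0.005,
                         miss_baseline_bp = 0.184, miss_covariate = 0.005,
                         miss_bmi = 0.59,
                         missing_mechanism = c("MCAR", "MAR"),
                         regularity = 0.93, p_prior_user = 0.015,
                         p_gap_practice = 0.03, p_underage = 0.02,
                         subclass_ate_sbp = NULL, subclass_ate_dbp = NULL,
                         seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_practices >= 1, patients_per_practice >= 1,
            practice_sd > 0, patient_sd > 0, resid_sd > 0,
            p_short_target > 0, p_short_target < 1,
            p_long_target > 0, p_long_target < 1,
            p_short_target + p_long_target < 1,
            miss_baseline_bp >= 0, miss_baseline_bp < 1,
            miss_covariate >= 0, miss_covariate < 1,
            regularity > 0, regularity <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_practices, "practices x ~",
      x$patients_per_practice, "patients; targets",
      sprintf("%.1f%%/%.1f%%", 100 * x$p_short_target,
              100 * x$p_long_target),
      "short/long; seed", x$seed, "\n")
  invisible(x)
}

.year_start <- function(y) as.Date(sprintf("%d-01-01", y))
.rcat <- function(n, levels, prob) levels[sample.int(length(levels), n,
                                                     replace = TRUE,
                                                     prob = prob)]

# drug-mix probabilities follow the observed script shares of each class
.BZD_SHORT_PROBS <- c(temazepam = 0.397, diazepam = 0.388, oxazepam = 0.077,
                      nitrazepam = 0.011, alprazolam = 0.017,
                      lorazepam = 0.025, clonazepam = 0.013,
                      flunitrazepam = 0.001, clobazam = 0.001,
                      bromazepam = 0.002, zolpidem = 0.030,
                      zopiclone = 0.033)
.BZD_LONG_PROBS <- c(temazepam = 0.329, diazepam = 0.311, oxazepam = 0.134,
                     nitrazepam = 0.027, alprazolam = 0.028,
                     lorazepam = 0.033, clonazepam = 0.012,
                     flunitrazepam = 0.001, clobazam = 0.001,
                     bromazepam = 0.002, zolpidem = 0.042,
                     zopiclone = 0.069)

#' Generate a synthetic practice-clustered EHR population
#'
#' Draws practices, patients, consultation streams, BZD and non-BZD
#' prescription streams, and repeated blood-pressure measurements so that
#' (i) exposed patients' script patterns realise their assigned class under
#' the incident-episode rules, (ii) the configured confounders shift both
#' treatment assignment and BP, (iii) treatment effects are injected into
#' outcome-window BP only (baseline-year BP is never affected), and (iv)
#' baseline-BP and covariate cells are deleted at the configured rates.
#' Treatment assignment conditions on the \emph{recorded} 2016 median BP
#' (what a prescriber sees), so the downstream treatment model that adjusts
#' for measured baseline BP is correctly specified.
#'
#' Class intercepts are calibrated numerically to the target incidences
#' given the simulated confounder distribution; if the achieved marginal
#' rates end up more than 20\% (relative) away from target a warning
#' reports the achieved rates.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A list of class \code{bzd_population}: \code{consultations},
#'   \code{prescriptions}, \code{bp}, \code{attributes} (data.frames),
#'   \code{truth} (per-patient ground truth: latent treatment-free outcome
#'   BP, assigned class, realised causal effects, prior-user flag) and
#'   \code{config}.
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cf <- config

  ## practices -------------------------------------------------------------
  n_pr <- cf$n_practices
  practice_id <- sprintf("pr%04d", seq_len(n_pr))
  rurality <- .rcat(n_pr, c("major_city", "inner_regional", "outer_remote"),
                    c(0.58, 0.28, 0.14))
  practice_irsad <- .rcat(n_pr, c("advantaged", "middle", "disadvantaged"),
                          c(0.40, 0.24, 0.36))
  prac_int <- stats::rnorm(n_pr, 0, cf$practice_sd)
  defect <- stats::runif(n_pr) < cf$p_gap_practice
  defect_kind <- ifelse(defect & stats::runif(n_pr) < 0.5, "gap", "ratio")
  defect_kind[!defect] <- "none"

  ## patients --------------------------------------------------------------
  n_per <- pmax(1L, stats::rpois(n_pr, cf$patients_per_practice))
  n <- sum(n_per)
  prac_of <- rep(seq_len(n_pr), n_per)
  patient_id <- sprintf("pt%07d", seq_len(n))

  underage <- stats::runif(n) < cf$p_underage
  age <- ifelse(underage, sample(10:17, n, replace = TRUE),
                pmin(pmax(round(stats::rnorm(n, 59, 17)), 18), 95))
  sex <- .rcat(n, c("male", "female"), c(0.423, 0.577))
  indigenous <- .rcat(n, c("no", "yes", "not_stated"),
                      c(0.81, 0.017, 0.173))
  patient_irsad <- .rcat(n, c("advantaged", "middle", "disadvantaged"),
                         c(0.394, 0.237, 0.369))
  smoking <- .rcat(n, c("nonsmoker", "smoker", "ex_smoker", "not_stated"),
                   c(0.566, 0.097, 0.291, 0.046))
  insomnia <- stats::runif(n) < stats::plogis(-3.6 + 0.012 * (age - 59))
  stress <- stats::runif(n) < stats::plogis(-2.1)
  diabetes <- stats::runif(n) < stats::plogis(-2.6 + 0.03 * (age - 59))
  aht <- stats::runif(n) < stats::plogis(-0.2 + 0.06 * (age - 59))
  apnea <- stats::runif(n) < 0.012
  bmi <- pmin(pmax(stats::rnorm(n, 28, 5.5), 15), 60)
  lam_visit <- exp(1.05 + 0.25 * aht + 0.25 * diabetes + 0.35 * stress +
                     0.2 * insomnia + 0.008 * (age - 59))

  ## latent blood pressure -------------------------------------------------
  pat_int <- stats::rnorm(n, 0, cf$patient_sd)
  sbp_lat <- 128 + 0.30 * (age - 59) + 4 * aht + 2 * diabetes +
    2 * (smoking == "smoker") + 1 * (smoking == "ex_smoker") +
    1.5 * (sex == "male") + prac_int[prac_of] + pat_int
  dbp_lat <- 52 + 0.19 * sbp_lat - 0.10 * (age - 59) +
    0.5 * prac_int[prac_of] + stats::rnorm(n, 0, 4)

  ## baseline-year BP readings (before any treatment) ----------------------
  k16 <- 1L + stats::rpois(n, 1.3)
  bp16 <- data.frame(
    patient_id = rep(patient_id, k16),
    date = .year_start(2016) + sample.int(365, sum(k16), replace = TRUE) - 1L,
    sbp = rep(sbp_lat, k16) + stats::rnorm(sum(k16), 0, cf$resid_sd),
    dbp = rep(dbp_lat, k16) + stats::rnorm(sum(k16), 0, 0.6 * cf$resid_sd),
    stringsAsFactors = FALSE
  )
  b_sbp_obs <- unname(tapply(bp16$sbp, bp16$patient_id,
                             stats::median)[patient_id])

  ## treatment assignment (confounded multinomial) -------------------------
  xlin_short <- cf$confounding_strength *
    (1.9 * insomnia + 1.2 * stress + 0.35 * (age >= 65) +
       0.25 * (smoking == "smoker") + 0.30 * aht + 0.15 * diabetes -
       0.01 * (b_sbp_obs - 131))
  xlin_long <- cf$confounding_strength *
    (2.7 * insomnia + 1.6 * stress + 0.55 * (age >= 65) +
       0.55 * (smoking == "smoker") + 0.40 * aht + 0.25 * diabetes -
       0.015 * (b_sbp_obs - 131))
  a1 <- stats::qlogis(cf$p_short_target)
  a2 <- stats::qlogis(cf$p_long_target)
  for (i in 1:40) {
    e1 <- exp(a1 + xlin_short); e2 <- exp(a2 + xlin_long)
    den <- 1 + e1 + e2
    a1 <- a1 + log(cf$p_short_target / mean(e1 / den))
    a2 <- a2 + log(cf$p_long_target / mean(e2 / den))
  }
  e1 <- exp(a1 + xlin_short); e2 <- exp(a2 + xlin_long)
  den <- 1 + e1 + e2
  p1 <- e1 / den; p2 <- e2 / den
  if (abs(mean(p1) - cf$p_short_target) / cf$p_short_target > 0.2 ||
      abs(mean(p2) - cf$p_long_target) / cf$p_long_target > 0.2)
    warning(sprintf(
      "incidence targets infeasible under this confounding: achieved %.4f / %.4f",
      mean(p1), mean(p2)))
  u <- stats::runif(n)
  klass <- ifelse(u < p2, "long_term",
                  ifelse(u < p1 + p2, "short_term", "none"))
  prior_user <- stats::runif(n) < cf$p_prior_user

  ## realised causal effects ------------------------------------------------
  eff_long_sbp <- rep(cf$true_ate_long_sbp, n)
  eff_long_dbp <- rep(cf$true_ate_long_dbp, n)
  if (!is.null(cf$true_ate_long_sbp_65plus))
    eff_long_sbp[age >= 65] <- cf$true_ate_long_sbp_65plus
  if (!is.null(cf$true_ate_long_dbp_65plus))
    eff_long_dbp[age >= 65] <- cf$true_ate_long_dbp_65plus

  ## BZD scripts -----------------------------------------------------------
  short_ids <- which(klass == "short_term")
  long_ids <- which(klass == "long_term")
  rx <- list()
  subclass_planted <- rep(NA_character_, n)

  if (length(short_ids)) {
    # patterns that can never satisfy the long-term rule
    pat <- sample(1:3, length(short_ids), replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
    start <- sample.int(365, length(short_ids), replace = TRUE) - 1L
    drug1 <- .rcat(length(short_ids), names(.BZD_SHORT_PROBS),
                   .BZD_SHORT_PROBS)
    d0 <- .year_start(2017) + start
    rx$short1 <- data.frame(patient = short_ids, date = d0, drug = drug1)
    two <- pat >= 2
    if (any(two))  # a second script never makes an episode long-term
      rx$short2 <- data.frame(patient = short_ids[two],
                              date = d0[two] + sample(5:170, sum(two),
                                                      replace = TRUE),
                              drug = drug1[two])
    three <- pat == 3
    if (any(three)) {
      # three scripts but second distinct date within 28 days -> short-term
      g1 <- sample(3:28, sum(three), replace = TRUE)
      g2 <- g1 + sample(5:120, sum(three), replace = TRUE)
      rx$short2b <- data.frame(patient = short_ids[three],
                               date = d0[three] + g1, drug = drug1[three])
      rx$short3 <- data.frame(patient = short_ids[three],
                              date = d0[three] + g2, drug = drug1[three])
    }
    # keep the two-script patterns short: pattern 2 second gap may exceed 28
    # days, which with only 2 scripts in the 180-day window is still short
  }
  ep_start <- rep(as.Date(NA), n); ep_end <- rep(as.Date(NA), n)
  if (length(short_ids)) ep_start[short_ids] <- rx$short1$date

  if (length(long_ids)) {
    nl <- length(long_ids)
    start <- sample.int(365, nl, replace = TRUE) - 1L
    d0 <- .year_start(2017) + start
    g2 <- sample(29:85, nl, replace = TRUE)
    g3 <- g2 + mapply(function(g) sample(7:(175 - g), 1L), g2)
    # 1 or 2 distinct drugs per long-term patient
    two_drugs <- stats::runif(nl) < 0.45
    dA <- .rcat(nl, names(.BZD_LONG_PROBS), .BZD_LONG_PROBS)
    dB <- ifelse(two_drugs, .rcat(nl, names(.BZD_LONG_PROBS),
                                  .BZD_LONG_PROBS), dA)
    longs <- vector("list", nl)
    vocab_cls <- is_bzd(names(.BZD_LONG_PROBS))$half_life_class
    names(vocab_cls) <- names(.BZD_LONG_PROBS)
    for (i in seq_len(nl)) {
      offs <- c(0L, g2[i], g3[i])
      extra <- stats::rpois(1L, 1.5)
      last <- g3[i]
      if (extra > 0) for (e in seq_len(extra)) {
        gap <- sample(20:170, 1L)
        if (d0[i] + last + gap > as.Date("2018-12-31")) break
        last <- last + gap
        offs <- c(offs, last)
      }
      drugs <- sample(c(dA[i], dB[i]), length(offs), replace = TRUE)
      longs[[i]] <- data.frame(patient = long_ids[i], date = d0[i] + offs,
                               drug = drugs)
      cls <- unique(vocab_cls[unique(drugs)])
      subclass_planted[long_ids[i]] <-
        if (all(cls == "short_intermediate")) "short_intermediate_only"
        else if (all(cls == "long_acting")) "long_acting_only" else "mixed"
      ep_start[long_ids[i]] <- d0[i]
      ep_end[long_ids[i]] <- d0[i] + last
    }
    rx$long <- do.call(rbind, longs)
  }

  # subclass-specific effect overrides (optional)
  if (!is.null(cf$subclass_ate_sbp))
    for (sc in names(cf$subclass_ate_sbp))
      eff_long_sbp[!is.na(subclass_planted) & subclass_planted == sc] <-
        cf$subclass_ate_sbp[[sc]]
  if (!is.null(cf$subclass_ate_dbp))
    for (sc in names(cf$subclass_ate_dbp))
      eff_long_dbp[!is.na(subclass_planted) & subclass_planted == sc] <-
        cf$subclass_ate_dbp[[sc]]

  # washout-year scripts for prior users (excluded by the new-user filter)
  pu <- which(prior_user)
  if (length(pu))
    rx$prior <- data.frame(
      patient = pu,
      date = .year_start(2016) + sample.int(365, length(pu),
                                            replace = TRUE) - 1L,
      drug = .rcat(length(pu), names(.BZD_SHORT_PROBS), .BZD_SHORT_PROBS))

  # non-BZD background scripts
  k_other <- stats::rpois(n, 1) + aht
  oth <- which(k_other > 0)
  rx$other <- data.frame(
    patient = rep(oth, k_other[oth]),
    date = .year_start(2016) + sample.int(1095, sum(k_other[oth]),
                                          replace = TRUE) - 1L,
    drug = sample(c("metformin", "atorvastatin", "perindopril",
                    "sertraline", "amlodipine"), sum(k_other[oth]),
                  replace = TRUE))
  rx <- do.call(rbind, rx)
  prescriptions <- data.frame(patient_id = patient_id[rx$patient],
                              date = rx$date, drug = rx$drug,
                              stringsAsFactors = FALSE)
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$date), ]
  rownames(prescriptions) <- NULL

  ## outcome-window BP readings --------------------------------------------
  bp_parts <- list(bp16 = bp16)
  none_ids <- which(klass == "none")
  k17 <- 1L + stats::rpois(length(none_ids), 1.3)
  bp_parts$none <- data.frame(
    patient_id = rep(patient_id[none_ids], k17),
    date = .year_start(2017) + sample.int(365, sum(k17),
                                          replace = TRUE) - 1L,
    sbp = rep(sbp_lat[none_ids], k17) +
      stats::rnorm(sum(k17), 0, cf$resid_sd),
    dbp = rep(dbp_lat[none_ids], k17) +
      stats::rnorm(sum(k17), 0, 0.6 * cf$resid_sd))
  if (length(short_ids)) {
    # one pre-start reading (no effect) and one qualifying reading >= 28 d
    pre_date <- pmax(ep_start[short_ids] - sample(10:100, length(short_ids),
                                                  replace = TRUE),
                     .year_start(2017))
    out_date <- pmin(ep_start[short_ids] + 28 +
                       stats::rpois(length(short_ids), 20),
                     as.Date("2018-12-31"))
    bp_parts$short <- data.frame(
      patient_id = rep(patient_id[short_ids], 2L),
      date = c(pre_date, out_date),
      sbp = c(sbp_lat[short_ids] +
                stats::rnorm(length(short_ids), 0, cf$resid_sd),
              sbp_lat[short_ids] + cf$true_ate_short_sbp +
                stats::rnorm(length(short_ids), 0, cf$resid_sd)),
      dbp = c(dbp_lat[short_ids] +
                stats::rnorm(length(short_ids), 0, 0.6 * cf$resid_sd),
              dbp_lat[short_ids] + cf$true_ate_short_dbp +
                stats::rnorm(length(short_ids), 0, 0.6 * cf$resid_sd)))
  }
  if (length(long_ids)) {
    kw <- 2L + stats::rpois(length(long_ids), 1.5)
    span <- pmax(as.numeric(ep_end[long_ids] - ep_start[long_ids]), 1)
    win_date <- ep_start[rep(long_ids, kw)] +
      floor(stats::runif(sum(kw)) * (rep(span, kw) + 1))
    pre_date <- pmax(ep_start[long_ids] - sample(10:100, length(long_ids),
                                                 replace = TRUE),
                     .year_start(2017))
    bp_parts$long <- data.frame(
      patient_id = c(rep(patient_id[long_ids], kw), patient_id[long_ids]),
      date = c(win_date, pre_date),
      sbp = c(rep(sbp_lat[long_ids] + eff_long_sbp[long_ids], kw) +
                stats::rnorm(sum(kw), 0, cf$resid_sd),
              sbp_lat[long_ids] +
                stats::rnorm(length(long_ids), 0, cf$resid_sd)),
      dbp = c(rep(dbp_lat[long_ids] + eff_long_dbp[long_ids], kw) +
                stats::rnorm(sum(kw), 0, 0.6 * cf$resid_sd),
              dbp_lat[long_ids] +
                stats::rnorm(length(long_ids), 0, 0.6 * cf$resid_sd)))
  }
  bp <- do.call(rbind, bp_parts)
  bp$sbp <- pmin(pmax(bp$sbp, 50), 300)
  bp$dbp <- pmin(pmax(bp$dbp, 30), pmin(bp$sbp - 5, 200))

  ## baseline-BP missingness: delete all 2016 readings ---------------------
  if (cf$miss_baseline_bp > 0) {
    if (cf$missing_mechanism == "MCAR") {
      p_miss <- rep(cf$miss_baseline_bp, n)
    } else {
      lp <- 0.6 * (age < 50) + 0.4 * (klass != "none")
      a <- stats::qlogis(cf$miss_baseline_bp)
      for (i in 1:30) a <- a + log(cf$miss_baseline_bp /
                                     mean(stats::plogis(a + lp)))
      p_miss <- stats::plogis(a + lp)
    }
    drop_base <- patient_id[stats::runif(n) < p_miss]
    in2016 <- as.integer(format(bp$date, "%Y")) == 2016
    bp <- bp[!(in2016 & bp$patient_id %in% drop_base), , drop = FALSE]
  }
  bp <- bp[order(bp$patient_id, bp$date), ]
  rownames(bp) <- NULL

  ## consultations ---------------------------------------------------------
  years <- 2016:2018
  cnt <- matrix(1L + stats::rpois(3L * n, rep(lam_visit, 3L)), n, 3L)
  skip <- stats::runif(n) > cf$regularity
  cnt[cbind(which(skip), sample.int(3L, sum(skip), replace = TRUE))] <- 0L
  tot <- rowSums(cnt)
  vis_pat <- rep(seq_len(n), tot)
  vis_year <- rep(rep(years, n), as.vector(t(cnt)))
  vis_date <- as.Date(sprintf("%d-01-01", vis_year)) +
    sample.int(365, length(vis_pat), replace = TRUE) - 1L
  consultations <- data.frame(patient_id = patient_id[vis_pat],
                              practice_id = practice_id[prac_of[vis_pat]],
                              date = vis_date,
                              contact_type = "clinical",
                              stringsAsFactors = FALSE)
  # administrative contacts and same-day duplicates exercise dedupe_visits
  n_adm <- max(1L, round(0.06 * nrow(consultations)))
  adm <- consultations[sample.int(nrow(consultations), n_adm), ]
  adm$contact_type <- "administrative"
  dup <- consultations[sample.int(nrow(consultations),
                                  max(1L, round(0.02 * nrow(consultations)))), ]
  consultations <- rbind(consultations, adm, dup)
  # practice data-provision defects
  if (any(defect_kind == "gap")) {
    bad <- practice_id[defect_kind == "gap"]
    g0 <- as.Date("2018-03-01")
    del <- consultations$practice_id %in% bad &
      consultations$date >= g0 & consultations$date <= g0 + 55
    consultations <- consultations[!del, , drop = FALSE]
  }
  if (any(defect_kind == "ratio")) {
    bad <- practice_id[defect_kind == "ratio"]
    cand <- consultations$practice_id %in% bad &
      format(consultations$date, "%Y") == "2018"
    del <- cand & stats::runif(nrow(consultations)) < 0.85
    consultations <- consultations[!del, , drop = FALSE]
  }
  consultations <- consultations[order(consultations$practice_id,
                                       consultations$patient_id,
                                       consultations$date), ]
  rownames(consultations) <- NULL

  ## attributes with covariate missingness ---------------------------------
  attributes <- data.frame(
    patient_id = patient_id, practice_id = practice_id[prac_of],
    birth_year = 2016L - age, sex = sex, indigenous_status = indigenous,
    patient_irsad = patient_irsad,
    practice_irsad = practice_irsad[prac_of],
    rurality = rurality[prac_of], smoking = smoking,
    insomnia = as.integer(insomnia), mental_stress = as.integer(stress),
    diabetes = as.integer(diabetes), antihypertensive = as.integer(aht),
    sleep_apnea = as.integer(apnea), bmi = round(bmi, 1),
    stringsAsFactors = FALSE
  )
  if (cf$miss_covariate > 0)
    for (v in c("smoking", "patient_irsad", "indigenous_status"))
      attributes[[v]][stats::runif(n) < cf$miss_covariate] <- NA
  if (cf$miss_bmi > 0)
    attributes$bmi[stats::runif(n) < cf$miss_bmi] <- NA

  truth <- data.frame(
    patient_id = patient_id, practice_id = practice_id[prac_of],
    klass = klass, age = age, prior_user = prior_user,
    y0_sbp = sbp_lat, y0_dbp = dbp_lat,
    eff_short_sbp = cf$true_ate_short_sbp,
    eff_short_dbp = cf$true_ate_short_dbp,
    eff_long_sbp = eff_long_sbp, eff_long_dbp = eff_long_dbp,
    subclass_planted = subclass_planted,
    episode_start = ep_start, episode_end = ep_end,
    stringsAsFactors = FALSE
  )
  structure(list(consultations = consultations,
                 prescriptions = prescriptions, bp = bp,
                 attributes = attributes, truth = truth,
                 achieved_incidence = c(short = mean(p1), long = mean(p2)),
                 config = config),
            class = "bzd_population")
}

#' @export
print.bzd_population <- function(x, ...) {
  cat("<bzd_population>", nrow(x$attributes), "patients,",
      length(unique(x$attributes$practice_id)), "practices;",
      nrow(x$prescriptions), "scripts,", nrow(x$bp), "BP readings\n")
  invisible(x)
}

#' Write a synthetic population to delimited text
#'
#' Writes the four tables as CSV (header row, ISO-8601 dates) plus a JSON
#' ground-truth file.
#'
#' @param pop a \code{\link{generate_population}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "bzd_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("consultations", "prescriptions", "bp", "attributes"))
    utils::write.csv(pop[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(pop$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(dir)
}
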