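#' Cohort construction settings
#'
#' Bundles the study-window years and the practice data-quality thresholds:
#' the maximum tolerated silent stretch in a practice's consultation record
#' (6 weeks) and the maximum ratio between its largest and smallest annual
#' consultation counts (5), assessed over the two years ending at the close
#' of the study window.
#'
#' @param baseline_year,exposure_year,followup_year consecutive calendar
#'   years (defaults 2016, 2017, 2018).
#' @param max_gap_weeks maximum data-provision gap, in weeks (default 6).
#' @param max_visit_ratio practices with max/min annual consultation counts
#'   at or above this ratio are excluded (default 5).
#' @param min_age_years minimum patient age at the start of the baseline
#'   year (default 18).
#' @param gap_assessment_years years over which the gap and ratio rules are
#'   assessed; defaults to the exposure and follow-up years (the 24 months
#'   ending at the close of the study window).
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(baseline_year = 2016, exposure_year = 2017,
                          followup_year = 2018, max_gap_weeks = 6,
                          max_visit_ratio = 5, min_age_years = 18,
                          gap_assessment_years = c(exposure_year, followup_year)) {
  stopifnot(exposure_year == baseline_year + 1,
            followup_year == exposure_year + 1,
            max_gap_weeks > 0, max_visit_ratio > 1, min_age_years >= 0)
  structure(list(baseline_year = baseline_year, exposure_year = exposure_year,
                 followup_year = followup_year, max_gap_weeks = max_gap_weeks,
                 max_visit_ratio = max_visit_ratio,
                 min_age_years = min_age_years,
                 gap_assessment_years = gap_assessment_years),
            class = "cohort_config")
}

#' Deduplicate consultations to one clinical visit per patient-day
#'
#' Removes administrative contacts (phone calls, reminders, and similar
#' non-clinical rows) and collapses the remainder to at most one row per
#' patient per day.
#'
#' @param consultations data.frame with columns \code{patient_id},
#'   \code{practice_id}, \code{date}, \code{contact_type} (rows with
#'   \code{contact_type != "clinical"} are treated as administrative).
#' @return The deduplicated consultation table.
#' @export
dedupe_visits <- function(consultations) {
  req <- c("patient_id", "practice_id", "date", "contact_type")
  if (!all(req %in% names(consultations)))
    stop("consultations must have columns: ", paste(req, collapse = ", "))
  x <- consultations[consultations$contact_type == "clinical", , drop = FALSE]
  if (nrow(x) == 0L) return(x)
  x$date <- as.Date(x$date)
  x[!duplicated(x[c("patient_id", "date")]), , drop = FALSE]
}

#' Practices with consistent data provision
#'
#' A practice is retained when, over the assessment window, (a) there is no
#' stretch longer than \code{max_gap_weeks} weeks without any recorded
#' consultation — including the stretches from the window start to the first
#' record and from the last record to the window end — and (b) the ratio of
#' its maximum to minimum annual consultation count over the assessed years
#' is below \code{max_visit_ratio}. Practices with no consultations at all
#' are excluded (their gap is the whole window).
#'
#' @param consultations deduplicated consultation table
#'   (\code{\link{dedupe_visits}}).
#' @param config a \code{\link{cohort_config}}.
#' @return Character vector of retained practice ids, with an attribute
#'   \code{"excluded"} naming the dropped practices and the rule that dropped
#'   them.
#' @export
eligible_practices <- function(consultations, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  yrs <- config$gap_assessment_years
  win_start <- as.Date(sprintf("%d-01-01", min(yrs)))
  win_end <- as.Date(sprintf("%d-12-31", max(yrs)))
  max_gap <- config$max_gap_weeks * 7

  x <- consultations
  x$date <- as.Date(x$date)
  x <- x[x$date >= win_start & x$date <= win_end, , drop = FALSE]
  x$year <- as.integer(format(x$date, "%Y"))

  all_practices <- sort(unique(as.character(consultations$practice_id)))
  keep <- character(0)
  excluded <- data.frame(practice_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  by_prac <- split(x, as.character(x$practice_id))
  for (p in all_practices) {
    xp <- by_prac[[p]]
    if (is.null(xp) || nrow(xp) == 0L) {
      excluded <- rbind(excluded, data.frame(practice_id = p,
                                             reason = "no_consultations"))
      next
    }
    d <- sort(unique(xp$date))
    gaps <- as.numeric(diff(c(win_start, d, win_end)))
    # interior gaps are day differences between successive consultation days;
    # endpoint gaps measure silence from/to the window edges
    if (max(gaps) > max_gap) {
      excluded <- rbind(excluded, data.frame(practice_id = p, reason = "gap"))
      next
    }
    ann <- table(factor(xp$year, levels = yrs))
    if (min(ann) == 0L || max(ann) / min(ann) >= config$max_visit_ratio) {
      excluded <- rbind(excluded, data.frame(practice_id = p,
                                             reason = "visit_ratio"))
      next
    }
    keep <- c(keep, p)
  }
  structure(keep, excluded = excluded)
}

#' Regular adult patients
#'
#' Retains patients with at least one clinical consultation in each of the
#' baseline, exposure and follow-up years, aged at least
#' \code{min_age_years} at the start of the baseline year. Age is computed
#' from the year of birth in \code{attributes}; patients with a missing birth
#' year are excluded and counted.
#'
#' @param consultations deduplicated consultations restricted to eligible
#'   practices.
#' @param attributes data.frame with \code{patient_id} and \code{birth_year}.
#' @param config a \code{\link{cohort_config}}.
#' @return Character vector of retained patient ids with attribute
#'   \code{"counts"} (named integer vector of exclusion tallies).
#' @export
regular_patients <- function(consultations, attributes,
                             config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  yrs <- c(config$baseline_year, config$exposure_year, config$followup_year)
  x <- consultations
  x$date <- as.Date(x$date)
  x$year <- as.integer(format(x$date, "%Y"))
  x <- x[x$year %in% yrs, , drop = FALSE]
  tab <- table(as.character(x$patient_id), factor(x$year, levels = yrs))
  regular <- rownames(tab)[apply(tab > 0, 1L, all)]

  idx <- match(regular, as.character(attributes$patient_id))
  birth <- attributes$birth_year[idx]
  missing_birth <- is.na(birth) | is.na(idx)
  age <- config$baseline_year - birth
  adult <- !missing_birth & age >= config$min_age_years

  counts <- c(not_regular = length(unique(as.character(consultations$patient_id))) -
                length(regular),
              missing_birth_year = sum(missing_birth),
              under_age = sum(!missing_birth & age < config$min_age_years))
  structure(regular[adult], counts = counts)
}

#' Exclude prevalent BZD users (washout year)
#'
#' New-user design: removes any patient with at least one benzodiazepine /
#' z-drug script dated in the baseline (washout) year.
#'
#' @param patient_ids candidate patients.
#' @param prescriptions prescription table (\code{patient_id}, \code{date},
#'   \code{drug}).
#' @param vocab a \code{\link{bzd_vocabulary}}.
#' @param baseline_year washout year (default 2016).
#' @return Character vector of retained patient ids.
#' @export
exclude_prior_users <- function(patient_ids, prescriptions,
                                vocab = bzd_vocabulary(),
                                baseline_year = 2016) {
  if (nrow(prescriptions) == 0L) return(as.character(patient_ids))
  rx <- prescriptions
  rx$date <- as.Date(rx$date)
  rx <- rx[as.integer(format(rx$date, "%Y")) == baseline_year, , drop = FALSE]
  rx <- rx[is_bzd(rx$drug, vocab)$is_bzd, , drop = FALSE]
  prior <- unique(as.character(rx$patient_id))
  setdiff(as.character(patient_ids), prior)
}

#' Build the incident-user study cohort
#'
#' Runs the full eligibility cascade — visit deduplication, practice
#' data-quality filters, regular-adult-patient filter, washout-year BZD
#' exclusion — and reports the flow of counts at each step.
#'
#' @param consultations,prescriptions,attributes raw input tables.
#' @param config a \code{\link{cohort_config}}.
#' @param vocab a \code{\link{bzd_vocabulary}}.
#' @return A list of class \code{bzd_cohort}: \code{patient_ids},
#'   \code{practice_ids}, \code{consultations} (deduplicated, eligible
#'   practices only) and \code{flow}, a data.frame of step names and counts
#'   that telescope (each count equals the previous minus that step's
#'   exclusions).
#' @export
build_cohort <- function(consultations, prescriptions, attributes,
                         config = cohort_config(), vocab = bzd_vocabulary()) {
  visits <- dedupe_visits(consultations)
  pracs <- eligible_practices(visits, config)
  visits_el <- visits[as.character(visits$practice_id) %in% pracs, ,
                      drop = FALSE]
  pat_all <- unique(as.character(visits$patient_id))
  pat_prac <- unique(as.character(visits_el$patient_id))
  reg <- regular_patients(visits_el, attributes, config)
  incident <- exclude_prior_users(reg, prescriptions, vocab,
                                  config$baseline_year)
  flow <- data.frame(
    step = c("patients_with_clinical_visit", "in_eligible_practices",
             "regular_adult_patients", "no_baseline_year_bzd"),
    n = c(length(pat_all), length(pat_prac), length(reg), length(incident)),
    stringsAsFactors = FALSE
  )
  structure(list(patient_ids = incident, practice_ids = as.character(pracs),
                 consultations = visits_el, flow = flow,
                 practice_exclusions = attr(pracs, "excluded"),
                 patient_exclusions = attr(reg, "counts")),
            class = "bzd_cohort")
}

#' @export
print.bzd_cohort <- function(x, ...) {
  cat("<bzd_cohort>", length(x$patient_ids), "patients in",
      length(x$practice_ids), "practices\n")
  print(x$flow, row.names = FALSE)
  invisible(x)
}
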