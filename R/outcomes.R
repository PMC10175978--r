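#' Baseline blood pressure (washout-year median)
#'
#' Baseline SBP and DBP are the componentwise medians of all measurements
#' recorded in the baseline year. Same-day duplicate readings are averaged
#' before the median is taken; even-count medians use the midpoint of the
#' two central values. Patients without any baseline-year reading get
#' \code{NA} (baseline BP is a confounder and flows to imputation).
#'
#' @param measurements data.frame for one patient: \code{date}, \code{sbp},
#'   \code{dbp}.
#' @param baseline_year integer year (default 2016).
#' @return Named numeric vector \code{c(baseline_sbp, baseline_dbp)}.
#' @export
baseline_bp <- function(measurements, baseline_year = 2016) {
  m <- collapse_same_day(measurements)
  m <- m[as.integer(format(m$date, "%Y")) == baseline_year, , drop = FALSE]
  if (nrow(m) == 0L)
    return(c(baseline_sbp = NA_real_, baseline_dbp = NA_real_))
  c(baseline_sbp = stats::median(m$sbp), baseline_dbp = stats::median(m$dbp))
}

#' Post-exposure outcome blood pressure
#'
#' Derives the outcome SBP/DBP under the rule matching the patient's
#' exposure class:
#' \itemize{
#'   \item unexposed: componentwise median of all exposure-year measurements;
#'   \item short-term: the single earliest measurement dated at least 28 days
#'     after the episode start (a reading exactly at start + 28 days
#'     qualifies);
#'   \item long-term: componentwise median of measurements dated within the
#'     episode window \code{[start_date, end_date]}, both ends inclusive.
#' }
#' Same-day duplicates are averaged before the window logic. When no
#' qualifying measurement exists both outcomes are \code{NA} and the patient
#' is flagged for exclusion from estimation (outcome BP is never imputed).
#'
#' @param measurements data.frame for one patient: \code{date}, \code{sbp},
#'   \code{dbp}.
#' @param episode an \code{exposure_episode}, or a one-row slice of
#'   \code{\link{classify_exposure}} output (list with \code{klass},
#'   \code{start_date}, \code{end_date}).
#' @param exposure_year integer year (default 2017).
#' @param min_days_after_start qualifying delay for the short-term rule
#'   (default 28 days).
#' @return Named numeric vector \code{c(outcome_sbp, outcome_dbp)} with
#'   attribute \code{"rule"} recording which window rule fired
#'   (\code{"median_2017"}, \code{"first_after_28d"},
#'   \code{"median_episode"}).
#' @export
outcome_bp <- function(measurements, episode, exposure_year = 2017,
                       min_days_after_start = 28) {
  klass <- episode$klass
  m <- collapse_same_day(measurements)
  miss <- c(outcome_sbp = NA_real_, outcome_dbp = NA_real_)
  if (identical(klass, "none")) {
    m <- m[as.integer(format(m$date, "%Y")) == exposure_year, , drop = FALSE]
    out <- if (nrow(m)) c(outcome_sbp = stats::median(m$sbp),
                          outcome_dbp = stats::median(m$dbp)) else miss
    return(structure(out, rule = "median_2017"))
  }
  start <- as.Date(episode$start_date)
  if (is.na(start)) stop("exposed episode without a start date")
  if (identical(klass, "short_term")) {
    m <- m[m$date >= start + min_days_after_start, , drop = FALSE]
    out <- if (nrow(m)) {
      first <- m[which.min(m$date), ]
      c(outcome_sbp = first$sbp, outcome_dbp = first$dbp)
    } else miss
    return(structure(out, rule = "first_after_28d"))
  }
  if (identical(klass, "long_term")) {
    end <- as.Date(episode$end_date)
    if (is.na(end)) stop("long-term episode without an end date")
    m <- m[m$date >= start & m$date <= end, , drop = FALSE]
    out <- if (nrow(m)) c(outcome_sbp = stats::median(m$sbp),
                          outcome_dbp = stats::median(m$dbp)) else miss
    return(structure(out, rule = "median_episode"))
  }
  stop("unknown exposure class: ", klass)
}

# average same-day duplicate readings; order-insensitive
collapse_same_day <- function(measurements) {
  req <- c("date", "sbp", "dbp")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  m <- measurements
  m$date <- as.Date(m$date)
  if (anyDuplicated(m$date)) {
    agg <- stats::aggregate(m[c("sbp", "dbp")], by = list(date = m$date), mean)
    m <- agg
  }
  m[order(m$date), , drop = FALSE]
}

#' Derive baseline and outcome BP for a whole cohort
#'
#' Applies \code{\link{baseline_bp}} and \code{\link{outcome_bp}} per patient
#' against the exposure classification table.
#'
#' @param bp blood-pressure table: \code{patient_id}, \code{date},
#'   \code{sbp}, \code{dbp}.
#' @param episodes output of \code{\link{classify_exposure}} (one row per
#'   patient; patients absent from it are treated as unexposed).
#' @param patient_ids patients to process (default: those in
#'   \code{episodes}).
#' @param baseline_year,exposure_year study years.
#' @details The whole-cohort driver is a vectorised \pkg{data.table}
#'   implementation of exactly the per-patient semantics of
#'   \code{\link{baseline_bp}} and \code{\link{outcome_bp}} (same-day
#'   averaging first, then window selection, then componentwise medians).
#' @return data.frame: \code{patient_id}, \code{baseline_sbp},
#'   \code{baseline_dbp}, \code{outcome_sbp}, \code{outcome_dbp},
#'   \code{outcome_rule_used}.
#' @export
derive_outcomes <- function(bp, episodes, patient_ids = episodes$patient_id,
                            baseline_year = 2016, exposure_year = 2017) {
  patient_id <- sbp <- dbp <- year <- klass <- start_date <- end_date <-
    NULL # data.table NSE
  pid <- as.character(patient_ids)
  m <- data.table::as.data.table(bp[c("patient_id", "date", "sbp", "dbp")])
  m[, patient_id := as.character(patient_id)]
  m <- m[patient_id %in% pid]
  m[, date := as.Date(date)]
  m <- m[, list(sbp = mean(sbp), dbp = mean(dbp)),
         by = list(patient_id, date)]
  m[, year := as.integer(format(date, "%Y"))]

  base <- m[year == baseline_year,
            list(baseline_sbp = stats::median(sbp),
                 baseline_dbp = stats::median(dbp)), by = patient_id]

  ep <- data.table::as.data.table(
    episodes[c("patient_id", "klass", "start_date", "end_date")])
  ep[, patient_id := as.character(patient_id)]
  ep <- ep[match(pid, patient_id)]
  ep[, patient_id := pid]
  ep[is.na(klass), klass := "none"]

  # unexposed: exposure-year medians
  none_ids <- ep[klass == "none", patient_id]
  out_none <- m[year == exposure_year & patient_id %in% none_ids,
                list(outcome_sbp = stats::median(sbp),
                     outcome_dbp = stats::median(dbp)), by = patient_id]

  # short-term: earliest reading >= start + 28 days
  st <- ep[klass == "short_term", list(patient_id, start_date)]
  ms <- m[st, on = "patient_id", nomatch = 0L]
  ms <- ms[date >= start_date + 28]
  out_short <- ms[order(date),
                  list(outcome_sbp = sbp[1L], outcome_dbp = dbp[1L]),
                  by = patient_id]

  # long-term: median over the episode window, inclusive
  lt <- ep[klass == "long_term", list(patient_id, start_date, end_date)]
  ml <- m[lt, on = "patient_id", nomatch = 0L]
  ml <- ml[date >= start_date & date <= end_date]
  out_long <- ml[, list(outcome_sbp = stats::median(sbp),
                        outcome_dbp = stats::median(dbp)), by = patient_id]

  out <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  bi <- match(pid, base$patient_id)
  out$baseline_sbp <- base$baseline_sbp[bi]
  out$baseline_dbp <- base$baseline_dbp[bi]
  rule <- c(none = "median_2017", short_term = "first_after_28d",
            long_term = "median_episode")[ep$klass]
  oc <- data.table::rbindlist(list(out_none, out_short, out_long))
  oi <- match(pid, oc$patient_id)
  out$outcome_sbp <- oc$outcome_sbp[oi]
  out$outcome_dbp <- oc$outcome_dbp[oi]
  out$outcome_rule_used <- unname(rule)
  out
}
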