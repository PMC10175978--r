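#' Classify a patient's first incident BZD episode
#'
#' Applies the incident-management rules to one patient's benzodiazepine /
#' z-drug scripts under a new-user design (no scripts in the washout year,
#' enforced upstream). The first script dated in \code{exposure_year} starts
#' the episode. The episode is \emph{long-term} when (a) at least three
#' scripts fall within \code{window_days} (default 180) days of the start,
#' and (b) the second distinct script \emph{date} is more than
#' \code{second_script_gap_days} (default 28) days after the start; any other
#' pattern that starts in the exposure year is \emph{short-term}. A long-term
#' episode accrues scripts forward (into the following year if needed) while
#' successive inter-script gaps stay below \code{termination_gap_days}
#' (default 180) days; the episode ends at the last accrued script. Patients
#' with no script in the exposure year are unexposed. Only the first episode
#' is ever classified; later script activity never reassigns the class.
#'
#' Same-day duplicate scripts count as one date for the second-script
#' condition (a same-day duplicate is a recording artifact, not a dispensing
#' interval) but every script row is retained in the episode.
#'
#' @param dates \code{Date} vector of one patient's BZD script dates, sorted
#'   ascending.
#' @param drugs optional character vector of generic drug names parallel to
#'   \code{dates} (used for half-life subclassification downstream).
#' @param exposure_year integer calendar year in which incident episodes are
#'   identified (default 2017).
#' @param window_days,second_script_gap_days,termination_gap_days rule
#'   thresholds; the long-term window is inclusive (a third script exactly
#'   \code{window_days} after the start still qualifies), the second-script
#'   condition strict (exactly \code{second_script_gap_days} days does not
#'   qualify), and a gap of \code{termination_gap_days} or more ends the
#'   episode.
#' @return A list of class \code{exposure_episode}: \code{klass} one of
#'   \code{"none"}, \code{"short_term"}, \code{"long_term"};
#'   \code{start_date}, \code{end_date} (\code{NA} unless long-term);
#'   \code{script_dates}, \code{script_drugs} for the scripts belonging to
#'   the episode.
#' @examples
#' d <- as.Date("2017-01-01") + c(0, 40, 100)
#' classify_first_episode(d)$klass   # "long_term"
#' @export
classify_first_episode <- function(dates, drugs = NULL, exposure_year = 2017,
                                   window_days = 180,
                                   second_script_gap_days = 28,
                                   termination_gap_days = 180) {
  dates <- as.Date(dates)
  if (is.null(drugs)) drugs <- rep(NA_character_, length(dates))
  stopifnot(length(drugs) == length(dates))
  if (is.unsorted(as.numeric(dates), na.rm = TRUE))
    stop("script dates must be sorted ascending")

  none <- structure(list(klass = "none", start_date = as.Date(NA),
                         end_date = as.Date(NA),
                         script_dates = dates[0], script_drugs = character(0)),
                    class = "exposure_episode")
  if (length(dates) == 0L) return(none)
  yr <- as.integer(format(dates, "%Y"))
  first_idx <- which(yr == exposure_year)
  if (length(first_idx) == 0L) return(none)

  start <- dates[first_idx[1L]]
  keep <- dates >= start
  d <- dates[keep]; g <- drugs[keep]
  offs <- as.numeric(d - start)

  n_in_window <- sum(offs <= window_days)
  distinct <- sort(unique(offs))
  second_ok <- length(distinct) >= 2L && distinct[2L] > second_script_gap_days

  if (n_in_window >= 3L && second_ok) {
    # accrue forward while successive distinct-date gaps stay < termination gap
    end_off <- distinct[1L]
    for (o in distinct[-1L]) {
      if (o - end_off >= termination_gap_days) break
      end_off <- o
    }
    in_ep <- offs <= end_off
    structure(list(klass = "long_term", start_date = start,
                   end_date = start + end_off,
                   script_dates = d[in_ep], script_drugs = g[in_ep]),
              class = "exposure_episode")
  } else {
    structure(list(klass = "short_term", start_date = start,
                   end_date = as.Date(NA),
                   script_dates = d[offs == 0], script_drugs = g[offs == 0]),
              class = "exposure_episode")
  }
}

#' @export
print.exposure_episode <- function(x, ...) {
  cat("<exposure_episode>", x$klass)
  if (!is.na(x$start_date)) cat(" start", format(x$start_date))
  if (!is.na(x$end_date)) cat(" end", format(x$end_date))
  cat(" scripts", length(x$script_dates), "\n")
  invisible(x)
}

#' Subclassify a long-term episode by drug half-life
#'
#' Long-term incident episodes are subclassified by the elimination half-life
#' classes of the drugs dispensed during the episode: exclusively
#' short-intermediate acting, exclusively long-acting, or a mix of both.
#'
#' @param episode an \code{\link{classify_first_episode}} result with
#'   \code{klass == "long_term"}.
#' @param vocab a \code{\link{bzd_vocabulary}}.
#' @return One of \code{"short_intermediate_only"}, \code{"long_acting_only"},
#'   \code{"mixed"}.
#' @export
subclassify_half_life <- function(episode, vocab = bzd_vocabulary()) {
  stopifnot(inherits(episode, "exposure_episode"))
  if (!identical(episode$klass, "long_term"))
    stop("half-life subclassification applies to long-term episodes only")
  cls <- unique(is_bzd(episode$script_drugs, vocab)$half_life_class)
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L)
    stop("episode contains no recognised BZD drug names")
  if (all(cls == "short_intermediate")) "short_intermediate_only"
  else if (all(cls == "long_acting")) "long_acting_only"
  else "mixed"
}

#' Classify incident BZD exposure for every patient
#'
#' Vectorised driver over a prescription table: filters scripts to recognised
#' BZD drugs, applies \code{\link{classify_first_episode}} per patient, and
#' subclassifies long-term episodes by half-life. Patients present in
#' \code{patient_ids} but without any exposure-year BZD script are returned
#' as unexposed.
#'
#' @param prescriptions data.frame with columns \code{patient_id},
#'   \code{date} (\code{Date} or ISO-8601 string), \code{drug}.
#' @param patient_ids vector of patients to classify (defaults to those
#'   appearing in \code{prescriptions}).
#' @param vocab a \code{\link{bzd_vocabulary}}.
#' @param exposure_year integer year (default 2017).
#' @param ... passed to \code{\link{classify_first_episode}} (rule thresholds).
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{klass}, \code{start_date}, \code{end_date},
#'   \code{n_scripts} (scripts in the classified episode),
#'   \code{half_life_subclass} (\code{NA} unless long-term).
#' @export
classify_exposure <- function(prescriptions, patient_ids = NULL,
                              vocab = bzd_vocabulary(), exposure_year = 2017,
                              ...) {
  req <- c("patient_id", "date", "drug")
  if (!all(req %in% names(prescriptions)))
    stop("prescriptions must have columns: ", paste(req, collapse = ", "))
  rx <- prescriptions
  rx$date <- as.Date(rx$date)
  look <- is_bzd(rx$drug, vocab)
  rx <- rx[look$is_bzd, , drop = FALSE]
  rx$generic <- look$generic[look$is_bzd]
  rx <- rx[order(rx$patient_id, rx$date), , drop = FALSE]

  if (is.null(patient_ids)) patient_ids <- unique(rx$patient_id)
  split_idx <- split(seq_len(nrow(rx)), rx$patient_id)

  out <- data.frame(patient_id = patient_ids,
                    klass = "none",
                    start_date = as.Date(NA), end_date = as.Date(NA),
                    n_scripts = 0L,
                    half_life_subclass = NA_character_,
                    stringsAsFactors = FALSE)
  rows <- split_idx[as.character(patient_ids)]
  has_rx <- !vapply(rows, is.null, logical(1))
  for (i in which(has_rx)) {
    ii <- rows[[i]]
    ep <- classify_first_episode(rx$date[ii], rx$generic[ii],
                                 exposure_year = exposure_year, ...)
    out$klass[i] <- ep$klass
    out$start_date[i] <- ep$start_date
    out$end_date[i] <- ep$end_date
    out$n_scripts[i] <- length(ep$script_dates)
    if (identical(ep$klass, "long_term"))
      out$half_life_subclass[i] <- subclassify_half_life(ep, vocab)
  }
  out
}
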