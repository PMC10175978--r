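#' Hand-constructed fixture bundles
#'
#' Small, fully deterministic table bundles with documented expected
#' downstream results, used throughout the test-suite:
#' \describe{
#'   \item{\code{"episode_edges"}}{22 single-patient BZD script patterns
#'     covering every boundary of the episode rules (second script at
#'     exactly versus just over 28 days; the 180-day window inclusive edge;
#'     the 180-day termination gap; same-day duplicate scripts; episodes
#'     crossing into the following year; half-life drug mixes). Returns
#'     \code{scripts} plus an \code{expected} table of hand-derived class,
#'     episode end, and subclass labels.}
#'   \item{\code{"saturated_toy"}}{12 analysis rows, one binary covariate,
#'     three treatment levels, two readings per covariate-by-treatment cell
#'     with fixed outcomes, so that saturated treatment and outcome models
#'     make the AIPW estimate collapse to the stratified g-formula value,
#'     which is hand-computable.}
#'   \item{\code{"null_cluster"}}{20 patients in 5 practices, three
#'     treatment levels assigned round-robin, fixed outcomes with
#'     practice-level offsets and no treatment effect, for
#'     variance-estimator checks.}
#' }
#'
#' @param name fixture name.
#' @return A named list of tables (contents depend on the fixture).
#' @export
make_fixture <- function(name = c("episode_edges", "saturated_toy",
                                  "null_cluster")) {
  name <- match.arg(name)
  switch(name,
         episode_edges = .fixture_episode_edges(),
         saturated_toy = .fixture_saturated_toy(),
         null_cluster = .fixture_null_cluster())
}

.fixture_episode_edges <- function() {
  a <- as.Date("2017-01-05") # anchor well inside the exposure year
  pat <- function(id, offsets, drugs, klass, end_off = NA, subclass = NA)
    list(id = id, offsets = offsets, drugs = drugs, klass = klass,
         end_off = end_off, subclass = subclass)
  specs <- list(
    pat("e01", 0, "temazepam", "short_term"),                 # single script
    pat("e02", c(0, 40, 100), rep("temazepam", 3), "long_term", 100,
        "short_intermediate_only"),
    pat("e03", c(0, 10, 20), rep("temazepam", 3), "short_term"), # 2nd <= 28
    pat("e04", c(0, 29, 100), rep("diazepam", 3), "long_term", 100,
        "long_acting_only"),                                  # 29 > 28
    pat("e05", c(0, 28, 100), rep("diazepam", 3), "short_term"), # 28 !> 28
    pat("e06", c(0, 40, 180), rep("oxazepam", 3), "long_term", 180,
        "short_intermediate_only"),                 # window edge inclusive
    pat("e07", c(0, 40, 181), rep("oxazepam", 3), "short_term"), # outside
    pat("e08", c(0, 40, 100, 300), rep("temazepam", 4), "long_term", 100,
        "short_intermediate_only"),                 # 200-day gap terminates
    pat("e09", c(0, 40, 100, 279), rep("temazepam", 4), "long_term", 279,
        "short_intermediate_only"),                 # 179-day gap accrues
    pat("e10", c(0, 40, 100, 280), rep("temazepam", 4), "long_term", 100,
        "short_intermediate_only"),                 # exactly 180 terminates
    pat("e11", c(0, 0, 40, 100), rep("zolpidem", 4), "long_term", 100,
        "short_intermediate_only"),   # same-day dup; 2nd distinct date 40
    pat("e12", c(0, 10, 10, 40), rep("zolpidem", 4), "short_term"),
                                      # same-day dup; 2nd distinct date 10
    pat("e13", c(0, 0, 40), rep("temazepam", 3), "long_term", 40,
        "short_intermediate_only"),   # 3 script rows on 2 dates still count
    pat("e14", c(0, 100, 150), rep("diazepam", 3), "long_term", 150,
        "long_acting_only"),
    pat("e15", c(0, 40, 200), rep("diazepam", 3), "short_term"),
                                      # only 2 scripts within 180 d of start
    pat("e16", c(0, 40), rep("temazepam", 2), "short_term"),
    pat("e17", c(0, 40, 170, 350, 520), rep("temazepam", 5), "long_term",
        170, "short_intermediate_only"),        # 180-day gap at 170 -> 350
    pat("e18", c(0, 40, 170, 349), rep("temazepam", 4), "long_term", 349,
        "short_intermediate_only"),             # 179-day gap accrues
    pat("e19", c(0, 90, 181), rep("temazepam", 3), "short_term"),
    pat("e20", c(0, 90, 180), c("temazepam", "diazepam", "temazepam"),
        "long_term", 180, "mixed"),
    pat("e21", c(0, 35, 90, 260, 430), rep("zopiclone", 5), "long_term",
        430, "short_intermediate_only"),        # crosses into 2018
    pat("e22", numeric(0), character(0), "none")  # script in 2018 only
  )
  scripts <- do.call(rbind, lapply(specs, function(s) {
    if (s$id == "e22")
      return(data.frame(patient_id = s$id, date = as.Date("2018-02-01"),
                        drug = "temazepam", stringsAsFactors = FALSE))
    data.frame(patient_id = s$id, date = a + s$offsets, drug = s$drugs,
               stringsAsFactors = FALSE)
  }))
  expected <- do.call(rbind, lapply(specs, function(s)
    data.frame(patient_id = s$id, klass = s$klass,
               end_date = if (is.na(s$end_off)) as.Date(NA) else
                 a + s$end_off,
               half_life_subclass = as.character(s$subclass),
               stringsAsFactors = FALSE)))
  list(scripts = scripts, expected = expected, anchor = a)
}

.fixture_saturated_toy <- function() {
  # one binary covariate x, treatments 0/1/2, two rows per (x, t) cell
  grid <- expand.grid(x = c(0, 1), treatment = c("none", "short_term",
                                                 "long_term"),
                      rep = 1:2, stringsAsFactors = FALSE)
  base <- ifelse(grid$x == 1, 140, 120)
  shift <- c(none = 0, short_term = 4, long_term = -6)[grid$treatment]
  wiggle <- ifelse(grid$rep == 1, -5, 5)
  rows <- data.frame(
    patient_id = sprintf("s%02d", seq_len(nrow(grid))),
    practice_id = rep(c("prA", "prB"), length.out = nrow(grid)),
    treatment = factor(grid$treatment,
                       levels = c("none", "short_term", "long_term")),
    x = grid$x,
    outcome_sbp = base + shift + wiggle,
    stringsAsFactors = FALSE
  )
  rows$outcome_dbp <- rows$outcome_sbp - 50
  rows
}

.fixture_null_cluster <- function() {
  # 5 practices x 4 patients; no treatment effect; practice offsets plus a
  # deterministic non-repeating wiggle (so cluster residual sums differ)
  prac <- rep(sprintf("pr%d", 1:5), each = 4L)
  offset <- rep(c(-4, -2, 0, 2, 4), each = 4L)
  tr <- rep(c("none", "none", "short_term", "long_term"), times = 5L)
  wig <- ((seq_len(20L) * 7L) %% 11L) - 5L
  data.frame(
    patient_id = sprintf("n%02d", 1:20),
    practice_id = prac,
    treatment = factor(tr, levels = c("none", "short_term", "long_term")),
    x = rep(c(0, 1), 10),
    outcome_sbp = 130 + offset + wig,
    outcome_dbp = 80 + offset / 2 + wig / 2,
    stringsAsFactors = FALSE
  )
}
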