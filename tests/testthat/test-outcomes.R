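mk_bp <- function(dates, sbp, dbp = sbp - 50)
  data.frame(date = as.Date(dates), sbp = sbp, dbp = dbp)

test_that("baseline BP is the washout-year componentwise median", {
  m <- mk_bp(c("2016-01-10", "2016-06-10", "2016-11-10", "2017-02-01"),
             c(120, 130, 140, 999))
  expect_equal(unname(baseline_bp(m)["baseline_sbp"]), 130)
  m2 <- mk_bp(c("2016-01-10", "2016-06-10"), c(120, 130))
  expect_equal(unname(baseline_bp(m2)["baseline_sbp"]), 125)
  expect_true(is.na(baseline_bp(mk_bp("2017-01-01", 120))["baseline_sbp"]))
})

test_that("unexposed outcome is the exposure-year median", {
  m <- mk_bp(c("2017-01-10", "2017-05-10", "2017-09-10"), c(150, 110, 130))
  o <- outcome_bp(m, list(klass = "none"))
  expect_equal(unname(o["outcome_sbp"]), 130)
  expect_equal(attr(o, "rule"), "median_2017")
})

test_that("short-term outcome is the first reading at or after day 28", {
  start <- as.Date("2017-04-11") # day 100 of 2017
  ep <- list(klass = "short_term", start_date = start)
  m <- mk_bp(start + c(20, 40), c(120, 140))
  o <- outcome_bp(m, ep)
  expect_equal(unname(o["outcome_sbp"]), 140)
  expect_equal(attr(o, "rule"), "first_after_28d")
  # a reading exactly at start + 28 qualifies
  m2 <- mk_bp(start + c(28, 40), c(121, 140))
  expect_equal(unname(outcome_bp(m2, ep)["outcome_sbp"]), 121)
  # none after day 28 -> missing, flagged for exclusion
  m3 <- mk_bp(start + 10, 120)
  expect_true(is.na(outcome_bp(m3, ep)["outcome_sbp"]))
})

test_that("long-term outcome is the episode-window median, window inclusive", {
  start <- as.Date("2017-02-01")
  ep <- list(klass = "long_term", start_date = start,
             end_date = start + 100)
  m <- mk_bp(start + c(-10, 10, 50, 120), c(200, 120, 130, 210))
  o <- outcome_bp(m, ep)
  expect_equal(unname(o["outcome_sbp"]), 125) # median of day-10, day-50
  expect_equal(attr(o, "rule"), "median_episode")
  # boundary readings at start and end are included
  m2 <- mk_bp(start + c(0, 100), c(110, 130))
  expect_equal(unname(outcome_bp(m2, ep)["outcome_sbp"]), 120)
})

test_that("readings outside the long-term window never leak in", {
  start <- as.Date("2017-02-01")
  ep <- list(klass = "long_term", start_date = start, end_date = start + 60)
  inside <- mk_bp(start + c(5, 30, 55), c(118, 122, 126))
  spiked <- rbind(inside, mk_bp(start + c(-1, 61), c(295, 51)))
  expect_equal(outcome_bp(inside, ep), outcome_bp(spiked, ep))
})

test_that("same-day duplicates are averaged and input order is irrelevant", {
  m <- mk_bp(c("2017-03-01", "2017-03-01", "2017-07-01"), c(120, 140, 135))
  o <- outcome_bp(m, list(klass = "none"))
  expect_equal(unname(o["outcome_sbp"]), stats::median(c(130, 135)))
  set.seed(9)
  shuf <- m[sample(nrow(m)), ]
  expect_equal(outcome_bp(shuf, list(klass = "none")), o)
})

test_that("vectorised cohort derivation matches the per-patient rules", {
  pop <- generate_population(synth_config(n_practices = 6,
                                          patients_per_practice = 60,
                                          seed = 17))
  eps <- classify_exposure(pop$prescriptions,
                           patient_ids = pop$attributes$patient_id)
  ids <- pop$attributes$patient_id
  fast <- derive_outcomes(pop$bp, eps, patient_ids = ids)
  set.seed(4)
  for (id in sample(ids, 40)) {
    m <- pop$bp[pop$bp$patient_id == id, c("date", "sbp", "dbp")]
    i <- which(eps$patient_id == id)
    ep <- list(klass = eps$klass[i], start_date = eps$start_date[i],
               end_date = eps$end_date[i])
    j <- which(fast$patient_id == id)
    if (nrow(m) == 0) next
    b <- baseline_bp(m); o <- outcome_bp(m, ep)
    expect_equal(fast$baseline_sbp[j], unname(b["baseline_sbp"]))
    expect_equal(fast$outcome_sbp[j], unname(o["outcome_sbp"]))
    expect_equal(fast$outcome_dbp[j], unname(o["outcome_dbp"]))
    expect_equal(fast$outcome_rule_used[j], attr(o, "rule"))
  }
})
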