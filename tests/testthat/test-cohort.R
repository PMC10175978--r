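mk_visits <- function(patient, practice, dates, type = "clinical")
  data.frame(patient_id = patient, practice_id = practice,
             date = as.Date(dates), contact_type = type,
             stringsAsFactors = FALSE)

test_that("dedupe keeps one clinical visit per patient-day, drops admin", {
  v <- rbind(mk_visits("p1", "A", rep("2017-03-01", 3)),
             mk_visits("p1", "A", "2017-03-02", "administrative"),
             mk_visits("p2", "A", "2017-03-01"))
  d <- dedupe_visits(v)
  expect_equal(nrow(d), 2L)
  expect_equal(sum(d$patient_id == "p1"), 1L)
  expect_equal(nrow(dedupe_visits(v[0, ])), 0L)
  expect_error(dedupe_visits(data.frame(x = 1)), "columns")
})

# a practice with visits every `step` days across 2017-2018
dense_practice <- function(practice, step = 10) {
  d <- seq(as.Date("2017-01-03"), as.Date("2018-12-28"), by = step)
  mk_visits(paste0(practice, "_pat"), practice, d)
}

test_that("practice filters drop long gaps and skewed annual volumes", {
  good <- dense_practice("G")
  gap <- dense_practice("H")
  gap <- gap[!(gap$date > as.Date("2018-05-01") &
                 gap$date < as.Date("2018-06-20")), ] # 49-day silence
  skew <- dense_practice("K", step = 3)
  skew <- skew[!(format(skew$date, "%Y") == "2018" &
                   seq_len(nrow(skew)) %% 8 != 0), ] # 2018 count ~1/8 of 2017
  keep <- eligible_practices(rbind(good, gap, skew))
  expect_true("G" %in% keep)
  expect_false("H" %in% keep)
  expect_false("K" %in% keep)
  ex <- attr(keep, "excluded")
  expect_equal(ex$reason[ex$practice_id == "H"], "gap")
  expect_equal(ex$reason[ex$practice_id == "K"], "visit_ratio")
})

test_that("regular-patient filter needs all three years and adult age", {
  v <- rbind(
    mk_visits("a", "G", c("2016-02-01", "2017-02-01", "2018-02-01")),
    mk_visits("b", "G", c("2016-02-01", "2018-02-01")),
    mk_visits("c", "G", c("2016-03-01", "2017-03-01", "2018-03-01")),
    mk_visits("d", "G", c("2016-03-01", "2017-03-01", "2018-03-01"))
  )
  at <- data.frame(patient_id = c("a", "b", "c", "d"),
                   birth_year = c(1976, 1976, 1999, NA))
  kept <- regular_patients(v, at)
  expect_setequal(kept, "a") # b not regular, c aged 17 in 2016, d no birth year
  expect_equal(attr(kept, "counts")[["missing_birth_year"]], 1L)
})

test_that("washout-year BZD exclusion is drug- and year-specific", {
  rx <- data.frame(
    patient_id = c("a", "b", "c"),
    date = as.Date(c("2016-05-01", "2017-05-01", "2016-05-01")),
    drug = c("temazepam", "diazepam", "metformin"))
  expect_setequal(exclude_prior_users(c("a", "b", "c"), rx), c("b", "c"))
  expect_setequal(exclude_prior_users(c("a", "b"), rx[0, ]), c("a", "b"))
})

test_that("logically independent filters commute", {
  v <- rbind(
    mk_visits("a", "G", c("2016-02-01", "2017-02-01", "2018-02-01")),
    mk_visits("b", "G", c("2016-02-01", "2018-02-01")),
    mk_visits("c", "G", c("2016-03-01", "2017-03-01", "2018-03-01")))
  at <- data.frame(patient_id = c("a", "b", "c"),
                   birth_year = c(1970, 1970, 1970))
  rx <- data.frame(patient_id = "c", date = as.Date("2016-06-01"),
                   drug = "diazepam")
  r1 <- exclude_prior_users(regular_patients(v, at), rx)
  r2 <- intersect(regular_patients(v, at),
                  exclude_prior_users(c("a", "b", "c"), rx))
  expect_setequal(r1, r2)
})

test_that("adding consultations can only grow the regular set", {
  v <- rbind(
    mk_visits("a", "G", c("2016-02-01", "2017-02-01", "2018-02-01")),
    mk_visits("b", "G", c("2016-02-01", "2018-02-01")))
  at <- data.frame(patient_id = c("a", "b"), birth_year = c(1970, 1970))
  before <- regular_patients(v, at)
  after <- regular_patients(rbind(v, mk_visits("b", "G", "2017-07-01")), at)
  expect_true(all(before %in% after))
  expect_true("b" %in% after)
})

test_that("cohort flow counts telescope on a generated population", {
  pop <- generate_population(synth_config(n_practices = 15,
                                          patients_per_practice = 120,
                                          seed = 31))
  coh <- build_cohort(pop$consultations, pop$prescriptions, pop$attributes)
  expect_true(all(diff(coh$flow$n) <= 0))
  expect_equal(coh$flow$step[1], "patients_with_clinical_visit")
  # every retained patient really is regular, adult, and BZD-free in 2016
  tr <- pop$truth[match(coh$patient_ids, pop$truth$patient_id), ]
  expect_true(all(!tr$prior_user))
  expect_true(all(tr$age >= 18))
})
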