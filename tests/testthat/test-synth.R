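test_that("identical config and seed reproduce the tables exactly", {
  cfg <- synth_config(n_practices = 8, patients_per_practice = 60,
                      seed = 123)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  for (nm in c("consultations", "prescriptions", "bp", "attributes",
               "truth"))
    expect_identical(p1[[nm]], p2[[nm]])
})

test_that("null generator yields no exposed-unexposed outcome difference", {
  cfg <- synth_config(n_practices = 40, patients_per_practice = 250,
                      confounding_strength = 0,
                      true_ate_short_sbp = 0, true_ate_short_dbp = 0,
                      true_ate_long_sbp = 0, true_ate_long_dbp = 0,
                      seed = 202)
  pop <- generate_population(cfg)
  eps <- classify_exposure(pop$prescriptions,
                           patient_ids = pop$attributes$patient_id)
  out <- derive_outcomes(pop$bp, eps)
  grp <- eps$klass != "none"
  d <- out$outcome_sbp
  diff <- mean(d[grp], na.rm = TRUE) - mean(d[!grp], na.rm = TRUE)
  se <- sqrt(stats::var(d[grp], na.rm = TRUE) / sum(!is.na(d[grp])) +
               stats::var(d[!grp], na.rm = TRUE) / sum(!is.na(d[!grp])))
  expect_lt(abs(diff), 3 * se)
})

test_that("realised incidences land near their targets", {
  pop <- generate_population(synth_config(n_practices = 60,
                                          patients_per_practice = 500,
                                          seed = 404))
  tr <- pop$truth
  p_short <- mean(tr$klass == "short_term")
  p_long <- mean(tr$klass == "long_term")
  expect_lt(abs(p_short - 0.032) / 0.032, 0.2)
  expect_lt(abs(p_long - 0.005) / 0.005, 0.2)
})

test_that("generated script streams reproduce their planted class labels", {
  pop <- generate_population(synth_config(n_practices = 30,
                                          patients_per_practice = 400,
                                          seed = 77))
  tr <- pop$truth[!pop$truth$prior_user, ]
  eps <- classify_exposure(pop$prescriptions, patient_ids = tr$patient_id)
  exposed <- tr$klass != "none"
  agree <- eps$klass[match(tr$patient_id, eps$patient_id)] == tr$klass
  expect_gte(mean(agree[exposed]), 0.99)
  expect_true(all(agree[!exposed]))
  # planted half-life subclasses survive the round trip too
  lt <- tr$klass == "long_term"
  got <- eps$half_life_subclass[match(tr$patient_id[lt], eps$patient_id)]
  expect_gte(mean(got == tr$subclass_planted[lt]), 0.99)
})

test_that("naive bias under the null shrinks as the sample grows", {
  naive <- function(n_prac, seed) {
    cfg <- synth_config(n_practices = n_prac, patients_per_practice = 150,
                        confounding_strength = 0, true_ate_short_sbp = 0,
                        true_ate_short_dbp = 0, true_ate_long_sbp = 0,
                        true_ate_long_dbp = 0, practice_sd = 1, seed = seed)
    pop <- generate_population(cfg)
    eps <- classify_exposure(pop$prescriptions,
                             patient_ids = pop$attributes$patient_id)
    out <- derive_outcomes(pop$bp, eps)
    grp <- eps$klass != "none"
    abs(mean(out$outcome_sbp[grp], na.rm = TRUE) -
          mean(out$outcome_sbp[!grp], na.rm = TRUE))
  }
  small <- mean(vapply(1:4, function(s) naive(8, 500 + s), numeric(1)))
  large <- mean(vapply(1:4, function(s) naive(80, 600 + s), numeric(1)))
  expect_lt(large, small)
})

test_that("MAR deletion keeps the marginal rate but tilts by age", {
  cfg <- synth_config(n_practices = 30, patients_per_practice = 300,
                      missing_mechanism = "MAR", seed = 88)
  pop <- generate_population(cfg)
  has16 <- pop$attributes$patient_id %in%
    pop$bp$patient_id[format(as.Date(pop$bp$date), "%Y") == "2016"]
  miss <- !has16
  expect_lt(abs(mean(miss) - 0.184), 0.02)
  age <- 2016 - pop$attributes$birth_year
  expect_gt(mean(miss[age < 50]), mean(miss[age >= 50]))
})

test_that("population tables serialise to delimited text and JSON truth", {
  pop <- generate_population(synth_config(n_practices = 4,
                                          patients_per_practice = 30,
                                          seed = 5))
  d <- withr::local_tempdir()
  write_population(pop, d)
  expect_setequal(list.files(d),
                  c("consultations.csv", "prescriptions.csv", "bp.csv",
                    "attributes.csv", "truth.json"))
  back <- utils::read.csv(file.path(d, "attributes.csv"))
  expect_equal(nrow(back), nrow(pop$attributes))
})
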