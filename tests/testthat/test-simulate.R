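small_cfg <- function(...) {
  sim_config(n_practices = 2, patients_per_practice = 50,
    span_start = "2000-01-01", span_end = "2012-12-31",
    registration_range = c("1995-01-01", "2008-12-31"), ...)
}

test_that("generation is reproducible from the seed and obeys the database invariants", {
  a <- simulate_ehr(small_cfg(), seed = 21L)
  b <- simulate_ehr(small_cfg(), seed = 21L)
  expect_equal(a$practices, b$practices)
  expect_equal(a$patients, b$patients)
  expect_equal(a$events, b$events)
  c <- simulate_ehr(small_cfg(), seed = 22L)
  expect_false(identical(a$events, c$events))

  expect_length(integrity(a), 0)  # generated rows never violate load rules
  expect_true(all(a$patients$practice_id %in% a$practices$practice_id))
  expect_true(all(a$events$patient_id %in% a$patients$patient_id))
  expect_true(all(a$practices$key_date <= a$practices$collection_date))
  ok_dereg <- is.na(a$patients$deregistration_date) |
    a$patients$deregistration_date >= a$patients$registration_date
  expect_true(all(ok_dereg))
})

test_that("zero exposure incidence plants no exposure events", {
  db <- simulate_ehr(small_cfg(exposure_incidence = 0), seed = 23L)
  expect_equal(sum(db$events$code %in% c("C10F.00", "C10F.11")), 0)
  expect_equal(sum(db$events$code == "RX0001"), 0)
})

test_that("impossible configurations are validation errors", {
  expect_error(sim_config(hazard_ratio = 0), "hazard_ratio")
  expect_error(sim_config(outcome_rate = -1), "non-negative")
  expect_error(sim_config(span_start = "2010-01-01", span_end = "2001-01-01"),
    "empty calendar span")
  expect_error(sim_config(registration_range = c("2010-01-01", "2001-01-01")),
    "impossible registration range")
  expect_error(sim_config(ethnicity_probs = c(1, 1, 1, 1, 1)), "sum to 1")
})

test_that("a unit hazard ratio gives equal pre- and post-exposure event rates", {
  cfg <- sim_config(n_practices = 4, patients_per_practice = 2500,
    span_start = "2000-01-01", span_end = "2012-12-31",
    registration_range = c("1995-01-01", "2008-12-31"),
    exposure_incidence = 0.05, outcome_rate = 0.02, hazard_ratio = 1,
    measurement_rate = 0, smoking_prob = 0)
  db <- simulate_ehr(cfg, seed = 24L)
  ev <- db$events
  exp_first <- ev |>
    dplyr::filter(code %in% c("C10F.00", "C10F.11")) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(exp_date = min(event_date), .groups = "drop")
  out <- ev |>
    dplyr::filter(code == "F25..00") |>
    dplyr::select(patient_id, out_date = event_date)
  pats <- db$patients |>
    dplyr::left_join(exp_first, by = "patient_id") |>
    dplyr::left_join(out, by = "patient_id") |>
    dplyr::mutate(
      rec_end = pmin(dplyr::coalesce(deregistration_date, as.Date("2999-01-01")),
        dplyr::coalesce(death_date, as.Date("2999-01-01")), as.Date("2012-12-31")),
      switch_date = dplyr::coalesce(exp_date, rec_end),
      pre_days = as.numeric(pmin(dplyr::coalesce(out_date, rec_end), switch_date) -
        registration_date),
      post_days = pmax(as.numeric(pmin(dplyr::coalesce(out_date, rec_end), rec_end) -
        switch_date), 0),
      pre_event = !is.na(out_date) & out_date <= switch_date,
      post_event = !is.na(out_date) & out_date > switch_date
    )
  pre_rate <- sum(pats$pre_event) / (sum(pats$pre_days) / 365.25)
  post_rate <- sum(pats$post_event) / (sum(pats$post_days) / 365.25)
  # Monte-Carlo standard error of the rate difference (Poisson counts)
  se <- sqrt(sum(pats$pre_event) / (sum(pats$pre_days) / 365.25)^2 +
    sum(pats$post_event) / (sum(pats$post_days) / 365.25)^2)
  expect_lt(abs(pre_rate - post_rate), 3 * se)
})

test_that("the planted unexposed rate is recovered by direct person-time accounting", {
  cfg <- sim_config(n_practices = 4, patients_per_practice = 2500,
    exposure_incidence = 0, outcome_rate = 0.01, hazard_ratio = 3,
    measurement_rate = 0, smoking_prob = 0)
  db <- simulate_ehr(cfg, seed = 25L)
  out <- db$events |>
    dplyr::filter(code == "F25..00") |>
    dplyr::select(patient_id, out_date = event_date)
  pats <- db$patients |>
    dplyr::left_join(out, by = "patient_id") |>
    dplyr::mutate(
      rec_end = pmin(dplyr::coalesce(deregistration_date, as.Date("2999-01-01")),
        dplyr::coalesce(death_date, as.Date("2999-01-01")), as.Date("2019-12-31")),
      stop = pmin(dplyr::coalesce(out_date, rec_end), rec_end),
      days = as.numeric(stop - registration_date)
    )
  events <- sum(!is.na(pats$out_date) & pats$out_date <= pats$rec_end)
  py <- sum(pats$days) / 365.25
  rate <- events / py
  se <- sqrt(events) / py
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("year-precision births appear at the configured fraction and normalise", {
  cfg <- small_cfg(year_dob_fraction = 0.5)
  db <- simulate_ehr(cfg, seed = 26L)
  yr <- db$patients$birth_precision == "year"
  expect_gt(mean(yr), 0.3)
  expect_true(all(format(db$patients$birth_date[yr], "%m-%d") == "07-01"))
})
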