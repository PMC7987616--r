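baseline_db <- function(events) {
  mini_db(mini_patient("b1"), events)
}

baseline_member <- function(index = "2006-06-01") {
  tibble::tibble(
    patient_id = "b1", practice_id = "p1", sex = "female",
    birth_date = as.Date("1960-01-01"), registration_date = as.Date("1999-01-01"),
    townsend_quintile = 3L, ethnicity = "white",
    practice_start = as.Date("2000-01-01"), practice_end = as.Date("2015-12-31"),
    patient_start = as.Date("2000-01-01"), patient_end = as.Date("2015-12-31"),
    role = "exposed_or_case", index_date = as.Date(index),
    group_id = 1L, exit_date = as.Date("2015-12-31")
  )
}

bmi_design <- function(baselines) {
  study_design("cohort",
    period = study_period("2000-01-01", "2015-12-31", entry_age_min = 18,
      entry_age_max = 90, exit_age_max = 95),
    entities = list(
      code_entity("Dx", "DX001", "inclusion", "incident_only"),
      code_entity("BMI", "BMI001", "inclusion", "incident_or_prevalent"),
      code_entity("Smoking", "SMOK01", "inclusion", "incident_or_prevalent")
    ),
    exposure_logic = "Dx", baselines = baselines)
}

test_that("baseline retrieval rules pick the declared record", {
  evs <- dplyr::bind_rows(
    mini_event("b1", "BMI001", "2004-03-24", value = 24.5, origin = "measurement"),  # index-800d
    mini_event("b1", "BMI001", "2006-05-02", value = 27.9, origin = "measurement"),  # index-30d
    mini_event("b1", "BMI001", "2009-01-01", value = 30.1, origin = "measurement")
  )
  db <- baseline_db(evs)
  design <- bmi_design(list(baseline_spec("BMI")))
  m <- baseline_member()

  latest <- extract_baseline(m, baseline_spec("BMI"), design, db)
  expect_equal(latest$value, 27.9)
  expect_equal(latest$measurement_date, as.Date("2006-05-02"))

  earliest <- extract_baseline(m, baseline_spec("BMI", "earliest_ever"), design, db)
  expect_equal(earliest$value, 24.5)

  after <- extract_baseline(m, baseline_spec("BMI", "first_after_index"), design, db)
  expect_equal(after$value, 30.1)
})

test_that("a lookback window turns an out-of-range record into a missing marker", {
  db <- baseline_db(mini_event("b1", "BMI001", "2004-03-24", value = 24.5,
    origin = "measurement"))  # 800 days before index
  design <- bmi_design(list(baseline_spec("BMI", lookback_days = 735)))
  got <- extract_baseline(baseline_member(),
    baseline_spec("BMI", lookback_days = 735), design, db)
  expect_true(is.na(got$value))
  expect_true(is.na(got$measurement_date))
  # without the lookback the same record is found
  got2 <- extract_baseline(baseline_member(), baseline_spec("BMI"), design, db)
  expect_equal(got2$value, 24.5)
})

test_that("never-recorded baselines and presence entities behave", {
  db <- baseline_db(mini_event("b1", "SMOK01", "2003-01-01"))
  design <- bmi_design(list(baseline_spec("Smoking"), baseline_spec("BMI")))
  smoke <- extract_baseline(baseline_member(), baseline_spec("Smoking"), design, db)
  expect_equal(smoke$value, 1)  # presence flag for value-less entities
  expect_equal(smoke$measurement_date, as.Date("2003-01-01"))
  bmi <- extract_baseline(baseline_member(), baseline_spec("BMI"), design, db)
  expect_true(is.na(bmi$value))
})

test_that("a cross-sectional dataset has no matching or outcome columns", {
  fix <- random_fixture(803)  # seed chosen to draw a cross-sectional design
  expect_equal(fix$design$design_type, "cross_sectional")
  res <- run_extraction(fix$db, fix$design, out_dir = withr::local_tempdir())
  expect_false(any(c("group_id", "exit_date", "follow_up_days") %in% names(res$dataset)))
  expect_false(any(grepl("_flag$", setdiff(names(res$dataset), "exposed_flag"))))
  expect_true(all(c("exposed_flag", "index_date", "patient_start") %in% names(res$dataset)))
  # unexposed members are retained as the denominator
  expect_true(any(res$dataset$exposed_flag == 0L))
})

test_that("row counts add up in a matched cohort dataset", {
  res <- run_extraction(worked_toy(), toy_design(), out_dir = withr::local_tempdir())
  n_ctl <- sum(!is.na(res$matched_sets$control_id))
  expect_equal(nrow(res$dataset), sum(res$dataset$exposed_flag == 1L) + n_ctl)
  expect_equal(res$dataset$follow_up_days,
    as.integer(res$dataset$exit_date - res$dataset$index_date))
  expect_equal(res$dataset$age_at_index,
    age_on(res$dataset$birth_date, res$dataset$index_date))
})

test_that("incidence summaries equal closed-form exact Poisson results", {
  # 44 events over exactly 100,000 person-years
  fud <- round(100000 * 365.25 / 200)
  dataset <- tibble::tibble(
    exposed_flag = 1L,
    follow_up_days = rep(fud, 200),
    Outcome_flag = rep(c(1L, 0L), c(44, 156))
  )
  ir <- summarise_incidence(dataset, "Outcome", by = character())
  expect_equal(ir$events, 44)
  expect_equal(ir$person_years, 100000, tolerance = 1e-6)
  expect_equal(ir$rate_per_1e5, 44, tolerance = 1e-6)
  # oracle: base R exact Poisson test on the same counts
  ci <- stats::poisson.test(44, 100000 / 1e5)$conf.int
  expect_equal(ir$rate_lower, ci[1], tolerance = 1e-6)
  expect_equal(ir$rate_upper, ci[2], tolerance = 1e-6)

  # zero events: rate 0 with a positive upper bound
  d0 <- dplyr::mutate(dataset, Outcome_flag = 0L)
  ir0 <- summarise_incidence(d0, "Outcome", by = character())
  expect_equal(ir0$rate_per_1e5, 0)
  expect_equal(ir0$rate_lower, 0)
  expect_gt(ir0$rate_upper, 0)
  ci0 <- stats::poisson.test(0, 1)$conf.int  # per 1e5 p-y at 1e5 p-y
  expect_equal(ir0$rate_upper, ci0[2], tolerance = 1e-6)
})

test_that("zero person-years flags the rate as undefined", {
  dataset <- tibble::tibble(exposed_flag = 1L, follow_up_days = 0L, Outcome_flag = 0L)
  ir <- summarise_incidence(dataset, "Outcome", by = character())
  expect_true(ir$rate_undefined)
  expect_true(is.na(ir$rate_per_1e5))
})

test_that("prevalence summaries equal exact binomial results", {
  dataset <- tibble::tibble(
    exposed_flag = rep(c(1L, 0L), c(33, 967)),
    patient_start = as.Date("2000-01-01"),
    patient_end = as.Date("2016-12-31")
  )
  pr <- summarise_prevalence(dataset, "2016-07-01")
  expect_equal(pr$cases, 33)
  expect_equal(pr$population, 1000)
  expect_equal(pr$prevalence, 0.033)
  ci <- stats::binom.test(33, 1000)$conf.int
  expect_equal(pr$prev_lower, ci[1], tolerance = 1e-8)
  expect_equal(pr$prev_upper, ci[2], tolerance = 1e-8)
  # members not registered on the reference date leave the denominator
  dataset$patient_end[1:100] <- as.Date("2010-01-01")
  pr2 <- summarise_prevalence(dataset, "2016-07-01")
  expect_equal(pr2$population, 900)
})

test_that("summaries equal a naive per-patient loop on a fixture dataset", {
  res <- run_extraction(worked_toy(), toy_design(), out_dir = withr::local_tempdir())
  ir <- summarise_incidence(res$dataset, "Stroke")
  for (g in ir$exposed_flag) {
    rows <- res$dataset[res$dataset$exposed_flag == g, ]
    ev <- 0; py <- 0
    for (i in seq_len(nrow(rows))) {
      ev <- ev + rows$Stroke_flag[i]
      py <- py + rows$follow_up_days[i] / 365.25
    }
    expect_equal(ir$events[ir$exposed_flag == g], ev)
    expect_equal(ir$person_years[ir$exposed_flag == g], py)
    expect_equal(ir$rate_per_1e5[ir$exposed_flag == g], ev / py * 1e5)
  }
})
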