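# members built directly (windows already resolved) for matching tests
mk_member <- function(id, sex, birth, role, index = NA, start = "2000-01-01",
                      end = "2015-12-31", reg = "1999-01-01", townsend = 3L,
                      eth = "white", practice = "p1") {
  tibble::tibble(
    patient_id = id, practice_id = practice, sex = sex,
    birth_date = as.Date(birth), registration_date = as.Date(reg),
    townsend_quintile = townsend, ethnicity = eth,
    practice_start = as.Date("2000-01-01"), practice_end = as.Date("2015-12-31"),
    patient_start = as.Date(start), patient_end = as.Date(end),
    role = role,
    index_date = if (is.na(index)) as.Date(NA_real_, origin = "1970-01-01") else as.Date(index),
    group_id = NA_integer_,
    exit_date = as.Date(NA_real_, origin = "1970-01-01")
  )
}

simple_match_design <- function(criteria) {
  study_design("cohort",
    period = study_period("2000-01-01", "2015-12-31", entry_age_min = 18,
      entry_age_max = 90, exit_age_max = 95),
    entities = list(
      code_entity("Dx", "DX001", "inclusion", "incident_only"),
      code_entity("HbA1c", "42W5.00", "inclusion", "incident_or_prevalent"),
      code_entity("Stroke", "STRK01", "inclusion", "first_after_entry")
    ),
    exposure_logic = "Dx", controls_required = TRUE,
    match_criteria = criteria)
}

test_that("age and sex tolerances select exactly the compatible candidates", {
  # exposed F aged 50 at index; pool F49, F52, M50; age +-1, same sex
  exposed <- mk_member("e1", "female", "1955-06-01", "exposed_or_case",
    index = "2005-06-01")
  pool <- dplyr::bind_rows(
    mk_member("f49", "female", "1956-01-01", "potential_control"),
    mk_member("f52", "female", "1953-03-01", "potential_control"),
    mk_member("m50", "male", "1955-06-01", "potential_control")
  )
  design <- simple_match_design(match_criteria(4, age_tolerance_years = 1,
    sex_match = "yes"))
  db <- mini_db(mini_patient("zz"))
  got <- eligible_controls(exposed, pool, design$match_criteria, design, db)
  expect_equal(got$patient_id, "f49")
  # empty pool
  expect_equal(nrow(eligible_controls(exposed, pool[0, ], design$match_criteria,
    design, db)), 0)
})

test_that("the matching filter agrees with an independent brute-force filter", {
  set.seed(701)
  n <- 40
  pool <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    mk_member(sprintf("c%02d", i),
      sample(c("female", "male"), 1),
      as.Date("1950-01-01") + sample.int(8000, 1),
      "potential_control",
      start = as.Date("2000-01-01") + sample.int(1000, 1),
      end = as.Date("2010-01-01") + sample.int(1500, 1),
      reg = as.Date("1995-01-01") + sample.int(3000, 1),
      townsend = sample(1:5, 1), eth = sample(c("white", "asian"), 1))
  }))
  exposed <- mk_member("e1", "female", "1957-07-07", "exposed_or_case",
    index = "2006-06-06", reg = "1999-09-09", townsend = 3L)
  events <- dplyr::bind_rows(
    # exposed HbA1c history + a diabetes record for duration matching
    mini_event("e1", "42W5.00", "2005-09-01", value = 48, origin = "measurement"),
    mini_event("e1", "DX001", "2003-01-01"),
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      id <- sprintf("c%02d", i)
      out <- list()
      if (runif(1) < 0.7) {
        out <- c(out, list(mini_event(id, "42W5.00",
          as.Date("2004-06-06") + sample.int(900, 1),
          value = 48 + rnorm(1, 0, 3), origin = "measurement")))
      }
      if (runif(1) < 0.5) {
        out <- c(out, list(mini_event(id, "DX001",
          as.Date("2002-01-01") + sample.int(1500, 1))))
      }
      if (runif(1) < 0.2) {
        out <- c(out, list(mini_event(id, "STRK01",
          as.Date("2004-01-01") + sample.int(1500, 1))))
      }
      dplyr::bind_rows(out)
    }))
  )
  pats <- dplyr::bind_rows(lapply(c("e1", sprintf("c%02d", seq_len(n))),
    mini_patient))
  db <- mini_db(pats, events)
  criteria <- match_criteria(4, age_tolerance_years = 1, sex_match = "yes",
    registration_tolerance_days = 1500,
    exposure_duration = list(entity = "Dx", tolerance_days = 600),
    measurement_matches = list(list(entity = "HbA1c", lookback_days = 735,
      value_tolerance = 2)),
    exclude_outcomes_before_index = "Stroke")
  design <- simple_match_design(criteria)
  got <- eligible_controls(exposed, pool, criteria, design, db)

  # independent re-check, one candidate at a time, straight from the rules
  idx <- as.Date("2006-06-06")
  first_ev <- function(id, code) {
    d <- events$event_date[events$patient_id == id & events$code == code]
    if (length(d)) min(d) else as.Date(NA_real_, origin = "1970-01-01")
  }
  latest_val <- function(id) {
    sel <- events$patient_id == id & events$code == "42W5.00" &
      events$event_date >= idx - 735 & events$event_date <= idx
    if (!any(sel)) return(NA_real_)
    events$value[sel][which.max(events$event_date[sel])]
  }
  expect_dur <- as.numeric(idx - first_ev("e1", "DX001"))
  v_e <- latest_val("e1")
  manual <- pool$patient_id[vapply(seq_len(nrow(pool)), function(i) {
    p <- pool[i, ]
    ok <- p$sex == "female" &&
      p$patient_start <= idx && idx <= p$patient_end &&
      abs(age_on(p$birth_date, idx) - age_on(exposed$birth_date, idx)) <= 1 &&
      abs(as.numeric(p$registration_date - exposed$registration_date)) <= 1500
    dur_c <- as.numeric(idx - first_ev(p$patient_id, "DX001"))
    ok <- ok && !is.na(dur_c) && abs(dur_c - expect_dur) <= 600
    v_c <- latest_val(p$patient_id)
    ok <- ok && !is.na(v_c) && abs(v_c - v_e) <= 2
    strk <- first_ev(p$patient_id, "STRK01")
    ok <- ok && !(!is.na(strk) && strk <= idx)
    isTRUE(ok)
  }, TRUE)]
  expect_setequal(got$patient_id, manual)
})

test_that("townsend, ethnicity and opposite-sex rules filter as declared", {
  exposed <- mk_member("e1", "female", "1955-06-01", "exposed_or_case",
    index = "2005-06-01", townsend = 2L, eth = "asian")
  pool <- dplyr::bind_rows(
    mk_member("a", "male", "1955-06-01", "potential_control", townsend = 2L, eth = "asian"),
    mk_member("b", "female", "1955-06-01", "potential_control", townsend = 2L, eth = "asian"),
    mk_member("c", "male", "1955-06-01", "potential_control", townsend = 4L, eth = "asian"),
    mk_member("d", "male", "1955-06-01", "potential_control", townsend = 2L, eth = "white")
  )
  criteria <- match_criteria(4, age_tolerance_years = 0, sex_match = "opposite",
    match_townsend = TRUE, match_ethnicity = TRUE)
  design <- simple_match_design(criteria)
  db <- mini_db(mini_patient("zz"))
  got <- eligible_controls(exposed, pool, criteria, design, db)
  expect_equal(got$patient_id, "a")
})

test_that("without-replacement selection empties a shared pool greedily", {
  members <- dplyr::bind_rows(
    mk_member("e1", "female", "1955-06-01", "exposed_or_case", index = "2005-06-01"),
    mk_member("e2", "female", "1955-06-01", "exposed_or_case", index = "2005-06-01"),
    dplyr::bind_rows(lapply(sprintf("c%d", 1:4), function(id) {
      mk_member(id, "female", "1955-06-01", "potential_control")
    }))
  )
  design <- simple_match_design(match_criteria(4, age_tolerance_years = 0,
    sex_match = "yes"))
  db <- mini_db(mini_patient("zz"))
  r <- run_stage4(members, design, db, seed = 5L)
  # one exposed takes all four, the other none
  got <- r$matched_sets |> dplyr::filter(!is.na(control_id))
  expect_equal(nrow(got), 4)
  expect_equal(dplyr::n_distinct(got$exposed_id), 1)
  expect_equal(anyDuplicated(got$control_id), 0)
  expect_equal(r$unmatched_exposed,
    setdiff(c("e1", "e2"), got$exposed_id))
})

test_that("matching is reproducible under a fixed seed", {
  fix <- random_fixture(702)  # seed chosen to draw a matched cohort design
  expect_equal(fix$design$design_type, "cohort")
  expect_false(is.null(fix$design$match_criteria))
  db <- fix$db
  s1 <- run_stage1(db, fix$design)
  s2 <- run_stage2(s1$members, fix$design, db, s1$log)
  r1 <- run_stage4(s2$members, fix$design, db, seed = 99L)
  r2 <- run_stage4(s2$members, fix$design, db, seed = 99L)
  expect_identical(r1$matched_sets, r2$matched_sets)
  expect_identical(r1$members, r2$members)
})

test_that("selection among equivalent candidates is uniform over seeds", {
  members <- dplyr::bind_rows(
    mk_member("e1", "female", "1955-06-01", "exposed_or_case", index = "2005-06-01"),
    dplyr::bind_rows(lapply(sprintf("c%d", 1:6), function(id) {
      mk_member(id, "female", "1955-06-01", "potential_control")
    }))
  )
  design <- simple_match_design(match_criteria(1, age_tolerance_years = 0,
    sex_match = "yes"))
  db <- mini_db(mini_patient("zz"))
  n_seeds <- 600
  picks <- vapply(seq_len(n_seeds), function(s) {
    r <- run_stage4(members, design, db, seed = s)
    r$matched_sets$control_id[1]
  }, "")
  tab <- table(picks)
  expect_equal(length(tab), 6)
  # binomial 99% band around n/6
  p <- 1 / 6
  half <- qnorm(0.995) * sqrt(n_seeds * p * (1 - p))
  expect_true(all(abs(as.integer(tab) - n_seeds * p) <= half + 3))
})
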