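# a two-patient candidate frame with explicit windows
cand_members <- function(db, design) run_stage1(db, design)$members

dx_db <- function(events) {
  pats <- dplyr::bind_rows(
    mini_patient("x1", reg = "2002-05-01", birth = "1960-01-01"),
    mini_patient("x2", reg = "2000-01-01", birth = "1955-01-01")
  )
  mini_db(pats, events)
}

test_that("locate_entity implements the three inclusion semantics", {
  design <- mini_design()
  db <- dx_db(dplyr::bind_rows(
    mini_event("x1", "DX001", "1999-06-01"),   # before x1's start (2002-05-01)
    mini_event("x1", "DX001", "2005-01-01"),
    mini_event("x2", "DX001", "2004-03-03")
  ))
  members <- cand_members(db, design)

  inc <- locate_entity(members, code_entity("E", "DX001", "inclusion", "incident_only"), db)
  expect_true(inc$prevalent_reject[inc$patient_id == "x1"])  # earliest is pre-entry
  expect_equal(inc$hit_date[inc$patient_id == "x2"], as.Date("2004-03-03"))

  iop <- locate_entity(members, code_entity("E", "DX001", "inclusion", "incident_or_prevalent"), db)
  expect_false(iop$prevalent_reject[iop$patient_id == "x1"])
  # pre-entry record contributes the patient start date
  expect_equal(iop$hit_date[iop$patient_id == "x1"], as.Date("2002-05-01"))

  fae <- locate_entity(members, code_entity("E", "DX001", "inclusion", "first_after_entry"), db)
  # pre-entry record ignored; first in-window one found
  expect_equal(fae$hit_date[fae$patient_id == "x1"], as.Date("2005-01-01"))
})

test_that("a lone event after patient end is never located", {
  design <- mini_design()
  db <- dx_db(mini_event("x1", "DX001", "2019-06-01"))  # after study end 2015-12-31
  members <- cand_members(db, design)
  for (ty in c("incident_only", "incident_or_prevalent", "first_after_entry")) {
    loc <- locate_entity(members, code_entity("E", "DX001", "inclusion", ty), db)
    expect_true(is.na(loc$hit_date[loc$patient_id == "x1"]), info = ty)
  }
})

two_entity_design <- function(mode, controls = TRUE, ...) {
  study_design("cohort",
    period = study_period("2000-01-01", "2015-12-31", entry_age_min = 18,
      entry_age_max = 90, exit_age_max = 95),
    entities = list(
      code_entity("Type2Diabetes", c("C10F.00", "C10F.11"), "inclusion", "incident_only"),
      code_entity("Metformin", "RX0001", "inclusion", "incident_only"),
      code_entity("Stroke", "STRK01", "inclusion", "first_after_entry"),
      code_entity("Palliative", "PALL01", "exclusion", "exclude_ever"),
      code_entity("PriorMI", "MI0001", "exclusion", "exclude_before_index")
    ),
    exposure_logic = "Type2Diabetes and Metformin", parsing_mode = mode,
    controls_required = controls,
    match_criteria = if (controls) match_criteria(1, age_tolerance_years = 50,
      sex_match = "any"),
    ...)
}

test_that("stage 2 assigns the latest needed date as index under loose parsing", {
  db <- dx_db(dplyr::bind_rows(
    mini_event("x1", "C10F.00", "2005-03-01"),
    mini_event("x1", "RX0001", "2007-06-15", origin = "therapy")
  ))
  design <- two_entity_design("loose")
  r <- run_stage2(cand_members(db, design), design, db)
  x1 <- r$members[r$members$patient_id == "x1", ]
  expect_equal(x1$role, "exposed_or_case")
  expect_equal(x1$index_date, as.Date("2007-06-15"))
  # x2 has no diabetes code and controls are required
  expect_equal(r$members$role[r$members$patient_id == "x2"], "potential_control")
})

test_that("strict parsing rejects out-of-order sequences with a documented reason", {
  db <- dx_db(dplyr::bind_rows(
    mini_event("x1", "RX0001", "2005-03-01", origin = "therapy"),
    mini_event("x1", "C10F.00", "2007-06-15")
  ))
  design <- two_entity_design("strict")
  r <- run_stage2(cand_members(db, design), design, db)
  expect_false("x1" %in% r$members$patient_id)
  counts <- rejection_counts(r$log)
  expect_equal(counts$count[counts$reason == "exposure order violated"], 1)
})

test_that("unsatisfied logic without controls is a documented rejection", {
  db <- dx_db(mini_event("x1", "C10F.00", "2005-03-01"))
  design <- two_entity_design("loose", controls = FALSE)
  r <- run_stage2(cand_members(db, design), design, db)
  expect_equal(nrow(r$members), 0)
  counts <- rejection_counts(r$log)
  expect_equal(sum(counts$count[counts$reason == "exposure logic unsatisfied"]), 2)
})

test_that("exclusions remove exposed members: ever-recorded, pre-index, pre-index outcome", {
  base <- dplyr::bind_rows(
    mini_event("x1", "C10F.00", "2005-03-01"),
    mini_event("x1", "RX0001", "2006-06-06", origin = "therapy"),
    mini_event("x2", "C10F.00", "2004-01-01"),
    mini_event("x2", "RX0001", "2004-02-02", origin = "therapy")
  )
  design <- two_entity_design("loose", outcomes = "Stroke",
    pre_index_outcome_exclusion = TRUE)

  # ever-recorded exclusion fires even for an event after patient end
  db <- dx_db(dplyr::bind_rows(base, mini_event("x1", "PALL01", "2019-12-01")))
  r <- run_stage2(cand_members(db, design), design, db)
  expect_false("x1" %in% r$members$patient_id)
  expect_true(any(grepl("ever recorded.*Palliative", r$log$reason)))

  # before-index exclusion: event on the index day counts as pre-index
  db <- dx_db(dplyr::bind_rows(base, mini_event("x2", "MI0001", "2004-02-02")))
  r <- run_stage2(cand_members(db, design), design, db)
  expect_false("x2" %in% r$members$patient_id)
  expect_true(any(grepl("before index.*PriorMI", r$log$reason)))

  # outcome the day before index rejects when pre-index exclusion is on
  db <- dx_db(dplyr::bind_rows(base, mini_event("x1", "STRK01", "2006-06-05")))
  r <- run_stage2(cand_members(db, design), design, db)
  expect_false("x1" %in% r$members$patient_id)
  expect_true(any(grepl("outcome before index.*Stroke", r$log$reason)))

  # no exclusion events: both exposed members kept
  db <- dx_db(base)
  r <- run_stage2(cand_members(db, design), design, db)
  expect_setequal(r$members$patient_id, c("x1", "x2"))
})

test_that("stage 3 refines the pool with control logic and matches a brute-force count", {
  pats <- dplyr::bind_rows(lapply(sprintf("k%d", 1:5), mini_patient,
    birth = "1965-01-01", reg = "2000-01-01"))
  evs <- dplyr::bind_rows(
    mini_event("k1", "C10F.00", "2004-01-01"),
    mini_event("k2", "C10F.00", "2006-01-01"),
    mini_event("k3", "C10F.00", "2008-01-01")
  )
  db <- mini_db(pats, evs)
  design <- study_design("cohort",
    period = study_period("2000-01-01", "2015-12-31", entry_age_min = 18,
      entry_age_max = 90, exit_age_max = 95),
    entities = list(
      code_entity("Type2Diabetes", c("C10F.00", "C10F.11"), "inclusion", "incident_only"),
      code_entity("Never", "NOPE01", "inclusion", "incident_only")
    ),
    exposure_logic = "Never",  # nobody qualifies: everyone is a potential control
    controls_required = TRUE,
    control_logic = "Type2Diabetes",
    match_criteria = match_criteria(1, age_tolerance_years = 50, sex_match = "any"))
  s1 <- run_stage1(db, design)
  s2 <- run_stage2(s1$members, design, db, s1$log)
  expect_equal(sum(s2$members$role == "potential_control"), 5)
  s3 <- run_stage3(s2$members, design, db, s2$log)
  pool <- s3$members[s3$members$role == "potential_control", ]
  expect_setequal(pool$patient_id, c("k1", "k2", "k3"))
  # provisional entity date kept, index date cleared
  expect_equal(sort(pool$control_entity_date),
    as.Date(c("2004-01-01", "2006-01-01", "2008-01-01")))
  expect_true(all(is.na(pool$index_date)))
  counts <- rejection_counts(s3$log)
  expect_equal(counts$count[counts$reason == "control logic unsatisfied"], 2)
})

test_that("an empty control logic leaves the pool unchanged", {
  fix <- random_fixture(510)
  design <- fix$design
  db <- fix$db
  s1 <- run_stage1(db, design)
  s2 <- run_stage2(s1$members, design, db, s1$log)
  s3 <- run_stage3(s2$members, design, db, s2$log)
  expect_equal(
    dplyr::select(s3$members, -dplyr::any_of("control_entity_date")),
    s2$members)
  expect_equal(nrow(s3$log), nrow(s2$log))
})

test_that("every exposed index date lies inside the observation window", {
  for (seed in c(601, 602, 603)) {
    fix <- random_fixture(seed)
    s1 <- run_stage1(fix$db, fix$design)
    s2 <- run_stage2(s1$members, fix$design, fix$db, s1$log)
    exp <- s2$members[s2$members$role == "exposed_or_case", ]
    expect_true(all(exp$index_date >= exp$patient_start))
    expect_true(all(exp$index_date <= exp$patient_end))
    # partition: counts conserve across stage 2
    expect_equal(nrow(s2$members) + nrow(s2$log) - nrow(s1$log), nrow(s1$members))
  }
})
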