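# Small programmatic fixtures shared across tests.

mini_practices <- function() {
  tibble::tibble(
    practice_id = c("p1", "p2"),
    key_date = as.Date(c("1995-01-01", "1999-06-30")),
    collection_date = as.Date(c("2018-05-01", "2018-05-01"))
  )
}

mini_patient <- function(id, sex = "female", birth = "1960-01-01",
                         reg = "1995-01-01", dereg = NA, death = NA,
                         practice = "p1", townsend = 3L, eth = "white",
                         prec = "day") {
  na_d <- as.Date(NA_real_, origin = "1970-01-01")
  tibble::tibble(
    patient_id = id, practice_id = practice, sex = sex,
    birth_date = as.Date(birth), birth_precision = prec,
    registration_date = as.Date(reg),
    deregistration_date = if (is.na(dereg)) na_d else as.Date(dereg),
    death_date = if (is.na(death)) na_d else as.Date(death),
    townsend_quintile = townsend, ethnicity = eth
  )
}

mini_event <- function(id, code, date, value = NA_real_,
                       origin = "clinical") {
  tibble::tibble(patient_id = id, code = code, event_date = as.Date(date),
    value = value, unit = NA_character_, table_of_origin = origin)
}

empty_events <- function() mini_event(character(), character(), as.Date(character()))[0, ]

mini_db <- function(patients, events = empty_events(), practices = mini_practices()) {
  ehr_db(practices, patients, events)
}

# a small design over one inclusion entity, configurable
mini_design <- function(..., entities = NULL, exposure_logic = "Dx",
                        period = study_period("2000-01-01", "2015-12-31",
                          entry_age_min = 18, entry_age_max = 90,
                          exit_age_max = 95)) {
  if (is.null(entities)) {
    entities <- list(code_entity("Dx", "DX001", "inclusion", "incident_only"))
  }
  study_design(design_type = "cohort", period = period, entities = entities,
    exposure_logic = exposure_logic, ...)
}

# randomized small population + design used by the conservation and
# fuzz properties; everything derives from the seed
random_fixture <- function(seed) {
  set.seed(seed)
  cfg <- sim_config(
    n_practices = 2,
    patients_per_practice = sample(15:35, 1),
    span_start = "2000-01-01", span_end = "2014-12-31",
    birth_year_range = c(1935, 1985),
    registration_range = c("1990-01-01", "2010-12-31"),
    exposure_incidence = runif(1, 0.01, 0.08),
    outcome_rate = runif(1, 0.001, 0.02),
    hazard_ratio = runif(1, 0.5, 4),
    measurement_rate = 0.3,
    rx_prob = runif(1, 0.5, 1)
  )
  db <- simulate_ehr(cfg, seed = seed + 1L)

  kind <- seed %% 3
  period <- study_period("2000-06-01", "2014-06-30", entry_age_min = 18,
    entry_age_max = 85, exit_age_max = 90,
    sex_filter = sample(c("any", "any", "female", "male"), 1))
  ents <- list(
    code_entity("Exposure", c("C10F.00", "C10F.11"), "inclusion",
      sample(c("incident_only", "incident_or_prevalent", "first_after_entry"), 1)),
    code_entity("Rx", "RX0001", "inclusion", "incident_only"),
    code_entity("Outcome", "F25..00", "inclusion", "first_after_entry")
  )
  if (kind == 0) {
    design <- study_design("cohort", period, ents,
      exposure_logic = "Exposure and Rx",
      parsing_mode = sample(c("loose", "strict"), 1),
      controls_required = TRUE,
      match_criteria = match_criteria(sample(1:3, 1),
        age_tolerance_years = sample(2:10, 1), sex_match = "yes",
        unmatched = sample(c("keep", "drop"), 1)),
      outcomes = "Outcome",
      pre_index_outcome_exclusion = sample(c(TRUE, FALSE), 1),
      seed = seed + 2L)
  } else if (kind == 1) {
    design <- study_design("cohort", period, ents,
      exposure_logic = "Exposure or Rx", parsing_mode = "loose",
      controls_required = FALSE, outcomes = "Outcome", seed = seed + 2L)
  } else {
    design <- study_design("cross_sectional", period, ents,
      exposure_logic = "Exposure", parsing_mode = "loose", seed = seed + 2L)
  }
  list(db = db, design = design)
}
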