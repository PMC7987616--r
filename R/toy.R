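#' A tiny hand-auditable study population
#'
#' `worked_toy()` returns a fixed three-practice, forty-patient database
#' and `toy_design()` its companion matched-cohort design (strict
#' "Diabetes and Metformin" exposure, two age- and sex-matched controls
#' per exposed, stroke outcome with pre-index exclusion, BMI and smoking
#' baselines).  Every patient is constructed to exercise one documented
#' pipeline path — in-order and out-of-order exposure sequences,
#' prevalent-at-entry records, pre-index outcomes, an ever-recorded
#' exclusion, a year-precision birth date, death/deregistration censoring,
#' an exposed patient with no eligible control, and a practice whose
#' collection predates the study — so the correct stage-by-stage outputs
#' can be verified by hand.  Generation is deterministic: repeated calls
#' give identical objects.
#'
#' @return `worked_toy()`: an [ehr_db()]; `toy_design()`: a
#'   [study_design()].
#' @export
worked_toy <- function() {
  practices <- tibble(
    practice_id = c("pr1", "pr2", "pr3"),
    key_date = as.Date(c("1995-06-01", "2003-05-10", "1998-01-01")),
    # pr3 stopped collecting before the study starts: empty practice window
    collection_date = as.Date(c("2014-06-30", "2016-03-01", "1999-06-01"))
  )

  na_date <- as.Date(NA_real_, origin = "1970-01-01")
  p <- function(id, pr, sex, birth, reg, dereg = NA, death = NA,
                townsend = 3L, eth = "white", prec = "day") {
    tibble(patient_id = id, practice_id = pr, sex = sex,
      birth_date = as.Date(birth), birth_precision = prec,
      registration_date = as.Date(reg),
      deregistration_date = if (is.na(dereg)) na_date else as.Date(dereg),
      death_date = if (is.na(death)) na_date else as.Date(death),
      townsend_quintile = townsend, ethnicity = eth)
  }
  patients <- bind_rows(
    # --- exposed (in-order strict sequences) ---
    p("T01", "pr1", "female", "1960-04-15", "1998-03-01"),
    p("T04", "pr1", "male",   "1948-11-05", "1990-01-01", dereg = "2008-10-31"),
    p("T07", "pr1", "female", "1990-12-01", "2005-01-01", prec = "year"),
    p("T08", "pr1", "male",   "1930-01-01", "1995-01-01", death = "2009-07-01"),
    p("T09", "pr2", "female", "1980-03-10", "2001-01-01"),
    p("T12", "pr1", "male",   "1970-06-06", "2013-06-01", dereg = "2013-09-01"),
    p("T13", "pr1", "male",   "1996-01-01", "2012-01-01"),  # no age-compatible control
    # --- rejected at stage 2 ---
    p("T02", "pr1", "male",   "1955-07-20", "2001-09-01"),  # out-of-order sequence
    p("T03", "pr1", "female", "1970-01-30", "2002-05-01"),  # prevalent at entry
    p("T05", "pr1", "female", "1964-02-29", "1999-01-01"),  # stroke before index
    p("T06", "pr1", "male",   "1975-08-08", "2000-02-01"),  # palliative ever-recorded
    p("T37", "pr1", "female", "1969-09-29", "1998-11-01"),  # out-of-order sequence
    p("T38", "pr1", "male",   "1940-06-10", "1996-06-01"),  # prevalent at entry
    # --- rejected at stage 1 ---
    p("T10", "pr1", "male",   "2000-05-05", "2000-06-01"),  # turns 18 after practice end
    p("T11", "pr1", "female", "1915-01-01", "1990-01-01"),  # over max entry age
    p("T33", "pr3", "male",   "1965-01-01", "1998-06-01"),  # practice window empty
    p("T34", "pr3", "female", "1972-02-02", "1998-07-01"),  # practice window empty
    p("T35", "pr1", "female", "1959-12-31", "2014-07-01"),  # registered after practice end
    # --- potential controls ---
    p("T14", "pr1", "female", "1961-05-20", "1999-01-01"),  # diabetes only
    p("T15", "pr1", "female", "1958-09-09", "2000-03-01"),
    p("T16", "pr1", "male",   "1950-02-02", "1995-05-01"),  # metformin only
    p("T17", "pr1", "male",   "1946-12-12", "2001-01-01"),
    p("T18", "pr1", "female", "1963-03-03", "1998-01-01"),  # stroke before any index
    p("T19", "pr1", "male",   "1972-04-04", "2000-01-01"),
    p("T20", "pr1", "male",   "1968-10-10", "2005-06-01"),
    p("T21", "pr2", "female", "1978-07-07", "2004-01-01"),
    p("T22", "pr2", "female", "1984-02-10", "2002-02-01"),
    p("T23", "pr1", "female", "1932-06-15", "1999-09-01"),
    p("T24", "pr1", "male",   "1929-04-01", "1998-01-01"),  # control with post-index stroke
    p("T25", "pr1", "male",   "1935-10-20", "2000-05-01"),
    p("T26", "pr1", "female", "1959-11-11", "2001-07-01", dereg = "2006-06-01"),
    p("T27", "pr1", "female", "1988-12-25", "2006-01-01"),
    p("T28", "pr1", "female", "1992-03-30", "2008-01-01"),
    p("T29", "pr1", "male",   "1944-08-18", "1999-01-01", death = "2001-05-01"),
    p("T30", "pr1", "female", "1966-06-06", "2003-03-03"),
    p("T31", "pr1", "male",   "1953-01-17", "1997-04-01"),  # diabetes only
    p("T32", "pr1", "male",   "1951-07-02", "2002-08-01"),
    p("T36", "pr1", "male",   "1985-05-15", "2004-04-04"),
    p("T39", "pr1", "female", "1973-02-14", "2000-09-01"),
    p("T40", "pr1", "male",   "1958-03-05", "1999-10-01")
  )

  e <- function(id, code, date, value = NA_real_, unit = NA_character_,
                origin = "clinical") {
    tibble(patient_id = id, code = code, event_date = as.Date(date),
      value = value, unit = unit, table_of_origin = origin)
  }
  events <- bind_rows(
    # exposed sequences (diabetes then metformin)
    e("T01", "C10F.00", "2005-03-01"), e("T01", "RX0001", "2007-06-15", origin = "therapy"),
    e("T04", "C10F.11", "2003-04-04"), e("T04", "RX0001", "2003-04-04", origin = "therapy"),
    e("T07", "C10F.00", "2010-10-10"), e("T07", "RX0001", "2011-11-11", origin = "therapy"),
    e("T08", "C10F.00", "2001-02-03"), e("T08", "RX0001", "2002-03-04", origin = "therapy"),
    e("T09", "C10F.00", "2004-01-01"), e("T09", "RX0001", "2004-06-01", origin = "therapy"),
    e("T12", "C10F.11", "2013-07-01"), e("T12", "RX0001", "2013-08-01", origin = "therapy"),
    e("T13", "C10F.00", "2014-02-01"), e("T13", "RX0001", "2014-03-01", origin = "therapy"),
    # out-of-order sequences (metformin first)
    e("T02", "RX0001", "2004-02-10", origin = "therapy"), e("T02", "C10F.00", "2006-08-01"),
    e("T37", "RX0001", "2001-01-01", origin = "therapy"), e("T37", "C10F.00", "2010-10-01"),
    # prevalent-at-entry diabetes
    e("T03", "C10F.00", "1999-06-01"), e("T03", "RX0001", "2003-06-01", origin = "therapy"),
    e("T38", "C10F.00", "1995-01-01"),
    # exposed but excluded
    e("T05", "C10F.00", "2004-05-01"), e("T05", "RX0001", "2006-01-20", origin = "therapy"),
    e("T05", "STRK01", "2005-12-01"),
    e("T06", "C10F.00", "2005-05-05"), e("T06", "RX0001", "2008-08-08", origin = "therapy"),
    e("T06", "PALL01", "2013-01-01"),
    # single-entity control-pool records
    e("T14", "C10F.00", "2006-01-01"),
    e("T16", "RX0001", "2005-01-01", origin = "therapy"),
    e("T31", "C10F.00", "2012-12-01"),
    # strokes
    e("T01", "STRK01", "2010-01-10"),
    e("T09", "STRK01", "2015-11-30"),
    e("T18", "STRK01", "2002-01-01"),
    e("T24", "STRK01", "2003-03-03"),
    # baseline measurements
    e("T01", "BMI001", "2003-01-15", value = 25.1, unit = "kg/m2", origin = "measurement"),
    e("T01", "BMI001", "2006-09-01", value = 28.4, unit = "kg/m2", origin = "measurement"),
    e("T07", "BMI001", "2011-05-05", value = 22.0, unit = "kg/m2", origin = "measurement"),
    e("T01", "SMOK01", "2001-01-01"),
    e("T12", "SMOK01", "2013-06-15")
  )
  ehr_db(practices, patients, events)
}

#' @rdname worked_toy
#' @export
toy_design <- function() {
  study_design(
    design_type = "cohort",
    period = study_period("2000-01-01", "2015-12-31",
      entry_age_min = 18, entry_age_max = 80, exit_age_max = 85),
    entities = list(
      code_entity("Diabetes", c("C10F.00", "C10F.11"), "inclusion", "incident_only"),
      code_entity("Metformin", "RX0001", "inclusion", "incident_only"),
      code_entity("Palliative", "PALL01", "exclusion", "exclude_ever"),
      code_entity("Stroke", "STRK01", "inclusion", "first_after_entry"),
      code_entity("BMI", "BMI001", "inclusion", "incident_or_prevalent"),
      code_entity("Smoking", "SMOK01", "inclusion", "incident_or_prevalent")
    ),
    exposure_logic = "Diabetes and Metformin",
    parsing_mode = "strict",
    controls_required = TRUE,
    match_criteria = match_criteria(
      n_controls_per_exposed = 2,
      age_tolerance_years = 5,
      sex_match = "yes",
      unmatched = "keep"
    ),
    outcomes = "Stroke",
    pre_index_outcome_exclusion = TRUE,
    baselines = list(
      baseline_spec("BMI", "latest_before_index", lookback_days = 1095),
      baseline_spec("Smoking", "latest_before_index")
    ),
    seed = 42L
  )
}
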