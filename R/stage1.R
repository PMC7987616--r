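#' Stage 1: practice and patient observation windows
#'
#' `practice_window()` derives each practice's eligible period:
#' start = latest of (key date + offset, study start);
#' end = earliest of (study end, collection date).  A practice whose start
#' exceeds its end contributes no patients.
#'
#' `patient_window()` derives the patient-level window inside the practice
#' window:
#' start = latest of (registration + lead-in, practice start, the date the
#' patient attains the minimum entry age);
#' end = earliest of (practice end, deregistration, death, the last day at
#' or below the maximum exit age).  Patients failing the sex filter, older
#' than the maximum entry age at their start date, or with an empty window
#' are rejected with a documented reason.
#'
#' @param practices tibble of practices (columns `practice_id`, `key_date`,
#'   `collection_date`).
#' @param spec a [study_period()].
#' @return `practice_window()`: the input with `practice_start`,
#'   `practice_end` and logical `practice_ok` columns.
#' @export
practice_window <- function(practices, spec) {
  practices |>
    mutate(
      practice_start = pmax_date(.data$key_date + spec$key_date_offset_days, spec$study_start),
      practice_end = pmin_date(spec$study_end, .data$collection_date),
      practice_ok = .data$practice_start <= .data$practice_end
    )
}

#' @rdname practice_window
#' @param patients patient tibble already joined to practice windows
#'   (columns `practice_start`, `practice_end` present).
#' @return `patient_window()`: the input with `patient_start`,
#'   `patient_end` and a `reject_reason` column (`NA` = retained).  The
#'   reason recorded is the first failing check, in the documented order:
#'   entry age, sex filter, window overlap, window validity.
#' @export
patient_window <- function(patients, spec) {
  out <- patients |>
    mutate(
      patient_start = pmax_date(
        .data$registration_date + spec$registration_leadin_days,
        .data$practice_start,
        add_years(.data$birth_date, spec$entry_age_min)
      ),
      patient_end = pmin_date(
        .data$practice_end,
        .data$deregistration_date,
        .data$death_date,
        add_years(.data$birth_date, spec$exit_age_max + 1L) - 1L
      ),
      age_at_start = age_on(.data$birth_date, .data$patient_start)
    )
  out |>
    mutate(reject_reason = dplyr::case_when(
      .data$age_at_start > spec$entry_age_max ~ "older than maximum entry age at patient start",
      spec$sex_filter != "any" & .data$sex != spec$sex_filter ~ "sex does not match study population",
      # literal strict overlap reading: start strictly before practice end,
      # end strictly after practice start
      !(.data$patient_start < .data$practice_end & .data$patient_end > .data$practice_start) ~
        "patient window outside practice window",
      .data$patient_start > .data$patient_end ~ "empty patient window",
      TRUE ~ NA_character_
    ))
}

#' Stage 1: derive the eligible study population
#'
#' Applies [practice_window()] and [patient_window()] over the whole
#' database and returns one candidate cohort member per surviving patient,
#' logging every rejection (patients of practices with an empty window are
#' rejected as "practice window empty").
#'
#' @param db an [ehr_db()].
#' @param design a [study_design()].
#' @param log a [rejection_log()].
#' @return `list(members = <tibble of candidates>, log = <updated log>)`.
#'   Members carry identifiers, demographics and the observation window;
#'   `role` is `"candidate"`.
#' @export
run_stage1 <- function(db, design, log = rejection_log()) {
  spec <- design$period
  if (nrow(db$patients) == 0) {
    warn("empty database: no patients to process")
  }
  pr <- practice_window(db$practices, spec)
  pat <- db$patients |>
    inner_join(pr |> select("practice_id", "practice_start", "practice_end", "practice_ok"),
      by = "practice_id")

  bad_pr <- pat |> filter(!.data$practice_ok)
  log <- record_rejection(log, "stage1", "practice window empty", bad_pr$patient_id)
  pat <- pat |> filter(.data$practice_ok)

  pat <- patient_window(pat, spec)
  rejected <- pat |> filter(!is.na(.data$reject_reason))
  log <- record_rejection(log, "stage1", rejected$reject_reason, rejected$patient_id)

  members <- pat |>
    filter(is.na(.data$reject_reason)) |>
    transmute(
      .data$patient_id, .data$practice_id, .data$sex, .data$birth_date,
      .data$registration_date, .data$townsend_quintile, .data$ethnicity,
      .data$practice_start, .data$practice_end,
      .data$patient_start, .data$patient_end,
      role = "candidate",
      index_date = as.Date(NA_real_, origin = "1970-01-01"),
      group_id = NA_integer_,
      exit_date = as.Date(NA_real_, origin = "1970-01-01")
    ) |>
    arrange(.data$patient_id)
  list(members = members, log = log)
}
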