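#' Construct an EHR database object
#'
#' Bundles the three source tables of a primary-care style record system —
#' practices, patients and coded events — into a validated `ehr_db` object.
#' Rows violating referential or date-order invariants are removed and
#' counted in the integrity report (`integrity(db)`); a duplicated
#' `practice_id` is an error because it poisons every downstream join.
#'
#' @param practices tibble with columns `practice_id`, `key_date`
#'   (latest of the practice's computerisation / acceptable-mortality-rate /
#'   healthcare-system dates, pre-combined), `collection_date`.
#' @param patients tibble with columns `patient_id`, `practice_id`, `sex`
#'   ("male"/"female"), `birth_date`, `birth_precision` ("day"/"year"),
#'   `registration_date`, `deregistration_date`, `death_date`,
#'   `townsend_quintile` (1-5 or NA), `ethnicity`.
#' @param events tibble with columns `patient_id`, `code`, `event_date`,
#'   `value` (numeric, NA for non-measurements), `unit`, `table_of_origin`
#'   ("clinical"/"therapy"/"measurement").
#' @param year_dob_day month-day assigned to year-precision birth dates,
#'   either `"07-01"` (default, mid-year) or `"01-01"`.
#' @return an `ehr_db`: a list of the three cleaned tibbles with an
#'   `integrity` attribute counting every dropped row by reason.
#' @seealso [read_ehr_db()], [events_for()]
#' @export
ehr_db <- function(practices, patients, events, year_dob_day = c("07-01", "01-01")) {
  year_dob_day <- match.arg(year_dob_day)
  practices <- as_tibble(practices)
  patients <- as_tibble(patients)
  events <- as_tibble(events)

  if (anyDuplicated(practices$practice_id)) {
    abort("duplicate practice_id in practice table")
  }
  dropped <- list()
  note <- function(reason, n) {
    if (n > 0) dropped[[reason]] <<- n
  }

  bad_pr <- is.na(practices$key_date) | is.na(practices$collection_date) |
    practices$key_date > practices$collection_date
  note("practice: key_date after collection_date or missing", sum(bad_pr))
  practices <- practices[!bad_pr, ]

  # normalise year-precision births to a fixed month-day
  yr <- !is.na(patients$birth_precision) & patients$birth_precision == "year"
  if (any(yr)) {
    patients$birth_date[yr] <- as.Date(sprintf(
      "%04d-%s", as.POSIXlt(patients$birth_date[yr])$year + 1900L, year_dob_day))
  }

  bad_ref <- !patients$practice_id %in% practices$practice_id
  note("patient: unknown practice_id", sum(bad_ref))
  bad_core <- is.na(patients$birth_date) | is.na(patients$registration_date) |
    !patients$sex %in% c("male", "female")
  note("patient: missing birth/registration/sex", sum(bad_core & !bad_ref))
  bad_ord <- (!is.na(patients$deregistration_date) &
      patients$deregistration_date < patients$registration_date) |
    (!is.na(patients$death_date) & patients$death_date < patients$registration_date)
  bad_ord[is.na(bad_ord)] <- FALSE
  note("patient: deregistration/death before registration", sum(bad_ord & !bad_ref & !bad_core))
  patients <- patients[!(bad_ref | bad_core | bad_ord), ]

  bad_ev_ref <- !events$patient_id %in% patients$patient_id
  note("event: unknown patient_id", sum(bad_ev_ref))
  bad_ev_date <- is.na(events$event_date) | is.na(events$code) | !nzchar(events$code)
  note("event: missing date or code", sum(bad_ev_date & !bad_ev_ref))
  events <- events[!(bad_ev_ref | bad_ev_date), ]
  events <- arrange(events, patient_id, event_date, code, table_of_origin)

  structure(
    list(practices = practices, patients = patients, events = events),
    integrity = dropped,
    class = "ehr_db"
  )
}

#' @rdname ehr_db
#' @param db an `ehr_db`.
#' @export
integrity <- function(db) attr(db, "integrity") %||% list()

#' @export
print.ehr_db <- function(x, ...) {
  cat("<ehr_db> ", nrow(x$practices), " practices, ", nrow(x$patients),
    " patients, ", nrow(x$events), " events\n", sep = "")
  dr <- integrity(x)
  if (length(dr)) {
    cat("rows dropped at load:\n")
    for (r in names(dr)) cat("  - ", r, ": ", dr[[r]], "\n", sep = "")
  }
  invisible(x)
}

ehr_csv_cols <- list(
  practice = readr::cols(
    practice_id = readr::col_character(),
    key_date = readr::col_character(),
    collection_date = readr::col_character()
  ),
  patient = readr::cols(
    patient_id = readr::col_character(),
    practice_id = readr::col_character(),
    sex = readr::col_character(),
    birth_date = readr::col_character(),
    birth_precision = readr::col_character(),
    registration_date = readr::col_character(),
    deregistration_date = readr::col_character(),
    death_date = readr::col_character(),
    townsend_quintile = readr::col_integer(),
    ethnicity = readr::col_character()
  ),
  events = readr::cols(
    patient_id = readr::col_character(),
    code = readr::col_character(),
    event_date = readr::col_character(),
    value = readr::col_double(),
    unit = readr::col_character(),
    table_of_origin = readr::col_character()
  )
)

#' Read / write an EHR database as flat CSV files
#'
#' The on-disk form is three CSV files with header rows —
#' `practice.csv`, `patient.csv`, `events.csv` — using ISO-8601 dates and
#' empty strings for missing values.  `read_ehr_db()` parses, validates and
#' returns an [ehr_db()]; `write_ehr_db()` is its inverse and round-trips
#' field-for-field.
#'
#' @param dir directory containing (or to receive) the three files.
#' @param year_dob_day passed on to [ehr_db()].
#' @return `read_ehr_db()` an `ehr_db`; `write_ehr_db()` `dir`, invisibly.
#' @export
read_ehr_db <- function(dir, year_dob_day = c("07-01", "01-01")) {
  paths <- file.path(dir, c("practice.csv", "patient.csv", "events.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste("missing database file(s):", paste(missing, collapse = ", ")))

  pr <- readr::read_csv(paths[1], col_types = ehr_csv_cols$practice, progress = FALSE)
  pa <- readr::read_csv(paths[2], col_types = ehr_csv_cols$patient, progress = FALSE)
  ev <- readr::read_csv(paths[3], col_types = ehr_csv_cols$events, progress = FALSE)

  pr <- mutate(pr, across(c(key_date, collection_date), parse_date_flex))
  pa <- mutate(pa, across(c(birth_date, registration_date, deregistration_date, death_date),
    parse_date_flex))
  ev <- mutate(ev, event_date = parse_date_flex(event_date))

  ehr_db(pr, pa, ev, year_dob_day = match.arg(year_dob_day))
}

#' @rdname read_ehr_db
#' @param db an `ehr_db`.
#' @export
write_ehr_db <- function(db, dir) {
  stopifnot(inherits(db, "ehr_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(db$practices, file.path(dir, "practice.csv"), na = "")
  readr::write_csv(db$patients, file.path(dir, "patient.csv"), na = "")
  readr::write_csv(db$events, file.path(dir, "events.csv"), na = "")
  invisible(dir)
}

#' Retrieve a patient's events for a code set within a window
#'
#' Returns the events of one patient whose code belongs to `codes` and whose
#' date lies in the closed interval `[from, to]`, sorted ascending by date
#' with ties broken by code string then table of origin, so results are
#' deterministic.  An unknown patient gives an empty result.
#'
#' @param db an [ehr_db()].
#' @param patient_id a single patient identifier.
#' @param codes character vector of clinical codes.
#' @param from,to closed window bounds (`Date`); `from` must not exceed `to`.
#' @return a tibble of matching events in deterministic order.
#' @export
events_for <- function(db, patient_id, codes, from, to) {
  stopifnot(inherits(db, "ehr_db"), from <= to)
  db$events |>
    filter(.data$patient_id == .env$patient_id, .data$code %in% .env$codes,
      .data$event_date >= .env$from, .data$event_date <= .env$to) |>
    arrange(.data$event_date, .data$code, .data$table_of_origin)
}
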