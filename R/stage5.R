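#' Stage 5: outcomes and patient exit dates
#'
#' For every member and every outcome entity, the first event strictly
#' after the member's index date and on or before the patient end date is
#' recorded (same-day events belong to the pre-index exclusion logic, so a
#' qualifying outcome can never create zero-length follow-up).  The exit
#' date is the patient end date, moved up to the first outcome of any kind
#' when one occurs; per-outcome dates are kept so analysts can apply
#' cause-specific censoring.
#'
#' @param members members with index dates (matched controls carry their
#'   group's index date).
#' @param design a [study_design()].
#' @param db an [ehr_db()].
#' @return `list(members =, outcomes =)`: members gain `exit_date`;
#'   `outcomes` is a tibble `(patient_id, outcome, event_date)` with one
#'   row per member and outcome entity (`NA` date = censored).
#' @export
run_stage5 <- function(members, design, db) {
  out_rows <- list()
  exit <- members$patient_end
  for (nm in design$outcomes) {
    ent <- design$entities[[nm]]
    first <- db$events |>
      filter(.data$code %in% ent$codes, .data$patient_id %in% members$patient_id) |>
      inner_join(members |> select("patient_id", "index_date", "patient_end"),
        by = "patient_id") |>
      filter(.data$event_date > .data$index_date, .data$event_date <= .data$patient_end) |>
      group_by(.data$patient_id) |>
      summarise(event_date = min_date(.data$event_date), .groups = "drop")
    aligned <- members |>
      select("patient_id") |>
      left_join(first, by = "patient_id")
    out_rows[[nm]] <- aligned |> mutate(outcome = nm, .after = "patient_id")
    exit <- pmin_date(exit, aligned$event_date)
  }
  members$exit_date <- exit
  outcomes <- if (length(out_rows)) bind_rows(out_rows) else
    tibble(patient_id = character(), outcome = character(),
      event_date = as.Date(numeric(), origin = "1970-01-01"))
  list(members = members, outcomes = outcomes)
}
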