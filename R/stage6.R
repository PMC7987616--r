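#' Stage 6: baseline variables, assembly and summaries
#'
#' `extract_baseline()` pulls one baseline variable per member under the
#' declared retrieval rule: `latest_before_index` (most recent record on or
#' before index, optionally restricted to a lookback window),
#' `earliest_ever`, or `first_after_index`.  Measurement entities yield
#' their recorded value; diagnosis/treatment entities a presence flag.
#' Absence is a missing marker, never an error.
#'
#' @param members member tibble with `index_date`.
#' @param spec a [baseline_spec()].
#' @param design the [study_design()].
#' @param db an [ehr_db()].
#' @return tibble aligned to members: `(patient_id, value, measurement_date)`.
#' @export
extract_baseline <- function(members, spec, design, db) {
  ent <- design$entities[[spec$entity]]
  ev <- db$events |>
    filter(.data$code %in% ent$codes, .data$patient_id %in% members$patient_id) |>
    inner_join(members |> select("patient_id", "index_date"), by = "patient_id")
  ev <- switch(spec$rule,
    latest_before_index = {
      e <- ev |> filter(.data$event_date <= .data$index_date)
      if (!is.null(spec$lookback_days)) {
        e <- e |> filter(.data$event_date >= .data$index_date - spec$lookback_days)
      }
      e |> group_by(.data$patient_id) |>
        slice_max(.data$event_date, n = 1, with_ties = FALSE) |> ungroup()
    },
    earliest_ever = ev |> group_by(.data$patient_id) |>
      slice_min(.data$event_date, n = 1, with_ties = FALSE) |> ungroup(),
    first_after_index = ev |> filter(.data$event_date > .data$index_date) |>
      group_by(.data$patient_id) |>
      slice_min(.data$event_date, n = 1, with_ties = FALSE) |> ungroup()
  )
  members |>
    select("patient_id") |>
    left_join(ev |> select("patient_id", "value", measurement_date = "event_date"),
      by = "patient_id") |>
    mutate(value = ifelse(is.na(.data$value) & !is.na(.data$measurement_date),
      1, .data$value))
}

#' Assemble the analysable dataset
#'
#' One row per surviving member with deterministic column order: study
#' population fields, exposure/case information, matching information,
#' per-outcome event columns and per-baseline value columns.
#' Cross-sectional designs carry no matching or outcome columns.
#'
#' @param members final member tibble.
#' @param outcomes stage-5 outcome tibble.
#' @param design a [study_design()].
#' @param db an [ehr_db()].
#' @return the dataset as a tibble.
#' @export
assemble_dataset <- function(members, outcomes, design, db) {
  cs <- design$design_type == "cross_sectional"
  base <- members |>
    mutate(
      exposed_flag = as.integer(.data$role == "exposed_or_case"),
      age_at_index = ifelse(is.na(.data$index_date), NA_integer_,
        age_on(.data$birth_date, .data$index_date)),
      follow_up_days = if (!cs) as.integer(.data$exit_date - .data$index_date) else NA_integer_
    )
  cols <- c("patient_id", "practice_id",
    if (!cs && !is.null(design$match_criteria)) c("group_id", "match_order"),
    "exposed_flag", "sex", "birth_date", "townsend_quintile", "ethnicity",
    "patient_start", "patient_end", "index_date",
    if (!cs) c("exit_date", "follow_up_days"),
    "age_at_index")
  out <- base |> select(all_of(intersect(cols, names(base))))

  if (!cs && length(design$outcomes)) {
    wide <- outcomes |>
      mutate(flag = as.integer(!is.na(.data$event_date))) |>
      left_join(members |> select("patient_id", "index_date"), by = "patient_id") |>
      mutate(days_to_event = as.integer(.data$event_date - .data$index_date)) |>
      select(-"index_date") |>
      tidyr::pivot_wider(names_from = "outcome",
        values_from = c("flag", "event_date", "days_to_event"),
        names_glue = "{outcome}_{.value}")
    out <- out |> left_join(wide, by = "patient_id")
  }
  for (b in design$baselines) {
    bl <- extract_baseline(members, b, design, db)
    names(bl)[2:3] <- paste0(b$entity, c("_value", "_date"))
    out <- out |> left_join(bl, by = "patient_id")
  }
  out |> arrange(.data$patient_id)
}

#' Incidence and prevalence summaries
#'
#' `summarise_incidence()` computes, per stratum, events, person-years
#' (follow-up days / 365.25) and the incidence rate per 100,000
#' person-years with an exact Poisson 95% CI.  `summarise_prevalence()`
#' computes, per stratum, the proportion of the population registered on a
#' reference date that is a case, with an exact (Clopper-Pearson) binomial
#' 95% CI.  These support the surveillance use of yearly cohort and
#' cross-sectional extractions.
#'
#' @param dataset an assembled dataset.
#' @param outcome outcome entity name (its `<name>_flag` column is used).
#' @param by character vector of stratification columns (e.g. `"exposed_flag"`,
#'   `"sex"`); empty for an overall summary.
#' @param conf_level confidence level, default 0.95.
#' @return a tibble with one row per stratum, class `ehr_rates`.
#' @export
summarise_incidence <- function(dataset, outcome, by = "exposed_flag",
                                conf_level = 0.95) {
  flag_col <- paste0(outcome, "_flag")
  stopifnot(flag_col %in% names(dataset), "follow_up_days" %in% names(dataset))
  out <- dataset |>
    group_by(across(all_of(by))) |>
    summarise(
      events = sum(.data[[flag_col]], na.rm = TRUE),
      person_years = sum(.data$follow_up_days, na.rm = TRUE) / 365.25,
      .groups = "drop"
    ) |>
    mutate(poisson_ci(.data$events, .data$person_years, conf_level))
  structure(out, class = c("ehr_rates", class(out)), measure = "incidence",
    outcome = outcome, conf_level = conf_level)
}

# exact Poisson CI for a rate per 100,000 person-years (chi-square form)
poisson_ci <- function(events, person_years, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  scale <- 1e5 / person_years
  rate <- events * scale
  lower <- qchisq(a, 2 * events) / 2 * scale
  lower[events == 0] <- 0
  upper <- qchisq(1 - a, 2 * events + 2) / 2 * scale
  rate[person_years <= 0] <- NA_real_
  lower[person_years <= 0] <- NA_real_
  upper[person_years <= 0] <- NA_real_
  tibble(rate_per_1e5 = rate, rate_lower = lower, rate_upper = upper,
    rate_undefined = person_years <= 0)
}

#' @rdname summarise_incidence
#' @param reference_date the day on which prevalence is assessed; cases are
#'   exposed/case members whose observation window covers the date, the
#'   population is every member whose window covers it.
#' @export
summarise_prevalence <- function(dataset, reference_date, by = character(),
                                 conf_level = 0.95) {
  reference_date <- parse_date_flex(reference_date)
  out <- dataset |>
    filter(.data$patient_start <= reference_date, .data$patient_end >= reference_date) |>
    group_by(across(all_of(by))) |>
    summarise(
      cases = sum(.data$exposed_flag == 1L),
      population = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(binomial_ci(.data$cases, .data$population, conf_level))
  structure(out, class = c("ehr_rates", class(out)), measure = "prevalence",
    reference_date = reference_date, conf_level = conf_level)
}

# exact Clopper-Pearson interval on the prevalence proportion
binomial_ci <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  p <- x / n
  lower <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  tibble(prevalence = p, prev_lower = lower, prev_upper = upper)
}
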