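#' Locate a code entity for cohort members
#'
#' Finds, per member, the qualifying event date of one entity under its
#' exposure-type rule:
#' * `incident_only` — earliest event on or before the patient end date;
#'   if that event precedes the patient start date the patient is flagged
#'   prevalent-at-entry (rejected from an exposed role).
#' * `incident_or_prevalent` — earliest event on or before the patient end
#'   date; a pre-entry event is kept and contributes the patient start date
#'   (a prevalent exposure puts the patient at risk from cohort entry).
#' * `first_after_entry` — earliest event inside `[patient_start,
#'   patient_end]`.
#'
#' @param members stage-1 member tibble (needs `patient_id`,
#'   `patient_start`, `patient_end`).
#' @param entity an inclusion [code_entity()].
#' @param db an [ehr_db()].
#' @return tibble aligned with `members`: columns `hit_date` (`NA` = not
#'   found), `raw_date` (the event's own date) and `prevalent_reject`.
#' @export
locate_entity <- function(members, entity, db) {
  stopifnot(entity$criteria == "inclusion")
  ev <- db$events |>
    filter(.data$code %in% entity$codes) |>
    select("patient_id", "event_date")
  win <- members |> select("patient_id", "patient_start", "patient_end")
  j <- win |>
    inner_join(ev, by = "patient_id", relationship = "one-to-many") |>
    filter(.data$event_date <= .data$patient_end)
  if (entity$exposure_type == "first_after_entry") {
    j <- j |> filter(.data$event_date >= .data$patient_start)
  }
  first <- j |>
    group_by(.data$patient_id) |>
    summarise(raw_date = min_date(.data$event_date), .groups = "drop")
  out <- win |>
    left_join(first, by = "patient_id") |>
    mutate(
      prevalent_reject = entity$exposure_type == "incident_only" &
        !is.na(.data$raw_date) & .data$raw_date < .data$patient_start,
      hit_date = dplyr::case_when(
        is.na(.data$raw_date) | .data$prevalent_reject ~ as.Date(NA_real_, origin = "1970-01-01"),
        entity$exposure_type == "incident_or_prevalent" ~
          pmax_date(.data$raw_date, .data$patient_start),
        TRUE ~ .data$raw_date
      )
    )
  out |> select("patient_id", "hit_date", "raw_date", "prevalent_reject")
}

# earliest event date per patient for an entity, unrestricted by window
entity_first_ever <- function(members, entity, db) {
  db$events |>
    filter(.data$code %in% entity$codes, .data$patient_id %in% members$patient_id) |>
    group_by(.data$patient_id) |>
    summarise(first_date = min_date(.data$event_date), .groups = "drop")
}

# index-date assignment shared by stages 2 and 3
evaluate_members <- function(members, logic, mode, entities, db, stage, log,
                             on_unsatisfied, on_order, satisfied_role) {
  needed <- logic_entities(logic)
  dates <- list()
  prev_reason <- rep(NA_character_, nrow(members))
  for (nm in needed) {
    loc <- locate_entity(members, entities[[nm]], db)
    dates[[nm]] <- loc$hit_date
    hit_prev <- loc$prevalent_reject & is.na(prev_reason)
    prev_reason[hit_prev] <- paste0("prevalent at entry: ", nm)
  }
  keep <- is.na(prev_reason)
  log <- record_rejection(log, stage, prev_reason[!keep], members$patient_id[!keep])
  members <- members[keep, ]
  dates <- lapply(dates, function(d) d[keep])

  if (nrow(members) == 0) {
    return(list(members = members, log = log))
  }
  if (mode == "strict") {
    res <- evaluate_strict(logic, dates)
    status <- res$status
    index <- res$index_date
  } else {
    index <- evaluate_loose(logic, dates)
    status <- ifelse(is.na(index), "unsatisfied", "date")
  }
  ord <- status == "reject_order"
  log <- record_rejection(log, stage, on_order, members$patient_id[ord])
  members$index_date[status == "date"] <- index[status == "date"]
  members$role[status == "date"] <- satisfied_role

  uns <- status == "unsatisfied"
  if (is.na(on_unsatisfied)) {
    members$role[uns] <- "potential_control"
    members$index_date[uns] <- NA
  } else {
    log <- record_rejection(log, stage, on_unsatisfied, members$patient_id[uns])
  }
  members <- members[!ord & !(uns & !is.na(on_unsatisfied)), ]
  list(members = members, log = log)
}

#' Stage 2: assign index dates to the exposed / case group
#'
#' Locates every inclusion entity referenced by the exposure logic,
#' evaluates the logic in the design's parsing mode, and partitions the
#' stage-1 candidates into exposed/case members (index date assigned),
#' potential controls (when the design requires controls, or always for a
#' cross-sectional design, where non-qualifying members form the unexposed
#' denominator), and documented rejections.  Exclusion entities and — when
#' requested — pre-index outcome occurrences then remove exposed members.
#'
#' @param members stage-1 candidates.
#' @param design a [study_design()].
#' @param db an [ehr_db()].
#' @param log a [rejection_log()].
#' @return `list(members =, log =)`; members carry roles
#'   `"exposed_or_case"` / `"potential_control"`.
#' @export
run_stage2 <- function(members, design, db, log = rejection_log()) {
  keep_unsatisfied <- design$controls_required ||
    design$design_type == "cross_sectional"
  res <- evaluate_members(
    members, design$exposure_logic, design$parsing_mode, design$entities, db,
    stage = "stage2", log = log,
    on_unsatisfied = if (keep_unsatisfied) NA_character_ else "exposure logic unsatisfied",
    on_order = "exposure order violated",
    satisfied_role = "exposed_or_case"
  )
  members <- res$members
  log <- res$log

  exposed <- members |> filter(.data$role == "exposed_or_case")
  if (nrow(exposed)) {
    drop <- apply_exclusions(exposed, design, db)
    log <- record_rejection(log, "stage2", drop$reason[!is.na(drop$reason)],
      drop$patient_id[!is.na(drop$reason)])
    members <- members |> filter(!.data$patient_id %in% drop$patient_id[!is.na(drop$reason)])
  }
  list(members = members, log = log)
}

#' Apply exclusion entities (and optional pre-index outcome exclusion)
#'
#' `exclude_ever` entities disqualify on any record at any time;
#' `exclude_before_index` entities disqualify on a record on or before the
#' member's index date (the index day itself counts as pre-index).  With
#' `pre_index_outcome_exclusion`, an outcome entity record on or before
#' index also disqualifies.
#'
#' @param members members holding an `index_date` (exposed/case).
#' @param design a [study_design()].
#' @param db an [ehr_db()].
#' @param which `"all"` (stage 2) or `"ever_only"` (stage 3: controls have
#'   no index date yet, so only `exclude_ever` applies).
#' @return tibble `(patient_id, reason)` with `NA` reason for kept members;
#'   the reason is the first matching exclusion in declaration order.
#' @export
apply_exclusions <- function(members, design, db, which = c("all", "ever_only")) {
  which <- match.arg(which)
  reason <- rep(NA_character_, nrow(members))
  excl <- keep(design$entities, ~ .x$criteria == "exclusion")
  for (e in excl) {
    if (e$exposure_type == "exclude_ever") {
      hit <- members$patient_id %in%
        unique(db$events$patient_id[db$events$code %in% e$codes])
      reason[hit & is.na(reason)] <- paste0("exclusion (ever recorded): ", e$name)
    } else if (which == "all") {
      first <- entity_first_ever(members, e, db)
      m <- members |> left_join(first, by = "patient_id")
      hit <- !is.na(m$first_date) & !is.na(m$index_date) & m$first_date <= m$index_date
      reason[hit & is.na(reason)] <- paste0("exclusion (before index): ", e$name)
    }
  }
  if (which == "all" && design$pre_index_outcome_exclusion) {
    for (nm in design$outcomes) {
      first <- entity_first_ever(members, design$entities[[nm]], db)
      m <- members |> left_join(first, by = "patient_id")
      hit <- !is.na(m$first_date) & !is.na(m$index_date) & m$first_date <= m$index_date
      reason[hit & is.na(reason)] <- paste0("outcome before index: ", nm)
    }
  }
  tibble(patient_id = members$patient_id, reason = reason)
}

#' Stage 3: refine the potential-control pool
#'
#' When the design declares control logic, the same locate / evaluate /
#' exclude machinery runs over the potential controls; candidates failing
#' it are rejected with documented reasons, survivors keep their
#' `potential_control` role (with a provisional entity-derived date kept in
#' `control_entity_date`).  Only `exclude_ever` exclusions apply here:
#' controls have no index date yet, so index-relative exclusions belong to
#' the matching stage.  Without control logic the pool passes unchanged.
#'
#' @inheritParams run_stage2
#' @return `list(members =, log =)`.
#' @export
run_stage3 <- function(members, design, db, log = rejection_log()) {
  pool <- members |> filter(.data$role == "potential_control")
  rest <- members |> filter(.data$role != "potential_control")
  if (is.null(design$control_logic) || nrow(pool) == 0) {
    return(list(members = members, log = log))
  }
  res <- evaluate_members(
    pool, design$control_logic, design$control_parsing_mode, design$entities, db,
    stage = "stage3", log = log,
    on_unsatisfied = "control logic unsatisfied",
    on_order = "control logic order violated",
    satisfied_role = "potential_control"
  )
  pool <- res$members
  log <- res$log
  # the control logic's date is provisional only; a matched control's true
  # index date comes from its exposed partner
  pool <- pool |>
    mutate(control_entity_date = .data$index_date,
      index_date = as.Date(NA_real_, origin = "1970-01-01"))

  if (nrow(pool)) {
    drop <- apply_exclusions(pool, design, db, which = "ever_only")
    bad <- !is.na(drop$reason)
    log <- record_rejection(log, "stage3", drop$reason[bad], drop$patient_id[bad])
    pool <- pool |> filter(!.data$patient_id %in% drop$patient_id[bad])
  }
  if (nrow(rest)) rest$control_entity_date <- as.Date(NA_real_, origin = "1970-01-01")
  members <- bind_rows(rest, pool) |> arrange(.data$patient_id)
  list(members = members, log = log)
}
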