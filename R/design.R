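#' Declare a code entity
#'
#' A code entity is a named bundle of clinical codes (diagnoses,
#' prescriptions or measurements) plus the rule describing how its
#' occurrence qualifies or disqualifies a patient.  Inclusion entities
#' support `incident_only` (earliest record on or before the patient end
#' date; a record before the patient start date disqualifies the patient as
#' prevalent-at-entry), `incident_or_prevalent` (earliest record on or
#' before end; a pre-entry record is kept and contributes the entry date),
#' and `first_after_entry` (earliest record inside the observation window).
#' Exclusion entities support `exclude_ever` (any record at any time
#' disqualifies) and `exclude_before_index` (a record on or before the
#' index date disqualifies).
#'
#' @param name identifier used in combination-logic expressions.
#' @param codes non-empty character vector of clinical codes.
#' @param criteria "inclusion" or "exclusion".
#' @param exposure_type one of `incident_only`, `incident_or_prevalent`,
#'   `first_after_entry` (inclusion) or `exclude_ever`,
#'   `exclude_before_index` (exclusion).
#' @return a `code_entity` object.
#' @export
code_entity <- function(name, codes,
                        criteria = c("inclusion", "exclusion"),
                        exposure_type = NULL) {
  criteria <- match.arg(criteria)
  if (!is.character(name) || length(name) != 1 || !grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    abort("entity name must be a single identifier ([A-Za-z_][A-Za-z0-9_]*)")
  }
  if (tolower(name) %in% c("and", "or")) abort("entity name may not be a logic keyword")
  if (length(codes) == 0) abort(paste0("entity '", name, "': empty code definition"))
  allowed <- if (criteria == "inclusion") {
    c("incident_only", "incident_or_prevalent", "first_after_entry")
  } else {
    c("exclude_ever", "exclude_before_index")
  }
  exposure_type <- exposure_type %||% allowed[1]
  if (!exposure_type %in% allowed) {
    abort(paste0("entity '", name, "': exposure_type '", exposure_type,
      "' invalid for ", criteria, " criteria"))
  }
  structure(
    list(name = name, criteria = criteria, exposure_type = exposure_type,
      codes = as.character(codes)),
    class = "code_entity"
  )
}

#' @export
print.code_entity <- function(x, ...) {
  cat("<code_entity> ", x$name, " [", x$criteria, "/", x$exposure_type, "] ",
    length(x$codes), " code(s)\n", sep = "")
  invisible(x)
}

#' Declare the study period and population filters
#'
#' The stage-1 inputs: calendar study period, data-quality offset added to
#' practice key dates, registration lead-in, entry/exit age limits and the
#' sex filter.
#'
#' @param study_start,study_end calendar bounds of the study
#'   (`Date` or strings in ISO or DD/MM/YYYY form).
#' @param key_date_offset_days days added to each practice key date before
#'   computing the practice window (data-quality filter), default 0.
#' @param registration_leadin_days days a patient must have been registered
#'   before entering, default 0.
#' @param entry_age_min,entry_age_max allowed age range (completed years) at
#'   cohort entry.
#' @param exit_age_max maximum age at cohort exit.
#' @param sex_filter "male", "female" or "any".
#' @return a `study_period` object.
#' @export
study_period <- function(study_start, study_end,
                         key_date_offset_days = 0,
                         registration_leadin_days = 0,
                         entry_age_min = 0, entry_age_max = 115,
                         exit_age_max = 115,
                         sex_filter = c("any", "male", "female")) {
  study_start <- parse_date_flex(study_start)
  study_end <- parse_date_flex(study_end)
  sex_filter <- match.arg(sex_filter)
  if (!study_start < study_end) abort("study_start must precede study_end")
  if (key_date_offset_days < 0 || registration_leadin_days < 0) {
    abort("day offsets must be non-negative")
  }
  if (!(entry_age_min <= entry_age_max && entry_age_max <= exit_age_max)) {
    abort("need entry_age_min <= entry_age_max <= exit_age_max")
  }
  structure(
    list(study_start = study_start, study_end = study_end,
      key_date_offset_days = as.integer(key_date_offset_days),
      registration_leadin_days = as.integer(registration_leadin_days),
      entry_age_min = as.integer(entry_age_min),
      entry_age_max = as.integer(entry_age_max),
      exit_age_max = as.integer(exit_age_max),
      sex_filter = sex_filter),
    class = "study_period"
  )
}

#' Declare matching criteria for control selection
#'
#' The stage-4 inputs.  All tolerances are "plus or minus"; entity-based
#' criteria refer to declared [code_entity()] names.
#'
#' @param n_controls_per_exposed controls sought per exposed/case.
#' @param age_tolerance_years allowed absolute age difference at index.
#' @param sex_match "yes" (same sex), "any", or "opposite".
#' @param registration_tolerance_days optional maximum absolute difference
#'   between registration dates.
#' @param match_townsend,match_ethnicity require equal Townsend quintile /
#'   ethnicity category.
#' @param exposure_duration optional `list(entity =, tolerance_days =)`:
#'   controls must have had their first record of the entity within the
#'   tolerance of the exposed's duration at index.
#' @param baseline_conditions,baseline_treatments entity names whose
#'   presence on or before the index date must agree between control and
#'   exposed.
#' @param measurement_matches list of `list(entity =, lookback_days =,
#'   value_tolerance =)`: the control's latest value of the entity within
#'   the lookback window before index must be within the tolerance of the
#'   exposed's corresponding value.
#' @param exclude_outcomes_before_index,exclude_events_before_index entity
#'   names disqualifying a control when recorded on or before index.
#' @param unmatched "keep" retains exposed with no eligible control
#'   (flagged unmatched); "drop" rejects them.
#' @return a `match_criteria` object.
#' @export
match_criteria <- function(n_controls_per_exposed,
                           age_tolerance_years = 0,
                           sex_match = c("yes", "any", "opposite"),
                           registration_tolerance_days = NULL,
                           match_townsend = FALSE,
                           match_ethnicity = FALSE,
                           exposure_duration = NULL,
                           baseline_conditions = character(),
                           baseline_treatments = character(),
                           measurement_matches = list(),
                           exclude_outcomes_before_index = character(),
                           exclude_events_before_index = character(),
                           unmatched = c("keep", "drop")) {
  sex_match <- match.arg(sex_match)
  unmatched <- match.arg(unmatched)
  stopifnot(n_controls_per_exposed >= 1, age_tolerance_years >= 0)
  if (!is.null(registration_tolerance_days)) stopifnot(registration_tolerance_days >= 0)
  if (!is.null(exposure_duration)) {
    stopifnot(is.list(exposure_duration),
      all(c("entity", "tolerance_days") %in% names(exposure_duration)),
      exposure_duration$tolerance_days >= 0)
  }
  for (m in measurement_matches) {
    stopifnot(all(c("entity", "lookback_days", "value_tolerance") %in% names(m)),
      m$lookback_days >= 0, m$value_tolerance >= 0)
  }
  structure(
    list(n_controls_per_exposed = as.integer(n_controls_per_exposed),
      age_tolerance_years = as.integer(age_tolerance_years),
      sex_match = sex_match,
      registration_tolerance_days = registration_tolerance_days,
      match_townsend = isTRUE(match_townsend),
      match_ethnicity = isTRUE(match_ethnicity),
      exposure_duration = exposure_duration,
      baseline_conditions = as.character(baseline_conditions),
      baseline_treatments = as.character(baseline_treatments),
      measurement_matches = measurement_matches,
      exclude_outcomes_before_index = as.character(exclude_outcomes_before_index),
      exclude_events_before_index = as.character(exclude_events_before_index),
      unmatched = unmatched),
    class = "match_criteria"
  )
}

#' Declare a baseline-variable extraction rule
#'
#' @param entity a declared [code_entity()] name.
#' @param rule `latest_before_index` (default), `earliest_ever`, or
#'   `first_after_index`.
#' @param lookback_days for `latest_before_index`, restrict the search to
#'   this many days before the index date (optional).
#' @return a `baseline_spec` object.
#' @export
baseline_spec <- function(entity,
                          rule = c("latest_before_index", "earliest_ever", "first_after_index"),
                          lookback_days = NULL) {
  rule <- match.arg(rule)
  if (!is.null(lookback_days)) stopifnot(lookback_days >= 0)
  structure(list(entity = entity, rule = rule, lookback_days = lookback_days),
    class = "baseline_spec")
}

#' Declare a study design
#'
#' The full declarative input to an extraction: the design type, study
#' period, code entities, exposure-combination logic with its parsing mode,
#' optional control logic and matching criteria, outcomes, baseline
#' variables, the seed driving randomized matching, and an optional
#' output-encryption password.
#'
#' Cross-sectional designs have no control selection, matching or outcome
#' stage; members not satisfying the exposure logic are retained as
#' unexposed rows so that prevalence has a denominator.
#'
#' @param design_type "cohort", "case_control" or "cross_sectional".
#' @param period a [study_period()].
#' @param entities list of [code_entity()] (inclusion and exclusion).
#' @param exposure_logic expression over inclusion entity names, e.g.
#'   `"Type2Diabetes and Metformin"`.
#' @param parsing_mode "loose" (index = latest date needed to satisfy the
#'   expression) or "strict" (conjunction operands must additionally occur
#'   in left-to-right date order).
#' @param controls_required keep non-qualifying patients as potential
#'   controls (cohort/case-control only).
#' @param control_logic optional expression the control pool must satisfy.
#' @param control_parsing_mode parsing mode for `control_logic`.
#' @param match_criteria optional [match_criteria()].
#' @param outcomes entity names sought after index (stage 5).
#' @param pre_index_outcome_exclusion reject exposed/cases with any outcome
#'   on or before their index date.
#' @param baselines list of [baseline_spec()].
#' @param seed integer seed for the randomized matching stage (the only
#'   stochastic stage).
#' @param encrypt_password optional password; when set the written dataset
#'   is also stored AES-256 encrypted.
#' @return a validated `study_design` object.
#' @export
study_design <- function(design_type = c("cohort", "case_control", "cross_sectional"),
                         period,
                         entities,
                         exposure_logic,
                         parsing_mode = c("loose", "strict"),
                         controls_required = FALSE,
                         control_logic = NULL,
                         control_parsing_mode = c("loose", "strict"),
                         match_criteria = NULL,
                         outcomes = character(),
                         pre_index_outcome_exclusion = FALSE,
                         baselines = list(),
                         seed = 1L,
                         encrypt_password = NULL) {
  design_type <- match.arg(design_type)
  parsing_mode <- match.arg(parsing_mode)
  control_parsing_mode <- match.arg(control_parsing_mode)
  stopifnot(inherits(period, "study_period"))
  if (inherits(entities, "code_entity")) entities <- list(entities)
  stopifnot(all(map_lgl(entities, inherits, "code_entity")))
  names(entities) <- map_chr(entities, "name")
  if (anyDuplicated(names(entities))) abort("duplicate entity names")

  incl <- names(entities)[map_chr(entities, "criteria") == "inclusion"]
  logic <- parse_logic(exposure_logic, incl)
  ctrl <- if (!is.null(control_logic)) parse_logic(control_logic, incl)

  problems <- character()
  if (design_type == "cross_sectional") {
    if (length(outcomes)) problems <- c(problems, "cross_sectional design cannot have outcomes")
    if (!is.null(match_criteria)) problems <- c(problems, "cross_sectional design cannot have match_criteria")
    if (isTRUE(controls_required)) problems <- c(problems, "cross_sectional design cannot require controls")
  }
  if (!is.null(match_criteria)) {
    stopifnot(inherits(match_criteria, "match_criteria"))
    if (!controls_required) problems <- c(problems, "match_criteria requires controls_required = TRUE")
  } else if (isTRUE(controls_required) && design_type != "cross_sectional") {
    # controls only receive an index date through matching
    problems <- c(problems, "controls_required needs match_criteria (controls get index dates by matching)")
  }
  known <- names(entities)
  for (nm in c(outcomes,
    if (!is.null(match_criteria)) c(match_criteria$baseline_conditions,
      match_criteria$baseline_treatments,
      match_criteria$exclude_outcomes_before_index,
      match_criteria$exclude_events_before_index,
      if (!is.null(match_criteria$exposure_duration)) match_criteria$exposure_duration$entity,
      map_chr(match_criteria$measurement_matches, "entity")))) {
    if (!nm %in% known) problems <- c(problems, paste0("unknown entity reference: ", nm))
  }
  for (b in baselines) {
    stopifnot(inherits(b, "baseline_spec"))
    if (!b$entity %in% known) problems <- c(problems, paste0("unknown baseline entity: ", b$entity))
  }
  if (length(problems)) abort(paste0("invalid study design:\n", paste("-", problems, collapse = "\n")))

  structure(
    list(design_type = design_type, period = period, entities = entities,
      exposure_logic = logic, parsing_mode = parsing_mode,
      controls_required = isTRUE(controls_required),
      control_logic = ctrl, control_parsing_mode = control_parsing_mode,
      match_criteria = match_criteria,
      outcomes = as.character(outcomes),
      pre_index_outcome_exclusion = isTRUE(pre_index_outcome_exclusion),
      baselines = baselines, seed = as.integer(seed),
      encrypt_password = encrypt_password),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$design_type, "\n", sep = "")
  cat("  period: ", format(x$period$study_start), " .. ", format(x$period$study_end),
    ", ages ", x$period$entry_age_min, "-", x$period$entry_age_max,
    " (exit <= ", x$period$exit_age_max, "), sex ", x$period$sex_filter, "\n", sep = "")
  cat("  exposure [", x$parsing_mode, "]: ", format_logic(x$exposure_logic), "\n", sep = "")
  if (!is.null(x$control_logic)) {
    cat("  controls [", x$control_parsing_mode, "]: ", format_logic(x$control_logic), "\n", sep = "")
  }
  cat("  entities: ", paste(names(x$entities), collapse = ", "), "\n", sep = "")
  if (length(x$outcomes)) cat("  outcomes: ", paste(x$outcomes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

design_to_list <- function(design) {
  mc <- design$match_criteria
  list(
    design_type = design$design_type,
    period = lapply(unclass(design$period), function(v) {
      if (inherits(v, "Date")) format(v) else v
    }),
    entities = lapply(unname(design$entities), function(e) {
      list(name = e$name, criteria = e$criteria, exposure_type = e$exposure_type,
        codes = as.list(e$codes))
    }),
    exposure_logic = format_logic(design$exposure_logic),
    parsing_mode = design$parsing_mode,
    controls_required = design$controls_required,
    control_logic = if (!is.null(design$control_logic)) format_logic(design$control_logic),
    control_parsing_mode = design$control_parsing_mode,
    match_criteria = if (!is.null(mc)) unclass(mc),
    outcomes = as.list(design$outcomes),
    pre_index_outcome_exclusion = design$pre_index_outcome_exclusion,
    baselines = lapply(design$baselines, unclass),
    seed = design$seed
  )
}

#' Read / write a study design configuration file
#'
#' Designs serialize to a single YAML (or JSON) document; dates are accepted
#' in ISO-8601 or DD/MM/YYYY form.  The encryption password is deliberately
#' never written to the config.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_study_design()` a [study_design()];
#'   `write_study_design()` `path`, invisibly.
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) abort(paste("no such design file:", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  per <- cfg$period
  entities <- lapply(cfg$entities, function(e) {
    code_entity(e$name, unlist(e$codes), e$criteria, e$exposure_type)
  })
  mc <- cfg$match_criteria
  crit <- if (!is.null(mc)) {
    match_criteria(
      n_controls_per_exposed = mc$n_controls_per_exposed,
      age_tolerance_years = mc$age_tolerance_years %||% 0,
      sex_match = mc$sex_match %||% "yes",
      registration_tolerance_days = mc$registration_tolerance_days,
      match_townsend = mc$match_townsend %||% FALSE,
      match_ethnicity = mc$match_ethnicity %||% FALSE,
      exposure_duration = mc$exposure_duration,
      baseline_conditions = unlist(mc$baseline_conditions) %||% character(),
      baseline_treatments = unlist(mc$baseline_treatments) %||% character(),
      measurement_matches = mc$measurement_matches %||% list(),
      exclude_outcomes_before_index = unlist(mc$exclude_outcomes_before_index) %||% character(),
      exclude_events_before_index = unlist(mc$exclude_events_before_index) %||% character(),
      unmatched = mc$unmatched %||% "keep"
    )
  }
  study_design(
    design_type = cfg$design_type,
    period = study_period(
      study_start = per$study_start, study_end = per$study_end,
      key_date_offset_days = per$key_date_offset_days %||% 0,
      registration_leadin_days = per$registration_leadin_days %||% 0,
      entry_age_min = per$entry_age_min %||% 0,
      entry_age_max = per$entry_age_max %||% 115,
      exit_age_max = per$exit_age_max %||% 115,
      sex_filter = per$sex_filter %||% "any"
    ),
    entities = entities,
    exposure_logic = cfg$exposure_logic,
    parsing_mode = cfg$parsing_mode %||% "loose",
    controls_required = cfg$controls_required %||% FALSE,
    control_logic = cfg$control_logic,
    control_parsing_mode = cfg$control_parsing_mode %||% "loose",
    match_criteria = crit,
    outcomes = unlist(cfg$outcomes) %||% character(),
    pre_index_outcome_exclusion = cfg$pre_index_outcome_exclusion %||% FALSE,
    baselines = lapply(cfg$baselines, function(b) {
      baseline_spec(b$entity, b$rule %||% "latest_before_index", b$lookback_days)
    }),
    seed = cfg$seed %||% 1L
  )
}

#' @rdname read_study_design
#' @param design a [study_design()].
#' @export
write_study_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  lst <- design_to_list(design)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}
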