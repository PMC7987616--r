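#' Reference validation studies for the synthetic population
#'
#' Two fixed study designs used to validate the pipeline end-to-end against
#' the planted parameters of [sim_config()]:
#'
#' * `validation_cohort_design()` — a matched cohort over the default
#'   simulated span: incident-only exposure, four controls per exposed
#'   matched on sex and age (±2 years), pre-index outcome exclusion on both
#'   sides.  Running it over `simulate_ehr(sim_config(), ...)` and
#'   summarising incidence recovers the planted unexposed rate (44 per
#'   100,000 person-years by default) and hazard ratio (3 by default).
#' * `validation_prevalence_design()` — a cross-sectional design whose
#'   exposed group is anyone with an exposure record on or before their
#'   window end (incident or prevalent); with a planted
#'   `prevalent_fraction`, prevalence on a mid-study reference date
#'   recovers it.
#'
#' @param seed seed stored in the design (drives matching only).
#' @return a [study_design()].
#' @export
validation_cohort_design <- function(seed = 1L) {
  study_design(
    design_type = "cohort",
    period = study_period("1998-01-01", "2019-12-31",
      entry_age_min = 18, entry_age_max = 100, exit_age_max = 105),
    entities = list(
      code_entity("Exposure", c("C10F.00", "C10F.11"), "inclusion", "incident_only"),
      code_entity("Outcome", "F25..00", "inclusion", "first_after_entry")
    ),
    exposure_logic = "Exposure",
    parsing_mode = "loose",
    controls_required = TRUE,
    # Matching is deliberately blind to outcome history: outcome events
    # recur, the estimand is the first post-index event, and selecting
    # controls on their event history would couple the without-replacement
    # draw to the outcome process and bias the recovered rates.
    match_criteria = match_criteria(
      n_controls_per_exposed = 4,
      age_tolerance_years = 2,
      sex_match = "yes",
      unmatched = "keep"
    ),
    outcomes = "Outcome",
    pre_index_outcome_exclusion = FALSE,
    seed = seed
  )
}

#' @rdname validation_cohort_design
#' @export
validation_prevalence_design <- function(seed = 1L) {
  study_design(
    design_type = "cross_sectional",
    period = study_period("1998-01-01", "2019-12-31",
      entry_age_min = 18, entry_age_max = 100, exit_age_max = 105),
    entities = list(
      code_entity("Condition", c("C10F.00", "C10F.11"), "inclusion",
        "incident_or_prevalent")
    ),
    exposure_logic = "Condition",
    parsing_mode = "loose",
    seed = seed
  )
}
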