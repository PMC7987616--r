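#' Stage 4: matched-control selection
#'
#' `eligible_controls()` filters the potential-control pool for one exposed
#' member against the full criterion set, in the documented order: sex rule;
#' the control's window must cover the exposed's index date; age at index
#' within tolerance; Townsend quintile and ethnicity concordance when
#' requested; registration date within tolerance; exposure duration at
#' index within tolerance; baseline treatment and condition concordance
#' (the control has a pre-index record of each listed entity exactly when
#' the exposed does); measurement value within tolerance inside the
#' lookback window; and no listed outcome or event on or before the index
#' date.
#'
#' `run_stage4()` shuffles the exposed list and the pool with the seeded
#' generator, then for each exposed in shuffled order uniformly samples up
#' to the requested number of eligible controls without replacement
#' (selected controls leave the pool), assigns the exposed's index date to
#' its controls (so control follow-up starts when exposed follow-up does,
#' avoiding immortal time), and numbers groups consecutively in processing
#' order.  Exposed members with no eligible control are reported and either
#' kept unmatched (default) or dropped — only dropping enters the
#' attrition books, which count removals.  Pool members never selected are
#' logged as "potential control not selected".
#'
#' @param exposed one row of (or a tibble of) exposed members.
#' @param pool the potential-control member tibble.
#' @param criteria a [match_criteria()].
#' @param design the [study_design()] (for entity definitions).
#' @param db an [ehr_db()].
#' @return `eligible_controls()`: the eligible subset of `pool`.
#' @export
eligible_controls <- function(exposed, pool, criteria, design, db) {
  stopifnot(nrow(exposed) == 1)
  ctx <- match_context(design, criteria, db, bind_rows(pool, exposed))
  pc <- pool_precompute(pool, criteria, ctx)
  pool[match_filter(exposed, pc, criteria, ctx), ]
}

# per-patient entity lookups shared by all matching filters
match_context <- function(design, criteria, db, members) {
  ctx <- list(first_dates = list(), measurements = list())
  ents <- unique(c(
    criteria$baseline_conditions, criteria$baseline_treatments,
    criteria$exclude_outcomes_before_index, criteria$exclude_events_before_index,
    if (!is.null(criteria$exposure_duration)) criteria$exposure_duration$entity
  ))
  for (nm in ents) {
    fd <- entity_first_ever(members, design$entities[[nm]], db)
    ctx$first_dates[[nm]] <- setNames(as.numeric(fd$first_date), fd$patient_id)
  }
  for (m in criteria$measurement_matches) {
    ctx$measurements[[m$entity]] <- db$events |>
      filter(.data$code %in% design$entities[[m$entity]]$codes, !is.na(.data$value)) |>
      select("patient_id", "event_date", "value")
  }
  ctx
}

# vectors aligned to the pool rows, computed once per matching run
pool_precompute <- function(pool, criteria, ctx) {
  bl <- as.POSIXlt(pool$birth_date)
  pc <- list(
    ids = pool$patient_id,
    sex = pool$sex,
    by = bl$year, bm = bl$mon, bd = bl$mday,
    start = as.numeric(pool$patient_start),
    end = as.numeric(pool$patient_end),
    reg = as.numeric(pool$registration_date),
    townsend = pool$townsend_quintile,
    ethnicity = pool$ethnicity,
    first = list()
  )
  for (nm in names(ctx$first_dates)) {
    pc$first[[nm]] <- unname(ctx$first_dates[[nm]][pool$patient_id])
  }
  pc
}

latest_value_in <- function(meas, ids, from, to) {
  # latest recorded value per patient within [from, to]; NA when none
  sub <- meas |>
    filter(.data$patient_id %in% ids,
      .data$event_date >= from, .data$event_date <= to) |>
    group_by(.data$patient_id) |>
    slice_max(.data$event_date, n = 1, with_ties = FALSE) |>
    ungroup()
  unname(setNames(sub$value, sub$patient_id)[ids])
}

# logical vector over pool rows for one exposed member
match_filter <- function(exposed, pc, criteria, ctx) {
  idx <- exposed$index_date
  idx_n <- as.numeric(idx)
  il <- as.POSIXlt(idx)

  ok <- switch(criteria$sex_match,
    yes = pc$sex == exposed$sex,
    opposite = pc$sex != exposed$sex,
    any = rep(TRUE, length(pc$ids)))
  ok <- ok & pc$start <= idx_n & idx_n <= pc$end
  age_c <- il$year - pc$by - (il$mon < pc$bm | (il$mon == pc$bm & il$mday < pc$bd))
  age_e <- age_on(exposed$birth_date, idx)
  ok <- ok & abs(age_c - age_e) <= criteria$age_tolerance_years
  if (criteria$match_townsend) {
    ok <- ok & ((pc$townsend == exposed$townsend_quintile) %in% TRUE |
      (is.na(pc$townsend) & is.na(exposed$townsend_quintile)))
  }
  if (criteria$match_ethnicity) {
    ok <- ok & ((pc$ethnicity == exposed$ethnicity) %in% TRUE |
      (is.na(pc$ethnicity) & is.na(exposed$ethnicity)))
  }
  if (!is.null(criteria$registration_tolerance_days)) {
    ok <- ok & abs(pc$reg - as.numeric(exposed$registration_date)) <=
      criteria$registration_tolerance_days
  }
  if (!is.null(criteria$exposure_duration)) {
    ed <- criteria$exposure_duration
    d_e <- unname(ctx$first_dates[[ed$entity]][exposed$patient_id])
    if (length(d_e) == 1 && !is.na(d_e)) {
      d_c <- pc$first[[ed$entity]]
      ok <- ok & !is.na(d_c) & abs(d_c - d_e) <= ed$tolerance_days
    }
  }
  for (nm in c(criteria$baseline_treatments, criteria$baseline_conditions)) {
    d_e <- unname(ctx$first_dates[[nm]][exposed$patient_id])
    has_e <- isTRUE(d_e <= idx_n)
    d_c <- pc$first[[nm]]
    has_c <- !is.na(d_c) & d_c <= idx_n
    ok <- ok & (has_c == has_e)
  }
  for (m in criteria$measurement_matches) {
    if (!any(ok)) break
    meas <- ctx$measurements[[m$entity]]
    v_e <- latest_value_in(meas, exposed$patient_id, idx - m$lookback_days, idx)
    if (is.na(v_e)) next  # exposed has no value in window: criterion vacuous
    v_c <- latest_value_in(meas, pc$ids[ok], idx - m$lookback_days, idx)
    ok[ok] <- !is.na(v_c) & abs(v_c - v_e) <= m$value_tolerance
  }
  for (nm in c(criteria$exclude_outcomes_before_index, criteria$exclude_events_before_index)) {
    d_c <- pc$first[[nm]]
    ok <- ok & !(!is.na(d_c) & d_c <= idx_n)
  }
  ok
}

#' @rdname eligible_controls
#' @param members full member tibble from stage 3.
#' @param log a [rejection_log()].
#' @param seed integer seed driving the shuffles and sampling (the only
#'   stochastic step of the pipeline).
#' @return `run_stage4()`: `list(members =, matched_sets =, log =,
#'   unmatched_exposed =)`.  `matched_sets` has one row per matched pair
#'   `(group_id, exposed_id, control_id, match_order, index_date)`;
#'   unmatched exposed appear with `NA` control.  Members retain exposed +
#'   matched controls; matched controls carry their group's index date.
#' @export
run_stage4 <- function(members, design, db, log = rejection_log(),
                       seed = design$seed) {
  criteria <- design$match_criteria
  exposed <- members |> filter(.data$role == "exposed_or_case")
  pool <- members |> filter(.data$role == "potential_control")
  rest <- members |> filter(!.data$role %in% c("exposed_or_case", "potential_control"))

  ctx <- match_context(design, criteria, db, members)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  exposed <- exposed[sample.int(nrow(exposed)), ]
  pool <- pool[sample.int(nrow(pool)), ]
  pc <- pool_precompute(pool, criteria, ctx)
  available <- rep(TRUE, nrow(pool))

  sets <- vector("list", nrow(exposed))
  exposed$group_id <- seq_len(nrow(exposed))
  pool_group <- rep(NA_integer_, nrow(pool))
  pool_index <- as.Date(rep(NA_real_, nrow(pool)), origin = "1970-01-01")
  pool_order <- rep(NA_integer_, nrow(pool))

  for (i in seq_len(nrow(exposed))) {
    elig <- available & match_filter(exposed[i, ], pc, criteria, ctx)
    n_el <- sum(elig)
    k <- min(criteria$n_controls_per_exposed, n_el)
    chosen <- integer()
    if (k > 0) {
      cand <- which(elig)
      chosen <- cand[sample.int(n_el, k)]
      available[chosen] <- FALSE
      pool_group[chosen] <- i
      pool_index[chosen] <- exposed$index_date[i]
      pool_order[chosen] <- seq_len(k)
    }
    sets[[i]] <- tibble(
      group_id = i,
      exposed_id = exposed$patient_id[i],
      control_id = if (k > 0) pool$patient_id[chosen] else NA_character_,
      match_order = if (k > 0) seq_len(k) else NA_integer_,
      index_date = exposed$index_date[i]
    )
  }
  matched_sets <- if (nrow(exposed)) {
    bind_rows(sets)
  } else {
    tibble(group_id = integer(), exposed_id = character(),
      control_id = character(), match_order = integer(),
      index_date = as.Date(numeric(), origin = "1970-01-01"))
  }

  unmatched <- matched_sets |>
    filter(is.na(.data$control_id)) |>
    pull("exposed_id")
  if (criteria$unmatched == "drop") {
    # dropped unmatched exposed are removals, so they enter the attrition books
    log <- record_rejection(log, "stage4",
      rep("no eligible controls", length(unmatched)), unmatched)
    exposed <- exposed |> filter(!.data$patient_id %in% unmatched)
    matched_sets <- matched_sets |> filter(!.data$exposed_id %in% unmatched)
  }

  selected <- pool |>
    mutate(group_id = pool_group, index_date = pool_index, match_order = pool_order) |>
    filter(!is.na(.data$group_id)) |>
    mutate(role = "matched_control")
  not_selected <- pool$patient_id[is.na(pool_group)]
  log <- record_rejection(log, "stage4",
    rep("potential control not selected", length(not_selected)), not_selected)

  exposed$match_order <- 0L
  out <- bind_rows(rest, exposed, selected) |> arrange(.data$patient_id)
  list(members = out, matched_sets = matched_sets, log = log,
    unmatched_exposed = if (criteria$unmatched == "keep") unmatched else character())
}
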