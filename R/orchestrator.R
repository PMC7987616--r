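#' Plan the stages of an extraction
#'
#' The stage plan is a pure function of the design: cohort and case-control
#' designs run all six stages, with control selection and matching (stages
#' 3-4) only when controls are required; a cross-sectional design has no
#' control selection, matching or outcome stage, so only stages 1, 2 and 6
#' run.
#'
#' @param design a [study_design()].
#' @return a tibble `(stage, enabled)` over stages `stage1`..`stage6`.
#' @export
stage_plan <- function(design) {
  stopifnot(inherits(design, "study_design"))
  stages <- paste0("stage", 1:6)
  enabled <- if (design$design_type == "cross_sectional") {
    stages %in% c("stage1", "stage2", "stage6")
  } else {
    ctrl <- design$controls_required
    c(TRUE, TRUE, ctrl, ctrl && !is.null(design$match_criteria), TRUE, TRUE)
  }
  tibble(stage = stages, enabled = enabled)
}

member_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    practice_id = readr::col_character(),
    sex = readr::col_character(),
    birth_date = readr::col_date(),
    registration_date = readr::col_date(),
    townsend_quintile = readr::col_integer(),
    ethnicity = readr::col_character(),
    practice_start = readr::col_date(),
    practice_end = readr::col_date(),
    patient_start = readr::col_date(),
    patient_end = readr::col_date(),
    role = readr::col_character(),
    index_date = readr::col_date(),
    group_id = readr::col_integer(),
    exit_date = readr::col_date(),
    control_entity_date = readr::col_date(),
    match_order = readr::col_integer()
  )
}

write_checkpoint <- function(dir, stage, state, design_digest, db_digest, seed) {
  ckdir <- file.path(dir, "checkpoints", stage)
  dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(state$members, file.path(ckdir, "members.csv"), na = "")
  readr::write_csv(state$log, file.path(ckdir, "log.csv"), na = "")
  readr::write_csv(state$stage_io, file.path(ckdir, "stage_io.csv"), na = "")
  if (!is.null(state$matched_sets)) {
    readr::write_csv(state$matched_sets, file.path(ckdir, "matched_sets.csv"), na = "")
  }
  if (!is.null(state$outcomes)) {
    readr::write_csv(state$outcomes, file.path(ckdir, "outcomes.csv"), na = "")
  }
  jsonlite::write_json(
    list(stage = stage, design_digest = design_digest, database_digest = db_digest,
      seed = seed, unmatched_exposed = state$unmatched_exposed %||% character()),
    file.path(ckdir, "meta.json"), auto_unbox = TRUE, null = "null")
  invisible(ckdir)
}

read_checkpoint <- function(dir, stage) {
  ckdir <- file.path(dir, "checkpoints", stage)
  meta <- jsonlite::read_json(file.path(ckdir, "meta.json"), simplifyVector = TRUE)
  rd <- function(f, types = NULL) {
    p <- file.path(ckdir, f)
    if (!file.exists(p)) return(NULL)
    if (!is.null(types)) {
      # some columns (matching, control dates) exist only for some designs
      hdr <- strsplit(readLines(p, n = 1), ",")[[1]]
      types$cols <- types$cols[intersect(names(types$cols), hdr)]
    }
    readr::read_csv(p, col_types = types, progress = FALSE)
  }
  members <- rd("members.csv", member_col_types())
  log_raw <- rd("log.csv", readr::cols(.default = readr::col_character()))
  log <- rejection_log()
  if (nrow(log_raw)) log <- record_rejection(log, log_raw$stage, log_raw$reason, log_raw$patient_id)
  ms <- rd("matched_sets.csv", readr::cols(group_id = readr::col_integer(),
    exposed_id = readr::col_character(), control_id = readr::col_character(),
    match_order = readr::col_integer(), index_date = readr::col_date()))
  oc <- rd("outcomes.csv", readr::cols(patient_id = readr::col_character(),
    outcome = readr::col_character(), event_date = readr::col_date()))
  io <- rd("stage_io.csv", readr::cols(stage = readr::col_character(),
    n_in = readr::col_integer(), n_out = readr::col_integer()))
  list(members = members, log = log, matched_sets = ms, outcomes = oc,
    stage_io = io, meta = meta,
    unmatched_exposed = unlist(meta$unmatched_exposed) %||% character())
}

#' Run a full extraction
#'
#' Executes the stage plan for the design over the database, writing a
#' checkpoint after every stage, and emits into `out_dir`:
#' `dataset.csv` (the analysable dataset), `attrition.csv` (stage, reason,
#' count), `extraction_log.json` (the audit log, written for every attempt
#' including failures) and, when the design carries an encryption password,
#' `dataset.csv.enc`.  The attrition books must balance — at every stage,
#' patients in equals patients out plus logged rejections — or the run
#' fails; this is the pipeline's verifiability guarantee.
#'
#' With `resume = TRUE` and a compatible checkpoint present (same design
#' and database digests), completed stages are reloaded instead of re-run;
#' the final outputs are identical to an uninterrupted run.
#'
#' @param db an [ehr_db()] or a directory for [read_ehr_db()].
#' @param design a [study_design()] or a config path for
#'   [read_study_design()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides the design seed when given.
#' @param resume reuse compatible checkpoints when present.
#' @param stop_after run only up to this stage (e.g. `"stage3"`) — used to
#'   exercise interruption and resume.
#' @return an `ehr_extraction` object: the dataset, attrition table,
#'   rejection log, matched sets, outcome records, stage plan and in/out
#'   counts.  When stopped early, the partial state invisibly.
#' @export
run_extraction <- function(db, design, out_dir, seed = NULL, resume = FALSE,
                           stop_after = NULL) {
  if (is.character(db)) db <- read_ehr_db(db)
  if (is.character(design)) design <- read_study_design(design)
  stopifnot(inherits(db, "ehr_db"), inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% design$seed
  design_digest <- digest_design(design)
  db_digest <- digest_ehr_db(db)

  plan <- stage_plan(design)
  todo <- plan$stage[plan$enabled]

  state <- list(members = NULL, log = rejection_log(), matched_sets = NULL,
    outcomes = NULL, stage_io = tibble(stage = character(), n_in = integer(),
      n_out = integer()), unmatched_exposed = character())
  done <- character()
  if (resume) {
    # the assembly stage is cheap and its product is the output itself,
    # so it is always re-run rather than checkpoint-restored
    for (st in setdiff(todo, "stage6")) {
      ckmeta <- file.path(out_dir, "checkpoints", st, "meta.json")
      if (!file.exists(ckmeta)) break
      meta <- jsonlite::read_json(ckmeta, simplifyVector = TRUE)
      if (!identical(meta$design_digest, design_digest) ||
          !identical(meta$database_digest, db_digest) ||
          !identical(as.integer(meta$seed), as.integer(seed))) break
      done <- c(done, st)
    }
    if (length(done)) state <- read_checkpoint(out_dir, done[length(done)])
  }

  status <- "failed"
  on.exit({
    write_extraction_log(file.path(out_dir, "extraction_log.json"), design,
      db_digest, state$stage_io, status, seed)
  })

  for (st in setdiff(todo, done)) {
    n_in <- if (is.null(state$members)) nrow(db$patients) else nrow(state$members)
    state <- execute_stage(st, state, db, design, seed)
    state$stage_io <- bind_rows(state$stage_io,
      tibble(stage = st, n_in = as.integer(n_in), n_out = nrow(state$members)))
    write_checkpoint(out_dir, st, state, design_digest, db_digest, seed)
    if (!is.null(stop_after) && st == stop_after) {
      status <- "interrupted"
      return(invisible(state))
    }
  }

  attrition <- attrition_table(state$log, state$stage_io)
  dataset <- state$dataset
  readr::write_csv(dataset, file.path(out_dir, "dataset.csv"), na = "")
  readr::write_csv(as_tibble(attrition), file.path(out_dir, "attrition.csv"), na = "")
  if (!is.null(design$encrypt_password)) {
    encrypt_file(file.path(out_dir, "dataset.csv"), design$encrypt_password)
  }
  status <- "complete"

  structure(
    list(dataset = dataset, attrition = attrition, log = state$log,
      matched_sets = state$matched_sets, outcomes = state$outcomes,
      stage_io = state$stage_io, plan = plan, design = design,
      unmatched_exposed = state$unmatched_exposed, out_dir = out_dir,
      seed = seed),
    class = "ehr_extraction"
  )
}

execute_stage <- function(stage, state, db, design, seed) {
  switch(stage,
    stage1 = {
      r <- run_stage1(db, design, state$log)
      state$members <- r$members
      state$log <- r$log
    },
    stage2 = {
      r <- run_stage2(state$members, design, db, state$log)
      state$members <- r$members
      state$log <- r$log
    },
    stage3 = {
      r <- run_stage3(state$members, design, db, state$log)
      state$members <- r$members
      state$log <- r$log
    },
    stage4 = {
      r <- run_stage4(state$members, design, db, state$log, seed = seed)
      state$members <- r$members
      state$matched_sets <- r$matched_sets
      state$log <- r$log
      state$unmatched_exposed <- r$unmatched_exposed
    },
    stage5 = {
      r <- run_stage5(state$members, design, db)
      state$members <- r$members
      state$outcomes <- r$outcomes
    },
    stage6 = {
      state$dataset <- assemble_dataset(state$members, state$outcomes, design, db)
    }
  )
  state
}

#' @export
print.ehr_extraction <- function(x, ...) {
  cat("<ehr_extraction> ", x$design$design_type, " design: ",
    nrow(x$dataset), " rows (",
    sum(x$dataset$exposed_flag == 1L), " exposed/case)\n", sep = "")
  cat("stage flow:\n")
  io <- x$stage_io
  for (i in seq_len(nrow(io))) {
    cat(sprintf("  %s: %d -> %d\n", io$stage[i], io$n_in[i], io$n_out[i]))
  }
  invisible(x)
}
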