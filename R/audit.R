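#' Rejection logging and attrition accounting
#'
#' Every patient removed at any pipeline stage is recorded against a
#' documented reason; the attrition table derived from the log is the
#' pipeline's verifiability guarantee: at every stage
#' `patients in = patients out + rejections logged`, and
#' [attrition_table()] fails loudly when the books do not balance.
#'
#' `rejection_log()` creates an empty log; [record_rejection()] adds one
#' patient (a reason seen for the first time enters with count 1, a repeat
#' increments it — counts are derived from the stored rows).
#'
#' @return `rejection_log()`: an empty `rejection_log` tibble with columns
#'   `stage`, `reason`, `patient_id`.
#' @export
rejection_log <- function() {
  structure(
    tibble(stage = character(), reason = character(), patient_id = character()),
    class = c("rejection_log", class(tibble()))
  )
}

#' @rdname rejection_log
#' @param log a `rejection_log`.
#' @param stage stage identifier, e.g. `"stage1"`.
#' @param reason documented reason string (one per patient).
#' @param patient_id patient identifier(s); `reason` is recycled.
#' @export
record_rejection <- function(log, stage, reason, patient_id) {
  if (length(patient_id) == 0) return(log)
  new <- tibble(stage = stage, reason = reason, patient_id = as.character(patient_id))
  structure(bind_rows(log, new), class = class(log))
}

#' @rdname rejection_log
#' @export
rejection_counts <- function(log) {
  log |>
    count(.data$stage, .data$reason, name = "count") |>
    arrange(.data$stage, .data$reason)
}

#' Build and verify the attrition table
#'
#' @param log a [rejection_log()].
#' @param stage_io tibble with columns `stage`, `n_in`, `n_out` as recorded
#'   by the orchestrator.
#' @return an `attrition_table`: tibble `(stage, reason, count)` with
#'   attributes `stage_io` and `consistent`.  Inconsistency (a stage whose
#'   `n_in - n_out` differs from its logged rejections) raises an error
#'   unless `error_on_mismatch = FALSE`.
#' @param error_on_mismatch raise on imbalance (default) or just flag it.
#' @export
attrition_table <- function(log, stage_io, error_on_mismatch = TRUE) {
  counts <- rejection_counts(log)
  chk <- stage_io |>
    left_join(counts |> group_by(.data$stage) |> summarise(rejected = sum(.data$count)),
      by = "stage") |>
    mutate(rejected = coalesce(.data$rejected, 0L),
      balanced = (.data$n_in - .data$n_out) == .data$rejected)
  ok <- all(chk$balanced)
  if (!ok && error_on_mismatch) {
    bad <- chk[!chk$balanced, ]
    abort(paste0("attrition imbalance at ", paste0(bad$stage, collapse = ", "),
      ": in - out != logged rejections"))
  }
  structure(counts, stage_io = chk, consistent = ok,
    class = c("attrition_table", class(counts)))
}

#' @export
print.attrition_table <- function(x, ...) {
  cat("<attrition_table> ", if (attr(x, "consistent")) "consistent" else "INCONSISTENT",
    "\n", sep = "")
  NextMethod()
}

#' Write the per-extraction audit log
#'
#' An extraction log is written for every attempt, successful or not:
#' timestamp, digests of the design and database, seed, package version,
#' per-stage in/out counts and the completion status.
#'
#' @param path output JSON path.
#' @param design a [study_design()].
#' @param db_digest SHA-256 digest of the database files (see
#'   [digest_ehr_db()]).
#' @param stage_io per-stage in/out counts tibble.
#' @param status "complete", "failed" or "invalid-design".
#' @param seed the seed in force.
#' @return `path`, invisibly.
#' @export
write_extraction_log <- function(path, design, db_digest, stage_io, status, seed) {
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    software = paste0("ehretl ", as.character(packageVersion("ehretl"))),
    design_digest = digest_design(design),
    database_digest = db_digest,
    seed = seed,
    stages = stage_io,
    status = status
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Digests used in audit logs and checkpoint validation
#'
#' SHA-256 over the canonical serialized design / the three database
#' tables, so a checkpoint can prove it belongs to the same inputs.
#'
#' @param design a [study_design()].
#' @return a hex digest string.
#' @export
digest_design <- function(design) {
  json <- jsonlite::toJSON(design_to_list(design), auto_unbox = TRUE, null = "null")
  as.vector(as.character(openssl::sha256(charToRaw(as.character(json)))))
}

#' @rdname digest_design
#' @param db an [ehr_db()].
#' @export
digest_ehr_db <- function(db) {
  payload <- paste(
    readr::format_csv(db$practices, na = ""),
    readr::format_csv(db$patients, na = ""),
    readr::format_csv(db$events, na = ""),
    sep = "\n"
  )
  as.vector(as.character(openssl::sha256(charToRaw(payload))))
}
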