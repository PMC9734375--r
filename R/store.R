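# Plain-text persistence of a tracker as a store directory:
#   ledger.csv    — the Data table (seq,date,sample,activity,wells_used,
#                   plate_size,note,user,machine), RFC 4180, UTF-8;
#   vocab.csv     — the controlled vocabulary (field,term);
#   metadata.json — the transfection metadata sheets.
# Loading replays the ledger through the registry state machine, so the loaded
# tracker is identical to the one that wrote the store.

CT_LEDGER_COLUMNS <- c(
  "seq", "date", "sample", "activity", "wells_used", "plate_size",
  "note", "user", "machine"
)

#' Save / load a tracker as a plain-text store directory
#'
#' @param tracker A `clonetrack_tracker`.
#' @param dir Store directory (created if missing on save).
#' @return `save_tracker()` returns `dir` invisibly; `load_tracker()` returns
#'   the reconstructed tracker.
#' @export
save_tracker <- function(tracker, dir) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_table(tracker$records, "csv", file.path(dir, "ledger.csv"))
  write_vocabulary(tracker$vocab, file.path(dir, "vocab.csv"))
  metas <- lapply(tracker$metadata, function(m) {
    list(
      name = format_name(m$name),
      plasmid_components = m$plasmid_components,
      guide_rna = m$guide_rna,
      electroporation_program = m$electroporation_program,
      cell_count = m$cell_count,
      reagent_inputs = m$reagent_inputs,
      vessel_capacity = m$vessel_capacity,
      notes = m$notes,
      attachments = m$attachments
    )
  })
  jsonlite::write_json(metas, file.path(dir, "metadata.json"),
    auto_unbox = TRUE, null = "null", na = "null", digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname save_tracker
#' @export
load_tracker <- function(dir) {
  vocab <- read_vocabulary(file.path(dir, "vocab.csv"))
  raw <- import_table(file.path(dir, "ledger.csv"), "csv")
  if (!identical(names(raw), CT_LEDGER_COLUMNS)) {
    ct_abort("ledger.csv does not have the expected columns", "clonetrack_parse_error")
  }
  records <- tibble::tibble(
    seq = as.integer(raw$seq),
    date = as.Date(raw$date),
    sample = raw$sample,
    activity = raw$activity,
    wells_used = as.integer(raw$wells_used),
    plate_size = as.integer(raw$plate_size),
    note = ifelse(is.na(raw$note), "", raw$note),
    user = raw$user,
    machine = raw$machine
  )
  tracker <- clonetrack(vocab)
  tracker$records <- records
  tracker$registry <- build_registry(records, vocab)
  meta_path <- file.path(dir, "metadata.json")
  if (file.exists(meta_path)) {
    metas <- jsonlite::read_json(meta_path)
    for (m in metas) {
      nm <- parse_name(m$name, vocab)
      ri <- NULL
      if (!is.null(m$reagent_inputs)) {
        ri <- tibble::tibble(
          reagent = vapply(m$reagent_inputs, function(r) as.character(r$reagent), ""),
          stock_conc = vapply(m$reagent_inputs, function(r) as.numeric(r$stock_conc), 0),
          target_amount = vapply(m$reagent_inputs, function(r) as.numeric(r$target_amount), 0)
        )
      }
      tracker$metadata[[m$name]] <- transfection_metadata(
        nm,
        plasmid_components = as.character(unlist(m$plasmid_components)),
        guide_rna = m$guide_rna,
        electroporation_program = if (is.null(m$electroporation_program)) {
          NA_character_
        } else {
          m$electroporation_program
        },
        cell_count = if (is.null(m$cell_count)) NA_real_ else as.numeric(m$cell_count),
        reagent_inputs = ri,
        vessel_capacity = if (is.null(m$vessel_capacity)) {
          NA_real_
        } else {
          as.numeric(m$vessel_capacity)
        },
        notes = if (is.null(m$notes)) "" else m$notes,
        attachments = as.character(unlist(m$attachments))
      )
    }
  }
  tracker
}
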