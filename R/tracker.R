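# The tracker bundles the append-only activity ledger (the Data worksheet),
# the transfection metadata records, the controlled vocabulary in force, and
# the sample registry derived from the ledger. All operations are value
# semantics: they return a new tracker and never mutate their argument, so the
# ledger is append-only by construction and the registry is a pure function of
# the record sequence (replay equivalence).

ct_empty_records <- function() {
  tibble::tibble(
    seq = integer(), date = as.Date(character()), sample = character(),
    activity = character(), wells_used = integer(), plate_size = integer(),
    note = character(), user = character(), machine = character()
  )
}

ct_empty_registry <- function() {
  tibble::tibble(
    name = character(), parent = character(), created_seq = integer(),
    status = character(), well = character(), sort_index = integer()
  )
}

#' Create an empty tracker
#'
#' @param vocab Controlled vocabulary in force; defaults to
#'   [default_vocabulary()].
#' @param capture_user If `TRUE`, new records carry the current login and host
#'   name (off by default; opt-in provenance capture).
#' @return A `clonetrack_tracker` with an empty ledger and registry.
#' @examples
#' tr <- clonetrack()
#' nrow(tr$records)
#' @export
clonetrack <- function(vocab = default_vocabulary(), capture_user = FALSE) {
  stopifnot(inherits(vocab, "clonetrack_vocabulary"))
  structure(
    list(
      vocab = vocab,
      records = ct_empty_records(),
      registry = ct_empty_registry(),
      metadata = list(),
      capture_user = isTRUE(capture_user)
    ),
    class = "clonetrack_tracker"
  )
}

# One step of the registry state machine. Creation rules:
#   * Transfect on an unregistered base-level name -> new root;
#   * any record whose sample is an unregistered clone-level name (well, no
#     sort) with a registered parent -> clone designation, new child;
#   * Sort on a registered clone-level sample -> child named by
#     derive_sort_name (a chain: Sort2's parent is Sort1);
#   * Discontinue -> status flip; everything else leaves the registry alone.
ct_registry_apply <- function(registry, seq, sample, activity, vocab) {
  registered <- sample %in% registry$name
  parsed <- NULL
  if (!registered) {
    parsed <- parse_name(sample, vocab)
    if (identical(activity, "Transfect")) {
      if (!is.null(parsed$well) || !is.null(parsed$sort_index)) {
        ct_abort(
          sprintf("'%s' is not a base-level transfection designator", sample),
          "clonetrack_name_error"
        )
      }
      registry <- ct_registry_add(registry, sample, NA_character_, seq, parsed)
    } else if (!is.null(parsed$well) && is.null(parsed$sort_index)) {
      parent <- format_name(sample_name(parsed$date, parsed$fp, parsed$gene, parsed$guide))
      if (!parent %in% registry$name) {
        ct_abort(
          sprintf("parent transfection '%s' of clone '%s' is not registered",
            parent, sample),
          "clonetrack_lookup_error"
        )
      }
      registry <- ct_registry_add(registry, sample, parent, seq, parsed)
    } else {
      ct_abort(
        sprintf("unknown sample '%s'", sample),
        "clonetrack_lookup_error"
      )
    }
    return(registry)
  }
  if (identical(activity, "Transfect")) {
    ct_abort(
      sprintf("transfection designator '%s' already registered", sample),
      "clonetrack_uniqueness_error"
    )
  }
  if (identical(activity, "Sort")) {
    parsed <- parse_name(sample, vocab)
    child <- derive_sort_name(parsed) # errors on non-clone-level input
    child_txt <- format_name(child)
    if (child_txt %in% registry$name) {
      ct_abort(
        sprintf("sorted sample '%s' already registered", child_txt),
        "clonetrack_duplicate_error"
      )
    }
    registry <- ct_registry_add(registry, child_txt, sample, seq, child)
  } else if (identical(activity, "Discontinue")) {
    registry$status[registry$name == sample] <- "discontinued"
  }
  registry
}

ct_registry_add <- function(registry, name, parent, seq, parsed) {
  rbind(
    registry,
    tibble::tibble(
      name = name, parent = parent, created_seq = as.integer(seq),
      status = "active",
      well = if (is.null(parsed$well)) NA_character_ else well_label(parsed$well),
      sort_index = if (is.null(parsed$sort_index)) NA_integer_ else parsed$sort_index
    )
  )
}

#' Append an activity record to the ledger
#'
#' Records one dated activity performed on a sample: the row of the tabular
#' Data worksheet. The activity must validate against the vocabulary in force;
#' the sample must be registered, except when the record itself creates it
#' (`Transfect` on a new base designator, or a clone designation recorded
#' against the new clone-level name — see [designate_clone()]). Entries may
#' carry any date, past, current or future: the calendar is also a planning
#' tool. Recording against a discontinued sample succeeds but raises a warning
#' and stamps the note, since `Discontinue` is a bookkeeping label rather than
#' a hard terminal state.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param date Activity date.
#' @param sample Sample designator text.
#' @param activity Activity term (validated against the vocabulary).
#' @param wells_used,plate_size Optional plate bookkeeping for the entry.
#' @param note Free-text note.
#' @param user,machine Optional provenance fields; filled automatically when
#'   the tracker was created with `capture_user = TRUE`.
#' @return The tracker with one more record (and any registry update replayed).
#' @export
record_activity <- function(tracker, date, sample, activity,
                            wells_used = NA, plate_size = NA, note = "",
                            user = NA, machine = NA) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  date <- as.Date(date)
  if (is.na(date)) ct_abort("invalid record date", "clonetrack_date_error")
  v <- validate_term(tracker$vocab, "activity", activity)
  if (!v$accept) {
    ct_abort(
      sprintf("'%s' is not an activity of the vocabulary", activity),
      "clonetrack_validation_error"
    )
  }
  activity <- v$canonical
  if (sample %in% tracker$registry$name &&
    tracker$registry$status[tracker$registry$name == sample] == "discontinued") {
    note <- if (nzchar(note)) {
      paste0(note, " [recorded on discontinued sample]")
    } else {
      "[recorded on discontinued sample]"
    }
    ct_warn(
      sprintf("sample '%s' is discontinued", sample),
      "clonetrack_discontinued_warning"
    )
  }
  if (isTRUE(tracker$capture_user)) {
    if (is.na(user)) user <- unname(Sys.info()[["user"]])
    if (is.na(machine)) machine <- unname(Sys.info()[["nodename"]])
  }
  seq <- nrow(tracker$records) + 1L
  tracker$registry <- ct_registry_apply(
    tracker$registry, seq, sample, activity, tracker$vocab
  )
  tracker$records <- rbind(
    tracker$records,
    tibble::tibble(
      seq = seq, date = date, sample = sample, activity = activity,
      wells_used = as.integer(wells_used), plate_size = as.integer(plate_size),
      note = as.character(note), user = as.character(user),
      machine = as.character(machine)
    )
  )
  tracker
}

#' Start a new transfection
#'
#' Formats the designator from the metadata's base name, appends the
#' `Transfect` record that roots a new lineage, registers the root sample, and
#' files the metadata under the designator.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param meta A [transfection_metadata()] record.
#' @param date Transfection date; defaults to the date in `meta$name`.
#' @param ... Passed to [record_activity()] (e.g. `note`, `wells_used`).
#' @return The tracker with the transfection registered. The designator is
#'   `format_name(meta$name)`.
#' @export
new_transfection <- function(tracker, meta, date = meta$name$date, ...) {
  stopifnot(inherits(tracker, "clonetrack_tracker"),
    inherits(meta, "clonetrack_metadata"))
  designator <- format_name(meta$name)
  if (designator %in% tracker$registry$name) {
    ct_abort(
      sprintf("transfection designator '%s' already registered", designator),
      "clonetrack_uniqueness_error"
    )
  }
  tracker <- record_activity(tracker, date, designator, "Transfect", ...)
  tracker$metadata[[designator]] <- meta
  tracker
}

#' Designate a new clone
#'
#' When fluorescence imaging identifies an edited colony in a well, the clone
#' receives the transfection designator with the well appended, and a record of
#' the triggering activity (imaging by default) is entered against the new
#' name. The registry links the clone to its parent transfection.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param designator Registered base transfection designator.
#' @param well Well label or `clonetrack_well` where the clone was observed.
#' @param date Date of designation.
#' @param activity Activity term recorded with the designation.
#' @param ... Passed to [record_activity()].
#' @return The tracker with the clone registered.
#' @export
designate_clone <- function(tracker, designator, well, date,
                            activity = "Image", ...) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  if (!designator %in% tracker$registry$name) {
    ct_abort(
      sprintf("unknown transfection '%s'", designator),
      "clonetrack_lookup_error"
    )
  }
  base <- parse_name(designator, tracker$vocab)
  clone <- format_name(derive_clone_name(base, well))
  if (clone %in% tracker$registry$name) {
    ct_abort(
      sprintf("well already occupied: clone '%s' exists", clone),
      "clonetrack_duplicate_error"
    )
  }
  record_activity(tracker, date, clone, activity, ...)
}

#' Sort a sample
#'
#' Records a `Sort` activity on a clone-level sample; the registry derives the
#' child population with the sort index incremented (`_Sort1`, `_Sort2`, ...).
#'
#' @inheritParams record_activity
#' @param ... Passed to [record_activity()].
#' @return The tracker with the sorted population registered.
#' @export
sort_sample <- function(tracker, sample, date, ...) {
  record_activity(tracker, date, sample, "Sort", ...)
}

#' Rebuild a registry by replaying ledger records
#'
#' The registry is a pure function of the record sequence; this replays it from
#' scratch, which is how a tracker is reconstructed from a persisted ledger
#' CSV.
#'
#' @param records A ledger records tibble.
#' @param vocab The vocabulary in force.
#' @return A registry tibble.
#' @export
build_registry <- function(records, vocab) {
  registry <- ct_empty_registry()
  for (i in seq_len(nrow(records))) {
    registry <- ct_registry_apply(
      registry, records$seq[[i]], records$sample[[i]], records$activity[[i]], vocab
    )
  }
  registry
}

#' Filter ledger records
#'
#' Returns matching records in `(date, seq)` order as a report table; the
#' ledger itself is unchanged. Named filters combine with AND; `predicate` may
#' supply any row-wise condition as a function of the records tibble.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param activity,sample Optional exact-match filters.
#' @param from,to Optional inclusive date bounds.
#' @param predicate Optional `function(records) -> logical vector`.
#' @return A `clonetrack_report` tibble with ledger columns.
#' @export
filter_records <- function(tracker, activity = NULL, sample = NULL,
                           from = NULL, to = NULL, predicate = NULL) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  recs <- tracker$records
  keep <- rep(TRUE, nrow(recs))
  if (!is.null(activity)) keep <- keep & recs$activity %in% activity
  if (!is.null(sample)) keep <- keep & recs$sample %in% sample
  if (!is.null(from)) keep <- keep & recs$date >= as.Date(from)
  if (!is.null(to)) keep <- keep & recs$date <= as.Date(to)
  if (!is.null(predicate)) keep <- keep & predicate(recs)
  out <- recs[keep, , drop = FALSE]
  out <- out[order(out$date, out$seq), , drop = FALSE]
  ct_as_report(out, query = "filter_records", ledger_length = nrow(recs))
}

#' @export
print.clonetrack_tracker <- function(x, ...) {
  cat(sprintf(
    "<clonetrack tracker> %d records, %d samples (%d transfections), %d metadata sheets\n",
    nrow(x$records), nrow(x$registry), sum(is.na(x$registry$parent)),
    length(x$metadata)
  ))
  invisible(x)
}
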