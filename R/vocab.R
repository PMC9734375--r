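# Controlled vocabularies restricting data entry: the activity list used on the
# calendar, plus the term lists behind each metadata field. Terms are stored
# case-sensitively; only fluorescent-protein matching is case-insensitive (the
# worked dataset itself mixes "mCh" and "mCH" in sample names).

CT_VOCAB_FIELDS <- c(
  "fluorescent_protein", "gene", "guide_rna", "plasmid_component",
  "electroporation_program", "plate_format", "medium"
)

#' Default controlled vocabulary
#'
#' Returns the vocabulary a fresh tracker starts from. The activity list is the
#' twelve calendar activities of the knock-in workflow, in their canonical
#' order (including the historical spelling "Feed w mTeSr+"). Field lists are
#' seeded only with tokens that the workflow's worked dataset actually uses
#' (`mCh`, `OCT4`, `sg2`, 96-well plates); laboratories extend them with
#' [amend_vocabulary()] or a vocabulary CSV.
#'
#' @return A `clonetrack_vocabulary` object: activity list, named field lists,
#'   and an edit-protection flag (initially unlocked).
#' @examples
#' v <- default_vocabulary()
#' v$activities
#' @export
default_vocabulary <- function() {
  structure(
    list(
      activities = c(
        "Transfect", "Feed w Ri", "Image", "Passage", "Sort", "Freeze",
        "Thaw", "Extract DNA", "Feed w mTeSR++Ri", "Feed w mTeSr+",
        "Discontinue", "Send out for analysis"
      ),
      fields = list(
        fluorescent_protein = "mCh",
        gene = "OCT4",
        guide_rna = "sg2",
        plasmid_component = character(),
        electroporation_program = character(),
        plate_format = "96",
        medium = character()
      ),
      locked = FALSE,
      token = NULL
    ),
    class = "clonetrack_vocabulary"
  )
}

ct_vocab_list <- function(vocab, field) {
  if (identical(field, "activity")) {
    return(vocab$activities)
  }
  if (!field %in% names(vocab$fields)) {
    ct_abort(
      sprintf("unknown vocabulary field '%s'", field),
      "clonetrack_config_error"
    )
  }
  vocab$fields[[field]]
}

#' Validate a term against the vocabulary
#'
#' A term is accepted iff it is in the list for `field` (`"activity"` or one of
#' the metadata fields). Fluorescent-protein terms match case-insensitively;
#' the verdict then carries the stored canonical casing. All other fields match
#' case-sensitively.
#'
#' @param vocab A `clonetrack_vocabulary`.
#' @param field `"activity"` or a metadata field name such as `"guide_rna"`.
#' @param term Term to check.
#' @return A list with elements `accept` (logical) and `canonical` (the stored
#'   spelling when accepted, otherwise `NA`).
#' @examples
#' validate_term(default_vocabulary(), "activity", "Sort")$accept
#' validate_term(default_vocabulary(), "fluorescent_protein", "mCH")$canonical
#' @export
validate_term <- function(vocab, field, term) {
  stopifnot(inherits(vocab, "clonetrack_vocabulary"))
  terms <- ct_vocab_list(vocab, field)
  if (identical(field, "fluorescent_protein")) {
    hit <- match(tolower(term), tolower(terms))
  } else {
    hit <- match(term, terms)
  }
  if (is.na(hit)) {
    list(accept = FALSE, canonical = NA_character_)
  } else {
    list(accept = TRUE, canonical = terms[[hit]])
  }
}

#' Amend a vocabulary list
#'
#' Adds or removes a term, returning a new vocabulary (the original is never
#' mutated). Added terms go to the end of their list; duplicates are rejected.
#' A locked vocabulary requires the unlock token that locked it — the analogue
#' of sheet protection, an anti-accident device rather than a security one.
#' When a tracker is supplied, removal of a term still referenced by its ledger
#' or registry fails with a referential-integrity error.
#'
#' @param vocab A `clonetrack_vocabulary`.
#' @param field `"activity"` or a metadata field name.
#' @param change `"add"` or `"remove"`.
#' @param term The term to add or remove.
#' @param unlock Unlock token, required when the vocabulary is locked.
#' @param tracker Optional `clonetrack_tracker` to scan for term usage before a
#'   removal.
#' @return The amended vocabulary; its lock state is preserved.
#' @examples
#' v <- amend_vocabulary(default_vocabulary(), "fluorescent_protein", "add", "GFP")
#' v$fields$fluorescent_protein
#' @export
amend_vocabulary <- function(vocab, field, change = c("add", "remove"), term,
                             unlock = NULL, tracker = NULL) {
  stopifnot(inherits(vocab, "clonetrack_vocabulary"))
  change <- match.arg(change)
  if (isTRUE(vocab$locked)) {
    if (is.null(unlock) || !identical(unlock, vocab$token)) {
      ct_abort(
        "vocabulary is protected; supply the unlock token to amend it",
        "clonetrack_protection_error"
      )
    }
  }
  terms <- ct_vocab_list(vocab, field)
  if (change == "add") {
    if (term %in% terms) {
      ct_abort(
        sprintf("term '%s' already present in '%s'", term, field),
        "clonetrack_duplicate_error"
      )
    }
    terms <- c(terms, term)
  } else {
    if (!term %in% terms) {
      ct_abort(
        sprintf("term '%s' not present in '%s'", term, field),
        "clonetrack_lookup_error"
      )
    }
    if (!is.null(tracker)) {
      ct_check_term_unused(tracker, field, term)
    }
    terms <- setdiff(terms, term)
    if (identical(field, "activity") && length(terms) == 0L) {
      ct_abort("activities list must stay non-empty", "clonetrack_validation_error")
    }
  }
  if (identical(field, "activity")) {
    vocab$activities <- terms
  } else {
    vocab$fields[[field]] <- terms
  }
  vocab
}

# Referential-integrity scan: a term in use by the ledger (activity) or
# encoded in a registered sample name (fp / guide) cannot be removed.
ct_check_term_unused <- function(tracker, field, term) {
  in_use <- FALSE
  if (identical(field, "activity")) {
    in_use <- term %in% tracker$records$activity
  } else if (field %in% c("fluorescent_protein", "guide_rna")) {
    for (nm in tracker$registry$name) {
      parsed <- try(parse_name(nm, tracker$vocab), silent = TRUE)
      if (inherits(parsed, "try-error")) next
      tok <- if (field == "fluorescent_protein") parsed$fp else parsed$guide
      same <- if (field == "fluorescent_protein") {
        identical(tolower(tok), tolower(term))
      } else {
        identical(tok, term)
      }
      if (same) {
        in_use <- TRUE
        break
      }
    }
  }
  if (in_use) {
    ct_abort(
      sprintf("term '%s' is referenced by existing records; cannot remove", term),
      "clonetrack_integrity_error"
    )
  }
  invisible(TRUE)
}

#' Lock or unlock a vocabulary
#'
#' Locking stores a token; subsequent amendments must supply it. Unlocking
#' requires the same token.
#'
#' @param vocab A `clonetrack_vocabulary`.
#' @param token Passphrase string.
#' @return The vocabulary with its protection state changed.
#' @export
lock_vocabulary <- function(vocab, token) {
  stopifnot(inherits(vocab, "clonetrack_vocabulary"), is.character(token))
  vocab$locked <- TRUE
  vocab$token <- token
  vocab
}

#' @rdname lock_vocabulary
#' @export
unlock_vocabulary <- function(vocab, token) {
  stopifnot(inherits(vocab, "clonetrack_vocabulary"))
  if (!identical(token, vocab$token)) {
    ct_abort("wrong unlock token", "clonetrack_protection_error")
  }
  vocab$locked <- FALSE
  vocab$token <- NULL
  vocab
}

#' Read / write a vocabulary as a two-column CSV
#'
#' The on-disk form is `field,term` (RFC 4180, UTF-8, header row); the reserved
#' field value `activity` populates the activity list. Term order in the file
#' is list order. Lock state is runtime configuration and is not persisted.
#'
#' @param path File path.
#' @param vocab A `clonetrack_vocabulary`.
#' @return `read_vocabulary()` returns a vocabulary; `write_vocabulary()`
#'   returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE
  )
  if (!identical(names(df), c("field", "term"))) {
    ct_abort("vocabulary file must have columns field,term", "clonetrack_parse_error")
  }
  vocab <- default_vocabulary()
  vocab$activities <- character()
  vocab$fields[] <- list(character())
  for (i in seq_len(nrow(df))) {
    vocab <- amend_vocabulary(vocab, df$field[[i]], "add", df$term[[i]])
  }
  if (length(vocab$activities) == 0L) {
    ct_abort("vocabulary file defines no activities", "clonetrack_validation_error")
  }
  vocab
}

#' @rdname read_vocabulary
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "clonetrack_vocabulary"))
  rows <- tibble::tibble(
    field = c(
      rep("activity", length(vocab$activities)),
      rep(names(vocab$fields), lengths(vocab$fields))
    ),
    term = c(vocab$activities, unlist(vocab$fields, use.names = FALSE))
  )
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @export
print.clonetrack_vocabulary <- function(x, ...) {
  cat("<clonetrack vocabulary>",
    if (isTRUE(x$locked)) "(locked)" else "(unlocked)", "\n"
  )
  cat("  activities:", paste(x$activities, collapse = ", "), "\n")
  for (f in names(x$fields)) {
    cat(sprintf("  %s: %s\n", f, paste(x$fields[[f]], collapse = ", ")))
  }
  invisible(x)
}
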