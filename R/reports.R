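# Recomputable queries over the ledger. Every report is a pure function of
# (ledger, registry, inputs): regenerating it on an extended ledger extends,
# never reorders, the earlier rows (refresh semantics). Reports carry their
# provenance (generating query and ledger length at generation) as attributes.

# Activities relevant to the passage count, plus the milestone activities at
# which the running count is read off.
CT_PASSAGE_ACTIVITIES <- c(
  "Passage", "Freeze", "Thaw", "Send out for analysis", "Extract DNA"
)

CT_ANALYSIS_COLUMNS <- c(
  "clone", "date_sent", "passage_at_analysis", "fp_copy_number", "cnv_flag",
  "insertion_site_pcr", "extra_insertion_flag", "phenotype_note",
  "mycoplasma", "str_markers", "data_url"
)

ct_as_report <- function(df, query, ledger_length) {
  attr(df, "provenance") <- list(query = query, ledger_length = ledger_length)
  class(df) <- unique(c("clonetrack_report", class(df)))
  df
}

#' Report of all records with a given activity
#'
#' The analogue of the per-activity report sheets (TransfectionsReport,
#' FreezeReport, DiscontinueReport, ...): all ledger rows with that activity,
#' all columns retained, in `(date, seq)` order.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param activity Activity term; must be in the vocabulary.
#' @return A `clonetrack_report` tibble.
#' @export
activity_report <- function(tracker, activity) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  if (!validate_term(tracker$vocab, "activity", activity)$accept) {
    ct_abort(
      sprintf("'%s' is not an activity of the vocabulary", activity),
      "clonetrack_validation_error"
    )
  }
  out <- filter_records(tracker, activity = activity)
  ct_as_report(out, paste0("activity_report:", activity), nrow(tracker$records))
}

#' Report of all activity on one transfection's lineage
#'
#' All records for the root and every sample derived from it, in `(date, seq)`
#' order — the per-transfection report sheet.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param designator Registered root transfection designator.
#' @return A `clonetrack_report` tibble.
#' @export
transfection_report <- function(tracker, designator) {
  members <- transfection_members(tracker, designator)
  out <- filter_records(tracker, sample = members)
  ct_as_report(out, paste0("transfection_report:", designator), nrow(tracker$records))
}

#' Passage-count table for a clone
#'
#' Restricts the clone lineage's records (the clone, its ancestors, and the
#' sorted populations derived from it) to the passage-relevant activities —
#' Passage, Freeze, Thaw, plus the Extract DNA and Send-out milestones — and
#' annotates each row with the cumulative number of Passage activities up to
#' and including it. Reading the count at a Freeze or Send-out row gives the
#' passage number of the banked or analyzed sample. Counting is cumulative
#' across Freeze/Thaw (no reset); `lineage = "clone"` restricts to the clone
#' and its descendants, excluding passages of the pre-designation pool.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param clone Registered clone-level designator.
#' @param lineage `"full"` (default: ancestors included) or `"clone"`.
#' @return A `clonetrack_report` tibble: ledger columns plus `passages`.
#' @export
passage_table <- function(tracker, clone, lineage = c("full", "clone")) {
  lineage <- match.arg(lineage)
  ct_require_registered(tracker, clone)
  fam <- c(
    if (lineage == "full") ancestors(tracker, clone) else clone,
    descendants(tracker, clone)
  )
  out <- filter_records(tracker,
    sample = unique(fam),
    activity = CT_PASSAGE_ACTIVITIES
  )
  out$passages <- cumsum(out$activity == "Passage")
  ct_as_report(out, paste0("passage_table:", clone), nrow(tracker$records))
}

#' Read clone analysis results from CSV
#'
#' Expects the columns of the clones-summary join: `clone`, `date_sent`,
#' `passage_at_analysis`, `fp_copy_number`, `cnv_flag`, `insertion_site_pcr`,
#' `extra_insertion_flag`, `phenotype_note`, `mycoplasma`, `str_markers`,
#' `data_url`.
#'
#' @param path CSV file path.
#' @return A typed tibble of analysis results.
#' @export
read_analysis_results <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE
  )
  if (!all(CT_ANALYSIS_COLUMNS %in% names(df))) {
    ct_abort(
      paste("analysis results need columns:", paste(CT_ANALYSIS_COLUMNS, collapse = ", ")),
      "clonetrack_parse_error"
    )
  }
  df$date_sent <- as.Date(df$date_sent)
  df$passage_at_analysis <- as.integer(df$passage_at_analysis)
  df$fp_copy_number <- as.numeric(df$fp_copy_number)
  df$cnv_flag <- as.logical(df$cnv_flag)
  df$extra_insertion_flag <- as.logical(df$extra_insertion_flag)
  df[CT_ANALYSIS_COLUMNS]
}

#' Clones summary
#'
#' One row per designated clone, collating registry state with derived counts
#' and (optionally) genomic analysis results: lineage status (discontinued if
#' the clone or any population derived from it was discontinued), number of
#' sorts (highest sort index reached), final passage count, the joined
#' analysis-result fields, and the workspace-relative data location.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param results Optional analysis-results tibble (see
#'   [read_analysis_results()]); every `clone` in it must name a registered
#'   clone-level sample.
#' @return A `clonetrack_report` tibble with one row per clone, in
#'   designation order.
#' @export
clones_summary <- function(tracker, results = NULL) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  reg <- tracker$registry
  clones <- reg$name[!is.na(reg$well) & is.na(reg$sort_index)]
  if (!is.null(results)) {
    bad <- setdiff(results$clone, clones)
    if (length(bad) > 0L) {
      ct_abort(
        sprintf("analysis results name unregistered clones: %s",
          paste(bad, collapse = ", ")),
        "clonetrack_join_error"
      )
    }
  }
  n <- length(clones)
  out <- tibble::tibble(
    clone = clones,
    alias = unname(vapply(clones, function(x) short_alias(parse_name(x, tracker$vocab)), "")),
    transfection = unname(vapply(clones, function(x) ancestors(tracker, x)[[1]], "")),
    status = character(n),
    n_sorts = integer(n),
    n_passages = integer(n),
    date_sent = as.Date(rep(NA, n)),
    passage_at_analysis = rep(NA_integer_, n),
    fp_copy_number = rep(NA_real_, n),
    cnv_flag = rep(NA, n),
    insertion_site_pcr = rep(NA_character_, n),
    extra_insertion_flag = rep(NA, n),
    phenotype_note = rep(NA_character_, n),
    mycoplasma = rep(NA_character_, n),
    str_markers = rep(NA_character_, n),
    data_url = unname(vapply(clones, function(x) ct_rel_path(tracker, x), ""))
  )
  for (i in seq_len(n)) {
    fam <- c(clones[[i]], descendants(tracker, clones[[i]]))
    out$status[[i]] <- if (any(reg$status[reg$name %in% fam] == "discontinued")) {
      "discontinued"
    } else {
      "active"
    }
    idx <- reg$sort_index[reg$name %in% fam]
    out$n_sorts[[i]] <- if (all(is.na(idx))) 0L else max(idx, na.rm = TRUE)
    pt <- passage_table(tracker, clones[[i]])
    out$n_passages[[i]] <- if (nrow(pt) == 0L) 0L else pt$passages[[nrow(pt)]]
  }
  if (!is.null(results)) {
    m <- match(out$clone, results$clone)
    hit <- !is.na(m)
    for (col in setdiff(CT_ANALYSIS_COLUMNS, c("clone", "data_url"))) {
      out[[col]][hit] <- results[[col]][m[hit]]
    }
    if ("data_url" %in% names(results)) {
      url <- results$data_url[m[hit]]
      out$data_url[hit] <- ifelse(is.na(url), out$data_url[hit], url)
    }
  }
  ct_as_report(out, "clones_summary", nrow(tracker$records))
}
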