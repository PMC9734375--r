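# The sample-naming grammar. A base designator concatenates the transfection
# date (YYYYMMDD) with the fluorescent-protein, target-gene and guide-RNA
# tokens, without delimiters: 20200113mChOCT4sg2. Derivation appends
# underscore-delimited suffixes: "_C6" when a clone is designated by its
# 96-well position, "_Sort3" after the third flow sort. Because the base is
# delimiter-free, parsing is vocabulary-driven: longest fluorescent-protein
# match from the left, longest guide match from the right, residue = gene.

# rows x columns for the standard plate formats
CT_PLATE_DIMS <- list(
  `6` = c(2L, 3L), `12` = c(3L, 4L), `24` = c(4L, 6L),
  `48` = c(6L, 8L), `96` = c(8L, 12L)
)

CT_TOKEN_RE <- "^[A-Za-z0-9+]+$"

#' Well address on a multi-well plate
#'
#' @param row Row letter (e.g. `"C"`).
#' @param column Column number.
#' @param plate_format Wells per plate: 6, 12, 24, 48 or 96 (default).
#' @return A `clonetrack_well` object.
#' @examples
#' well_address("C", 6)
#' parse_well("C6")
#' @export
well_address <- function(row, column, plate_format = 96) {
  plate_format <- as.integer(plate_format)
  dims <- CT_PLATE_DIMS[[as.character(plate_format)]]
  if (is.null(dims)) {
    ct_abort(
      sprintf("unsupported plate format %d", plate_format),
      "clonetrack_well_error"
    )
  }
  column <- as.integer(column)
  if (!is.character(row) || nchar(row) != 1L || !row %in% LETTERS[seq_len(dims[1])]) {
    ct_abort(
      sprintf(
        "row '%s' outside A..%s for %d-well format",
        as.character(row), LETTERS[dims[1]], plate_format
      ),
      "clonetrack_well_error"
    )
  }
  if (is.na(column) || column < 1L || column > dims[2]) {
    ct_abort(
      sprintf("column %s outside 1..%d for %d-well format", column, dims[2], plate_format),
      "clonetrack_well_error"
    )
  }
  structure(
    list(row = row, column = column, plate_format = plate_format),
    class = "clonetrack_well"
  )
}

#' @rdname well_address
#' @param label Well label such as `"C6"`.
#' @export
parse_well <- function(label, plate_format = 96) {
  if (!is.character(label) || length(label) != 1L ||
    !grepl("^[A-Z][0-9]{1,2}$", label)) {
    ct_abort(
      sprintf("malformed well label '%s'", as.character(label)),
      "clonetrack_well_error"
    )
  }
  well_address(
    substr(label, 1L, 1L),
    as.integer(substring(label, 2L)),
    plate_format
  )
}

#' @rdname well_address
#' @param well A `clonetrack_well`.
#' @export
well_label <- function(well) {
  stopifnot(inherits(well, "clonetrack_well"))
  paste0(well$row, well$column)
}

ct_check_token <- function(token, what) {
  if (!is.character(token) || length(token) != 1L || is.na(token) ||
    !grepl(CT_TOKEN_RE, token)) {
    ct_abort(
      sprintf(
        "%s token '%s' must be non-empty and contain only [A-Za-z0-9+]",
        what, as.character(token)
      ),
      "clonetrack_name_error"
    )
  }
  invisible(token)
}

#' Construct a sample name
#'
#' The parsed form of a designator: transfection date plus fluorescent-protein
#' (`fp`), gene and guide-RNA tokens, with optional well (clone level) and
#' sort-index (enrichment level) suffixes. A sort index requires a well: only
#' clone-derived populations are sorted.
#'
#' @param date Transfection date (`Date` or parseable string).
#' @param fp Fluorescent-protein token, e.g. `"mCh"`.
#' @param gene Target-gene token, e.g. `"OCT4"`.
#' @param guide Guide-RNA token, e.g. `"sg2"`.
#' @param well Optional `clonetrack_well` or well label.
#' @param sort_index Optional positive integer, the number of sorts performed.
#' @return A `clonetrack_sample_name` object.
#' @examples
#' format_name(sample_name("2020-01-13", "mCh", "OCT4", "sg2"))
#' @export
sample_name <- function(date, fp, gene, guide, well = NULL, sort_index = NULL) {
  date <- as.Date(date)
  if (is.na(date)) ct_abort("invalid date", "clonetrack_date_error")
  ct_check_token(fp, "fluorescent-protein")
  ct_check_token(gene, "gene")
  ct_check_token(guide, "guide-RNA")
  if (!is.null(well) && is.character(well)) well <- parse_well(well)
  if (!is.null(well)) stopifnot(inherits(well, "clonetrack_well"))
  if (!is.null(sort_index)) {
    sort_index <- as.integer(sort_index)
    if (is.na(sort_index) || sort_index < 1L) {
      ct_abort("sort_index must be a positive integer", "clonetrack_name_error")
    }
    if (is.null(well)) {
      ct_abort("a sort index requires a well (only clones are sorted)",
        "clonetrack_name_error")
    }
  }
  structure(
    list(
      date = date, fp = fp, gene = gene, guide = guide,
      well = well, sort_index = sort_index
    ),
    class = "clonetrack_sample_name"
  )
}

#' Format a sample name as its designator text
#'
#' @param name A `clonetrack_sample_name`.
#' @return The designator string, e.g. `"20200113mChOCT4sg2_C6_Sort4"`.
#' @export
format_name <- function(name) {
  stopifnot(inherits(name, "clonetrack_sample_name"))
  out <- paste0(format(name$date, "%Y%m%d"), name$fp, name$gene, name$guide)
  if (!is.null(name$well)) out <- paste0(out, "_", well_label(name$well))
  if (!is.null(name$sort_index)) out <- paste0(out, "_Sort", name$sort_index)
  out
}

#' Parse a designator back into a sample name
#'
#' The base (before any `_`) is decomposed as an 8-digit date, then the longest
#' case-insensitive prefix match against the vocabulary's fluorescent-protein
#' tokens, then the longest case-sensitive suffix match against its guide-RNA
#' tokens; the residue between them is the gene. The as-entered casing of the
#' fluorescent-protein token is preserved, so formatting a parsed name
#' reproduces the input text exactly. If no guide token matches, a trailing
#' letters-then-digits run (e.g. `sg2`) is accepted with a warning. Suffixes
#' are a well label and/or `Sort<k>`, in that order.
#'
#' @param text Designator string.
#' @param vocab A `clonetrack_vocabulary` supplying fp and guide token lists.
#' @param plate_format Plate format used to bound the well suffix (default 96).
#' @return A `clonetrack_sample_name`.
#' @examples
#' parse_name("20200220mChOCT4sg2_C10", default_vocabulary())
#' @export
parse_name <- function(text, vocab, plate_format = 96) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "_", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(parts))) {
    ct_abort(sprintf("malformed name '%s'", text), "clonetrack_name_error")
  }
  base <- parts[[1]]
  if (nchar(base) < 9L || !grepl("^[0-9]{8}", base)) {
    ct_abort(
      sprintf("name '%s' does not start with an 8-digit date", text),
      "clonetrack_date_error"
    )
  }
  date_txt <- substr(base, 1L, 8L)
  date <- as.Date(date_txt, format = "%Y%m%d")
  if (is.na(date) || !identical(format(date, "%Y%m%d"), date_txt)) {
    ct_abort(sprintf("invalid date digits '%s'", date_txt), "clonetrack_date_error")
  }
  rest <- substring(base, 9L)

  fp_terms <- vocab$fields$fluorescent_protein
  fp_terms <- fp_terms[order(-nchar(fp_terms))]
  fp <- NULL
  for (t in fp_terms) {
    if (nchar(rest) > nchar(t) &&
      identical(tolower(substr(rest, 1L, nchar(t))), tolower(t))) {
      fp <- substr(rest, 1L, nchar(t)) # keep as-entered casing
      break
    }
  }
  if (is.null(fp)) {
    ct_abort(
      sprintf("no fluorescent-protein token of the vocabulary starts '%s'", rest),
      "clonetrack_unparseable_name_error"
    )
  }
  mid <- substring(rest, nchar(fp) + 1L)

  guide_terms <- vocab$fields$guide_rna
  guide_terms <- guide_terms[order(-nchar(guide_terms))]
  guide <- NULL
  for (t in guide_terms) {
    if (nchar(mid) > nchar(t) && identical(substring(mid, nchar(mid) - nchar(t) + 1L), t)) {
      guide <- t
      break
    }
  }
  if (is.null(guide)) {
    m <- regexpr("[A-Za-z]+[0-9]+$", mid)
    if (m > 1L) {
      guide <- regmatches(mid, m)
      ct_warn(
        sprintf("guide token '%s' not in vocabulary; accepted by pattern", guide),
        "clonetrack_guide_warning"
      )
    } else {
      ct_abort(
        sprintf("no guide-RNA token of the vocabulary ends '%s'", mid),
        "clonetrack_unparseable_name_error"
      )
    }
  }
  gene <- substr(mid, 1L, nchar(mid) - nchar(guide))
  if (!nzchar(gene)) {
    ct_abort(
      sprintf("empty gene token in '%s'", base),
      "clonetrack_unparseable_name_error"
    )
  }

  well <- NULL
  sort_index <- NULL
  i <- 2L
  if (i <= length(parts) && grepl("^[A-Z][0-9]{1,2}$", parts[[i]])) {
    well <- parse_well(parts[[i]], plate_format)
    i <- i + 1L
  }
  if (i <= length(parts) && grepl("^Sort", parts[[i]])) {
    if (!grepl("^Sort[1-9][0-9]*$", parts[[i]])) {
      ct_abort(
        sprintf("malformed sort suffix '%s'", parts[[i]]),
        "clonetrack_suffix_error"
      )
    }
    if (is.null(well)) {
      ct_abort(
        "sort suffix without a well suffix is not a valid name",
        "clonetrack_suffix_error"
      )
    }
    sort_index <- as.integer(substring(parts[[i]], 5L))
    i <- i + 1L
  }
  if (i <= length(parts)) {
    ct_abort(
      sprintf("unrecognized suffix '%s' in '%s'", parts[[i]], text),
      "clonetrack_suffix_error"
    )
  }
  sample_name(date, fp, gene, guide, well = well, sort_index = sort_index)
}

#' Derive the name of a newly designated clone
#'
#' Appends the well where an edited colony was observed to a base transfection
#' designator.
#'
#' @param base Base-level `clonetrack_sample_name` (no well, no sort).
#' @param well A `clonetrack_well` or well label.
#' @return Clone-level sample name.
#' @export
derive_clone_name <- function(base, well) {
  stopifnot(inherits(base, "clonetrack_sample_name"))
  if (!is.null(base$well) || !is.null(base$sort_index)) {
    ct_abort("clone derivation requires a base-level designator",
      "clonetrack_derivation_error")
  }
  if (is.character(well)) well <- parse_well(well)
  sample_name(base$date, base$fp, base$gene, base$guide, well = well)
}

#' Derive the name produced by a flow sort
#'
#' The first sort of a clone yields `_Sort1`; each further sort increments the
#' index by one.
#'
#' @param current Clone-level `clonetrack_sample_name`.
#' @return Sample name with sort index incremented (or set to 1).
#' @export
derive_sort_name <- function(current) {
  stopifnot(inherits(current, "clonetrack_sample_name"))
  if (is.null(current$well)) {
    ct_abort("only clone-level samples are sorted", "clonetrack_derivation_error")
  }
  k <- if (is.null(current$sort_index)) 1L else current$sort_index + 1L
  sample_name(current$date, current$fp, current$gene, current$guide,
    well = current$well, sort_index = k
  )
}

#' Short alias of a clone: 6-digit date plus well
#'
#' The compact label used to title per-clone passage reports, e.g.
#' `"200113_C6"`.
#'
#' @param name Clone-level `clonetrack_sample_name`.
#' @return Alias string.
#' @export
short_alias <- function(name) {
  stopifnot(inherits(name, "clonetrack_sample_name"))
  if (is.null(name$well)) {
    ct_abort("short alias requires a clone-level name (well set)",
      "clonetrack_alias_error")
  }
  paste0(format(name$date, "%y%m%d"), "_", well_label(name$well))
}

#' @export
print.clonetrack_sample_name <- function(x, ...) {
  cat("<sample>", format_name(x), "\n")
  invisible(x)
}

#' @export
print.clonetrack_well <- function(x, ...) {
  cat(sprintf("<well> %s (%d-well plate)\n", well_label(x), x$plate_format))
  invisible(x)
}
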