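# Lossless serialization of report tables and the ledger to open formats.
# Tables are first canonicalized to text cells: Dates render as ISO-8601,
# numbers via as.character, logicals as TRUE/FALSE, and the empty string is
# identified with NA (the spreadsheet's empty cell). On canonical tables the
# round trip import(export(t)) is the identity in all three formats, and the
# byte output for a fixed table is deterministic (stable field order, no
# timestamps).
#
# Format shapes:
#   CSV  — RFC 4180 with header row, UTF-8, empty cell for NA (via readr);
#   XML  — <records columns="a,b"><record><field name="a">v</field>...</record>
#          </records>; an NA cell is an absent element, and the columns
#          attribute preserves schema and order even for all-NA columns;
#   JSON — array of flat objects keyed by column name, NA as null (jsonlite).

ct_canonical_table <- function(table) {
  if (anyDuplicated(names(table)) > 0L || any(!nzchar(names(table)))) {
    ct_abort("column names must be unique and non-empty", "clonetrack_schema_error")
  }
  df <- tibble::as_tibble(table, .name_repair = "minimal")
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (inherits(col, "Date")) {
      col <- format(col, "%Y-%m-%d")
    } else if (!is.character(col)) {
      col <- as.character(col)
    }
    col[!is.na(col) & !nzchar(col)] <- NA_character_
    df[[j]] <- col
  }
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}

#' Export a table to CSV, XML or JSON
#'
#' @param table A data frame / report table.
#' @param format `"csv"`, `"xml"` or `"json"`.
#' @param path Optional file to write (UTF-8).
#' @return The serialized document as a single string (invisibly when `path`
#'   is given).
#' @examples
#' t <- tibble::tibble(a = c("x", NA), b = c("1", "2"))
#' cat(export_table(t, "csv"))
#' @export
export_table <- function(table, format = c("csv", "xml", "json"), path = NULL) {
  format <- match.arg(format)
  df <- ct_canonical_table(table)
  doc <- switch(format,
    csv = readr::format_csv(df, na = ""),
    json = as.character(
      jsonlite::toJSON(df, dataframe = "rows", na = "null", auto_unbox = FALSE)
    ),
    xml = ct_to_xml(df)
  )
  if (!is.null(path)) {
    writeLines(doc, path, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

ct_to_xml <- function(df) {
  root <- xml2::xml_new_root("records")
  xml2::xml_set_attr(root, "columns", paste(names(df), collapse = ","))
  for (i in seq_len(nrow(df))) {
    rec <- xml2::xml_add_child(root, "record")
    for (col in names(df)) {
      v <- df[[col]][[i]]
      if (!is.na(v)) {
        f <- xml2::xml_add_child(rec, "field", v)
        xml2::xml_set_attr(f, "name", col)
      }
    }
  }
  as.character(root)
}

#' Import a table exported by [export_table()]
#'
#' Reconstructs the canonical table: identical columns, row order and cell
#' values. The input may be a file path or the document text itself.
#'
#' @param input Path to, or text of, the serialized document.
#' @param format `"csv"`, `"xml"` or `"json"`.
#' @return A tibble with all-character columns; empty cells are `NA`.
#' @export
import_table <- function(input, format = c("csv", "xml", "json")) {
  format <- match.arg(format)
  is_path <- length(input) == 1L && !grepl("\n", input) && file.exists(input)
  text <- if (is_path) {
    readChar(input, file.info(input)$size, useBytes = TRUE)
  } else {
    paste(input, collapse = "\n")
  }
  Encoding(text) <- "UTF-8"
  switch(format,
    csv = ct_from_csv(text),
    json = ct_from_json(text),
    xml = ct_from_xml(text)
  )
}

ct_from_csv <- function(text) {
  df <- readr::read_csv(I(text),
    col_types = readr::cols(.default = readr::col_character()),
    na = "", trim_ws = FALSE, skip_empty_rows = FALSE, progress = FALSE
  )
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}

ct_from_json <- function(text) {
  lst <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(lst) || (length(lst) > 0L && !is.null(names(lst)))) {
    ct_abort("JSON document is not an array of records", "clonetrack_parse_error")
  }
  if (length(lst) == 0L) return(tibble::tibble())
  cols <- names(lst[[1]])
  out <- lapply(cols, function(col) {
    vapply(seq_along(lst), function(i) {
      v <- lst[[i]][[col]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, "")
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

ct_from_xml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    ct_abort(paste("malformed XML:", conditionMessage(e)), "clonetrack_parse_error")
  })
  cols <- strsplit(xml2::xml_attr(doc, "columns"), ",", fixed = TRUE)[[1]]
  recs <- xml2::xml_find_all(doc, "./record")
  out <- lapply(cols, function(col) rep(NA_character_, length(recs)))
  names(out) <- cols
  for (i in seq_along(recs)) {
    fields <- xml2::xml_find_all(recs[[i]], "./field")
    for (f in fields) {
      nm <- xml2::xml_attr(f, "name")
      if (!nm %in% cols) {
        ct_abort(
          sprintf("record %d has field '%s' outside the declared columns", i, nm),
          "clonetrack_parse_error"
        )
      }
      out[[nm]][[i]] <- xml2::xml_text(f)
    }
  }
  tibble::as_tibble(out)
}
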