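# Shared fixtures built in code.

# A one-transfection, one-clone tracker for ledger/report tests.
mini_tracker <- function(fp = "mCh", gene = "OCT4", guide = "sg2",
                         date = as.Date("2021-01-01"), well = "A1") {
  tr <- clonetrack()
  tr <- new_transfection(
    tr, transfection_metadata(sample_name(date, fp, gene, guide)), date
  )
  designator <- format_name(sample_name(date, fp, gene, guide))
  tr <- designate_clone(tr, designator, well, date + 3)
  list(tracker = tr, designator = designator,
    clone = paste0(designator, "_", well))
}

# Random sample name constructible from the given vocabulary.
random_sample_name <- function(vocab, with_suffix = TRUE) {
  fp <- sample(vocab$fields$fluorescent_protein, 1L)
  guide <- sample(vocab$fields$guide_rna, 1L)
  gene <- paste(sample(LETTERS, sample(2:6, 1L), replace = TRUE), collapse = "")
  date <- as.Date("2015-01-01") + sample.int(4000L, 1L)
  well <- NULL
  sort_index <- NULL
  if (with_suffix && stats::runif(1) < 0.6) {
    well <- well_address(sample(LETTERS[1:8], 1L), sample.int(12L, 1L))
    if (stats::runif(1) < 0.5) sort_index <- sample.int(9L, 1L)
  }
  sample_name(date, fp, gene, guide, well = well, sort_index = sort_index)
}

same_sample_name <- function(a, b) {
  identical(format_name(a), format_name(b)) &&
    identical(a$date, b$date) && identical(a$fp, b$fp) &&
    identical(a$gene, b$gene) && identical(a$guide, b$guide)
}

# Random canonical table (all character, NA for empty) with awkward content:
# unicode, embedded newlines, quotes, commas, empty cells.
random_canonical_table <- function(n_rows = 5L, n_cols = 3L) {
  pieces <- c(
    "plain", "with,comma", "with\"quote\"", "multi\nline", "ümläut",
    "細胞", "tab\there", "  padded  ", "x"
  )
  cols <- lapply(seq_len(n_cols), function(j) {
    v <- vapply(seq_len(n_rows), function(i) {
      paste(sample(pieces, sample(1:3, 1L), replace = TRUE), collapse = " ")
    }, "")
    v[stats::runif(n_rows) < 0.2] <- NA_character_
    v
  })
  names(cols) <- paste0("col_", letters[seq_len(n_cols)])
  tibble::as_tibble(cols)
}

# Drop report provenance/class for comparison against a manually built subset.
strip_report <- function(x) {
  attr(x, "provenance") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
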