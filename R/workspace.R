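# The workspace mirrors the registry as nested directories: each sample's
# folder path is its ancestor chain, so the directory itself is a human-
# readable local persistent identifier for everything recorded about the
# sample. The workspace is an archive: nothing here ever deletes or moves a
# directory, and foreign files inside existing folders are untouched.

ct_rel_path <- function(tracker, name) {
  paste(ancestors(tracker, name), collapse = "/")
}

#' Filesystem path of a sample's data folder
#'
#' @param root Workspace root directory.
#' @param tracker A `clonetrack_tracker`.
#' @param name Registered sample designator.
#' @return The nested path `root/<root designator>/.../<name>`.
#' @export
sample_path <- function(root, tracker, name) {
  do.call(file.path, c(list(root), as.list(ancestors(tracker, name))))
}

#' Create any missing sample directories
#'
#' Idempotent: a second call on an unchanged registry creates nothing.
#'
#' @param root Existing, writable workspace root.
#' @param tracker A `clonetrack_tracker`.
#' @return Character vector of the paths created (invisibly).
#' @export
ensure_tree <- function(root, tracker) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  if (!dir.exists(root)) {
    ct_abort(sprintf("workspace root '%s' does not exist", root), "clonetrack_io_error")
  }
  if (file.access(root, mode = 2L) != 0L) {
    ct_abort(sprintf("workspace root '%s' is not writable", root), "clonetrack_io_error")
  }
  created <- character()
  for (name in tracker$registry$name) {
    p <- sample_path(root, tracker, name)
    if (!dir.exists(p)) {
      ok <- dir.create(p, recursive = TRUE, showWarnings = FALSE)
      if (!ok || !dir.exists(p)) {
        ct_abort(sprintf("could not create '%s'", p), "clonetrack_io_error")
      }
      created <- c(created, p)
    }
  }
  invisible(created)
}

#' Audit the workspace against the registry
#'
#' @param root Workspace root directory.
#' @param tracker A `clonetrack_tracker`.
#' @return A list with `missing` (registered samples lacking a folder, as
#'   sample names) and `unregistered` (folders under `root` that correspond to
#'   no registered sample, as relative paths).
#' @export
audit_workspace <- function(root, tracker) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  expected <- vapply(tracker$registry$name, function(n) ct_rel_path(tracker, n), "")
  found <- list.dirs(root, recursive = TRUE, full.names = FALSE)
  found <- found[nzchar(found)]
  list(
    missing = tracker$registry$name[!expected %in% found],
    unregistered = sort(setdiff(found, unname(expected)))
  )
}
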