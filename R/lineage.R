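# Queries over the sample registry: the derivation forest whose roots are
# transfection designators, whose depth-1 children are designated clones, and
# whose deeper chains are successive sorted populations.

ct_require_registered <- function(tracker, name) {
  if (!name %in% tracker$registry$name) {
    ct_abort(sprintf("unknown sample '%s'", name), "clonetrack_lookup_error")
  }
  invisible(name)
}

#' Ancestor chain of a sample, root first
#'
#' @param tracker A `clonetrack_tracker`.
#' @param name Registered sample designator.
#' @return Character vector from the root transfection down to `name`
#'   inclusive; its length is the derivation depth plus one.
#' @export
ancestors <- function(tracker, name) {
  ct_require_registered(tracker, name)
  reg <- tracker$registry
  chain <- character()
  cur <- name
  while (!is.na(cur)) {
    chain <- c(cur, chain)
    cur <- reg$parent[reg$name == cur]
  }
  chain
}

#' Descendants of a sample (creation order, sample excluded)
#'
#' @inheritParams ancestors
#' @return Character vector of all samples derived from `name`.
#' @export
descendants <- function(tracker, name) {
  ct_require_registered(tracker, name)
  reg <- tracker$registry
  out <- character()
  frontier <- name
  while (length(frontier) > 0L) {
    kids <- reg$name[!is.na(reg$parent) & reg$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out[order(match(out, reg$name))]
}

#' List registered samples, most recent first
#'
#' The order of the cell-sample drop-down: the most recently created sample
#' appears at the top.
#'
#' @param tracker A `clonetrack_tracker`.
#' @return Character vector of designators in reverse creation order.
#' @export
list_samples <- function(tracker) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  rev(tracker$registry$name)
}

#' All samples of one transfection's lineage tree
#'
#' @param tracker A `clonetrack_tracker`.
#' @param designator Registered root transfection designator.
#' @return Character vector: the root and every sample derived from it, in
#'   creation order.
#' @export
transfection_members <- function(tracker, designator) {
  ct_require_registered(tracker, designator)
  reg <- tracker$registry
  if (!is.na(reg$parent[reg$name == designator])) {
    ct_abort(
      sprintf("'%s' is not a transfection root", designator),
      "clonetrack_lookup_error"
    )
  }
  c(designator, descendants(tracker, designator))
}

#' Status of a sample
#'
#' @inheritParams ancestors
#' @return `"active"` or `"discontinued"`.
#' @export
sample_status <- function(tracker, name) {
  ct_require_registered(tracker, name)
  tracker$registry$status[tracker$registry$name == name]
}
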