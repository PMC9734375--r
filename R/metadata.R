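# Transfection metadata: the per-transfection template payload (constructs,
# guide, cell counts, reagent plan, free text, attachments) plus the reagent
# volume calculator with its vessel-capacity warning.

#' Transfection metadata record
#'
#' The payload of one transfection's metadata sheet. The base sample name must
#' agree with the guide-RNA entry, and (when plasmid components are listed) at
#' least one component is expected to mention the fluorescent-protein token.
#'
#' @param name Base-level [sample_name()] (no well, no sort suffix).
#' @param plasmid_components Character vector of plasmid component terms.
#' @param guide_rna Guide-RNA term; defaults to, and must equal, the name's
#'   guide token.
#' @param electroporation_program Optional program identifier.
#' @param cell_count Optional number of cells transfected.
#' @param reagent_inputs Optional tibble/data.frame with columns `reagent`,
#'   `stock_conc` (e.g. ng/uL, must be > 0) and `target_amount` (same mass
#'   unit as the concentration numerator).
#' @param vessel_capacity Optional transfection-vessel volume (uL) used for the
#'   reagent-plan warning.
#' @param notes Free text.
#' @param attachments Character vector of file references (paths/URLs), never
#'   embedded content.
#' @return A `clonetrack_metadata` object.
#' @export
transfection_metadata <- function(name, plasmid_components = character(),
                                  guide_rna = name$guide,
                                  electroporation_program = NA_character_,
                                  cell_count = NA_real_,
                                  reagent_inputs = NULL,
                                  vessel_capacity = NA_real_,
                                  notes = "", attachments = character()) {
  stopifnot(inherits(name, "clonetrack_sample_name"))
  if (!is.null(name$well) || !is.null(name$sort_index)) {
    ct_abort("transfection metadata takes a base-level name", "clonetrack_name_error")
  }
  if (!identical(guide_rna, name$guide)) {
    ct_abort(
      sprintf("guide_rna '%s' disagrees with name token '%s'", guide_rna, name$guide),
      "clonetrack_validation_error"
    )
  }
  if (length(plasmid_components) > 0L &&
    !any(grepl(name$fp, plasmid_components, ignore.case = TRUE))) {
    ct_warn(
      sprintf("no plasmid component mentions fluorescent protein '%s'", name$fp),
      "clonetrack_metadata_warning"
    )
  }
  if (!is.null(reagent_inputs)) {
    reagent_inputs <- tibble::as_tibble(reagent_inputs)
    need <- c("reagent", "stock_conc", "target_amount")
    if (!all(need %in% names(reagent_inputs))) {
      ct_abort("reagent_inputs needs columns reagent, stock_conc, target_amount",
        "clonetrack_validation_error")
    }
    if (any(!is.finite(reagent_inputs$stock_conc)) ||
      any(reagent_inputs$stock_conc <= 0)) {
      ct_abort("stock concentrations must be > 0", "clonetrack_domain_error")
    }
  }
  structure(
    list(
      name = name, plasmid_components = plasmid_components,
      guide_rna = guide_rna,
      electroporation_program = electroporation_program,
      cell_count = cell_count, reagent_inputs = reagent_inputs,
      vessel_capacity = vessel_capacity, notes = notes,
      attachments = attachments
    ),
    class = "clonetrack_metadata"
  )
}

#' Reuse an existing transfection's metadata as a template
#'
#' Copies the metadata filed under `source`, moves its name to `new_date`, and
#' clears run-specific free text and attachments; reagents, constructs and
#' program settings carry over so only new information needs entering.
#'
#' @param tracker A `clonetrack_tracker`.
#' @param source Registered transfection designator to copy.
#' @param new_date Date of the new transfection.
#' @return A fresh `clonetrack_metadata`, independent of the source.
#' @export
clone_transfection_template <- function(tracker, source, new_date) {
  stopifnot(inherits(tracker, "clonetrack_tracker"))
  meta <- tracker$metadata[[source]]
  if (is.null(meta)) {
    ct_abort(
      sprintf("no metadata filed under '%s'", source),
      "clonetrack_lookup_error"
    )
  }
  nm <- meta$name
  meta$name <- sample_name(as.Date(new_date), nm$fp, nm$gene, nm$guide)
  meta$notes <- ""
  meta$attachments <- character()
  meta
}

#' Reagent plan: volumes from target amounts and stock concentrations
#'
#' For each reagent, volume = target amount / stock concentration; the total is
#' checked against the vessel capacity and a warning message is attached to
#' the plan when it does not fit.
#'
#' @param meta A `clonetrack_metadata`.
#' @return A `clonetrack_reagent_plan`: `volumes` tibble (reagent, volume),
#'   `total` volume, and a character vector of `warnings`.
#' @examples
#' m <- transfection_metadata(
#'   sample_name("2020-01-13", "mCh", "OCT4", "sg2"),
#'   reagent_inputs = data.frame(
#'     reagent = "donor", stock_conc = 100, target_amount = 500
#'   )
#' )
#' reagent_volumes(m)$volumes$volume # 5 uL
#' @export
reagent_volumes <- function(meta) {
  stopifnot(inherits(meta, "clonetrack_metadata"))
  inp <- meta$reagent_inputs
  if (is.null(inp) || nrow(inp) == 0L) {
    return(structure(
      list(
        volumes = tibble::tibble(reagent = character(), volume = numeric()),
        total = 0, warnings = character()
      ),
      class = "clonetrack_reagent_plan"
    ))
  }
  if (any(!is.finite(inp$stock_conc)) || any(inp$stock_conc <= 0)) {
    ct_abort("stock concentrations must be > 0", "clonetrack_domain_error")
  }
  volumes <- tibble::tibble(
    reagent = inp$reagent,
    volume = inp$target_amount / inp$stock_conc
  )
  total <- sum(volumes$volume)
  warnings <- character()
  if (is.finite(meta$vessel_capacity) && total > meta$vessel_capacity) {
    warnings <- sprintf(
      "total volume %.3g exceeds vessel capacity %.3g",
      total, meta$vessel_capacity
    )
  }
  structure(
    list(volumes = volumes, total = total, warnings = warnings),
    class = "clonetrack_reagent_plan"
  )
}

#' @export
print.clonetrack_reagent_plan <- function(x, ...) {
  cat("<reagent plan> total volume:", format(x$total), "\n")
  print(x$volumes)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
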