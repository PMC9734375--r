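# Deterministic fixture generators. study_replica() rebuilds, event by event,
# a dataset with the shape of the reference three-transfection knock-in campaign:
# three roots (20200113mChOCT4sg2, 20200120mCHOCT4sg2, 20200220mChOCT4sg2 —
# printed casing preserved), fifteen designated clones in a 5/5/5 split, ten
# discontinued, five carried through iterative sorting and expansion, two
# survivors flagged with extra inserted sequence and three with a copy-number
# variant. The per-clone daily scripts, the discontinued wells and which
# survivors carry which flag are not printed anywhere; the constants below are
# arbitrary-but-fixed choices (see the methods vignette). The printed alias
# "2020220_A7" carries a 7-digit date typo; the fixture uses 200220_A7.

CT_REPLICA_PLAN <- list(
  list(
    date = "2020-01-13", fp = "mCh",
    survivors = "C6", discontinued = c("A2", "B3", "D4", "E5")
  ),
  list(
    date = "2020-01-20", fp = "mCH",
    survivors = "B9", discontinued = c("A1", "C2", "D3", "F6")
  ),
  list(
    date = "2020-02-20", fp = "mCh",
    survivors = c("A7", "C6", "C10"), discontinued = c("B2", "G8")
  )
)

# the clone that needed more sorting and passaging to reach a pure profile
CT_REPLICA_DEEP_CLONE <- "20200220mChOCT4sg2_C10"
CT_REPLICA_EXTRA_INSERTION <- c("20200113mChOCT4sg2_C6", "20200220mChOCT4sg2_C6")
CT_REPLICA_CNV <- c(CT_REPLICA_EXTRA_INSERTION, "20200120mCHOCT4sg2_B9")

#' Study-replica fixture
#'
#' Deterministically replays an event log reproducing the shape of the
#' three-transfection fluorescent knock-in study: 3 transfection roots, 15
#' designated clones, 10 discontinuations, 5 clones enriched by iterated
#' sorting (at least two sorts each; one clone needs four), frozen banks,
#' thaws, DNA extractions and send-outs, plus an analysis-results table in
#' which exactly 2 surviving clones carry an extra-insertion flag and 3 a
#' copy-number-variant flag.
#'
#' @return A list with elements `tracker` (ledger + registry + metadata) and
#'   `results` (analysis-results tibble for the five surviving clones).
#' @examples
#' sr <- study_replica()
#' sum(is.na(sr$tracker$registry$parent)) # 3 transfection roots
#' @export
study_replica <- function() {
  tr <- clonetrack()
  send_date <- character(0)
  for (plan in CT_REPLICA_PLAN) {
    d0 <- as.Date(plan$date)
    base <- sample_name(d0, plan$fp, "OCT4", "sg2")
    designator <- format_name(base)
    meta <- transfection_metadata(
      base,
      plasmid_components = c(
        paste0("pHDR-", plan$fp, "-OCT4-donor"),
        "pCas9-sg2"
      ),
      electroporation_program = "CA-137",
      cell_count = 1e6,
      reagent_inputs = tibble::tibble(
        reagent = c("donor plasmid", "Cas9 plasmid"),
        stock_conc = c(100, 200), # ng/uL
        target_amount = c(2000, 1000) # ng
      ),
      vessel_capacity = 100 # uL
    )
    tr <- new_transfection(tr, meta, d0,
      wells_used = 96L, plate_size = 96L,
      note = "distributed into 96-well plates with carrier cells"
    )
    tr <- record_activity(tr, d0 + 1, designator, "Feed w Ri")
    tr <- record_activity(tr, d0 + 2, designator, "Feed w mTeSr+")
    tr <- record_activity(tr, d0 + 3, designator, "Image",
      note = "screen wells for single fluorescent clusters"
    )
    for (w in c(plan$survivors, plan$discontinued)) {
      tr <- designate_clone(tr, designator, w, d0 + 3,
        note = "single fluorescent cluster observed"
      )
    }
    for (w in plan$discontinued) {
      clone <- paste0(designator, "_", w)
      tr <- record_activity(tr, d0 + 5, clone, "Passage")
      tr <- record_activity(tr, d0 + 8, clone, "Passage")
      tr <- record_activity(tr, d0 + 10, clone, "Discontinue",
        note = "population lost fluorescence"
      )
    }
    for (w in plan$survivors) {
      clone <- paste0(designator, "_", w)
      deep <- identical(clone, CT_REPLICA_DEEP_CLONE)
      tr <- record_activity(tr, d0 + 5, clone, "Passage")
      tr <- sort_sample(tr, clone, d0 + 7)
      s1 <- paste0(clone, "_Sort1")
      tr <- record_activity(tr, d0 + 8, s1, "Feed w Ri")
      tr <- record_activity(tr, d0 + 10, s1, "Passage")
      tr <- sort_sample(tr, s1, d0 + 12)
      tip <- paste0(clone, "_Sort2")
      off <- 14
      if (deep) {
        tr <- record_activity(tr, d0 + 14, tip, "Passage")
        tr <- sort_sample(tr, tip, d0 + 16,
          note = "population still heterogeneous"
        )
        tip <- paste0(clone, "_Sort3")
        tr <- record_activity(tr, d0 + 18, tip, "Passage")
        tr <- sort_sample(tr, tip, d0 + 20)
        tip <- paste0(clone, "_Sort4")
        tr <- record_activity(tr, d0 + 22, tip, "Passage")
        off <- 24
      }
      tr <- record_activity(tr, d0 + off, tip, "Passage")
      tr <- record_activity(tr, d0 + off + 2, tip, "Freeze",
        wells_used = 4L, plate_size = 24L, note = "bank of purified population"
      )
      tr <- record_activity(tr, d0 + off + 6, tip, "Thaw")
      tr <- record_activity(tr, d0 + off + 8, tip, "Passage")
      tr <- record_activity(tr, d0 + off + 10, tip, "Extract DNA")
      tr <- record_activity(tr, d0 + off + 11, tip, "Send out for analysis",
        note = "genomic analysis: copy number, insertion-site PCR, STR, mycoplasma"
      )
      send_date[[clone]] <- as.character(d0 + off + 11)
    }
  }
  survivors <- names(send_date)
  results <- tibble::tibble(
    clone = survivors,
    date_sent = as.Date(unname(send_date)),
    passage_at_analysis = unname(vapply(survivors, function(cl) {
      pt <- passage_table(tr, cl)
      pt$passages[[nrow(pt)]]
    }, 0L)),
    fp_copy_number = ifelse(survivors %in% CT_REPLICA_EXTRA_INSERTION, 2, 1),
    cnv_flag = survivors %in% CT_REPLICA_CNV,
    insertion_site_pcr = ifelse(
      survivors %in% CT_REPLICA_EXTRA_INSERTION,
      "extra bases downstream of edit", "expected junction bands"
    ),
    extra_insertion_flag = survivors %in% CT_REPLICA_EXTRA_INSERTION,
    phenotype_note = ifelse(
      survivors == CT_REPLICA_DEEP_CLONE,
      "tendency to differentiate; required extended sorting",
      "normal stem-cell morphology"
    ),
    mycoplasma = "negative",
    str_markers = "parental match",
    data_url = unname(vapply(survivors, function(cl) ct_rel_path(tr, cl), ""))
  )
  list(tracker = tr, results = results)
}

#' Randomized history generator for property tests
#'
#' Produces a reproducible, vocabulary-valid tracker: transfections on
#' successive dates, clones designated in randomly drawn distinct wells, and a
#' random activity script per clone in which a drawn `Sort` always applies to
#' the current tip of the clone's sort chain. All generated names round-trip
#' through the grammar.
#'
#' @param seed Integer seed; the same seed reproduces the same ledger.
#' @param n_transfections Number of transfections.
#' @param clones_per_transfection Clones designated per transfection (at most
#'   96, the plate capacity).
#' @param events_per_clone Number of post-designation activity records drawn
#'   per clone.
#' @param discontinue_prob Probability that a clone's history ends in
#'   `Discontinue`.
#' @param start_date Date of the first transfection.
#' @return A `clonetrack_tracker`.
#' @export
random_history <- function(seed, n_transfections = 2,
                           clones_per_transfection = 3,
                           events_per_clone = 8,
                           discontinue_prob = 0.2,
                           start_date = as.Date("2021-03-01")) {
  if (clones_per_transfection > 96L || clones_per_transfection < 0L ||
    n_transfections < 1L) {
    ct_abort("infeasible generator parameters", "clonetrack_generation_error")
  }
  set.seed(seed)
  vocab <- default_vocabulary()
  for (fp in c("GFP", "YFP")) {
    vocab <- amend_vocabulary(vocab, "fluorescent_protein", "add", fp)
  }
  for (g in c("sg1", "sg3")) vocab <- amend_vocabulary(vocab, "guide_rna", "add", g)
  tr <- clonetrack(vocab)
  genes <- c("OCT4", "SOX2", "NANOG", "KLF4", "TP53")
  all_wells <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  acts <- c("Passage", "Feed w Ri", "Image", "Sort", "Freeze", "Thaw")
  w_act <- c(0.30, 0.20, 0.10, 0.15, 0.15, 0.10)
  for (t in seq_len(n_transfections)) {
    d0 <- start_date + (t - 1L) * 10L
    base <- sample_name(
      d0,
      sample(vocab$fields$fluorescent_protein, 1L),
      sample(genes, 1L),
      sample(vocab$fields$guide_rna, 1L)
    )
    meta <- transfection_metadata(base,
      plasmid_components = paste0("pHDR-", base$fp, "-", base$gene)
    )
    tr <- new_transfection(tr, meta, d0)
    designator <- format_name(base)
    wells <- sample(all_wells, clones_per_transfection)
    for (w in wells) {
      tr <- designate_clone(tr, designator, w, d0 + 3L)
      tip <- paste0(designator, "_", w)
      d <- d0 + 3L
      for (e in seq_len(events_per_clone)) {
        d <- d + sample(1:3, 1L)
        act <- sample(acts, 1L, prob = w_act)
        if (identical(act, "Sort")) {
          tr <- sort_sample(tr, tip, d)
          tip <- format_name(derive_sort_name(parse_name(tip, vocab)))
        } else {
          tr <- record_activity(tr, d, tip, act)
        }
      }
      if (stats::runif(1L) < discontinue_prob) {
        tr <- record_activity(tr, d + 1L, tip, "Discontinue")
      }
    }
  }
  tr
}
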