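test_that("new transfections register unique roots and Transfect records", {
  tr <- clonetrack()
  dates <- as.Date(c("2020-01-13", "2020-01-20", "2020-02-20"))
  fps <- c("mCh", "mCH", "mCh")
  for (i in 1:3) {
    meta <- transfection_metadata(sample_name(dates[i], fps[i], "OCT4", "sg2"))
    tr <- new_transfection(tr, meta, dates[i])
  }
  expect_true("20200113mChOCT4sg2" %in% tr$registry$name)
  expect_identical(sum(tr$records$activity == "Transfect"), 3L)
  expect_identical(sum(is.na(tr$registry$parent)), 3L)
  dup <- transfection_metadata(sample_name(dates[1], "mCh", "OCT4", "sg2"))
  expect_error(new_transfection(tr, dup), class = "clonetrack_uniqueness_error")
})

test_that("template reuse copies settings, moves the date, clears run text", {
  tr <- clonetrack()
  meta <- transfection_metadata(
    sample_name("2020-01-13", "mCh", "OCT4", "sg2"),
    plasmid_components = c("pHDR-mCh-OCT4", "pCas9-sg2"),
    electroporation_program = "CA-137",
    notes = "first run", attachments = "counts.png"
  )
  tr <- new_transfection(tr, meta)
  copy <- clone_transfection_template(tr, "20200113mChOCT4sg2", "2020-01-20")
  expect_identical(format_name(copy$name), "20200120mChOCT4sg2")
  expect_identical(copy$plasmid_components, meta$plasmid_components)
  expect_identical(copy$notes, "")
  expect_identical(copy$attachments, character())
  # the copy is independent of the stored source
  copy$plasmid_components <- "edited"
  expect_identical(
    tr$metadata[["20200113mChOCT4sg2"]]$plasmid_components,
    meta$plasmid_components
  )
  tr <- new_transfection(tr, copy)
  expect_identical(sum(is.na(tr$registry$parent)), 2L)
  expect_error(clone_transfection_template(tr, "nope", "2020-02-01"),
    class = "clonetrack_lookup_error")
})

test_that("record validation: activities against vocab, samples against registry", {
  mt <- mini_tracker()
  tr <- mt$tracker
  tr2 <- record_activity(tr, "2021-01-05", mt$designator, "Image")
  expect_identical(nrow(tr2$records), nrow(tr$records) + 1L)
  expect_error(
    record_activity(tr, "2021-01-05", mt$designator, "Vortex"),
    class = "clonetrack_validation_error"
  )
  expect_error(
    record_activity(tr, "2021-01-05", "20990101mChOCT4sg2", "Image"),
    class = "clonetrack_lookup_error"
  )
  # future-dated planning entries are allowed
  tr3 <- record_activity(tr, Sys.Date() + 30, mt$designator, "Passage")
  expect_identical(max(tr3$records$date), Sys.Date() + 30)
})

test_that("activity on a discontinued sample warns and stamps the note", {
  mt <- mini_tracker()
  tr <- record_activity(mt$tracker, "2021-01-10", mt$clone, "Discontinue")
  expect_warning(
    tr <- record_activity(tr, "2021-01-12", mt$clone, "Image", note = "late check"),
    class = "clonetrack_discontinued_warning"
  )
  last <- tr$records[nrow(tr$records), ]
  expect_match(last$note, "discontinued")
  expect_match(last$note, "late check")
})

test_that("reagent volumes divide amount by concentration and flag overflow", {
  base <- sample_name("2020-01-13", "mCh", "OCT4", "sg2")
  m <- transfection_metadata(base, reagent_inputs = tibble::tibble(
    reagent = "donor", stock_conc = 100, target_amount = 500
  ))
  plan <- reagent_volumes(m)
  expect_equal(plan$volumes$volume, 5)
  expect_equal(plan$total, 5)
  expect_length(plan$warnings, 0)
  m2 <- transfection_metadata(base,
    reagent_inputs = tibble::tibble(
      reagent = c("a", "b"), stock_conc = c(10, 10), target_amount = c(700, 500)
    ),
    vessel_capacity = 100
  )
  plan2 <- reagent_volumes(m2)
  expect_equal(plan2$total, 120)
  expect_length(plan2$warnings, 1)
  expect_match(plan2$warnings, "capacity")
  # empty reagent list: zero total, no warnings
  plan0 <- reagent_volumes(transfection_metadata(base))
  expect_equal(plan0$total, 0)
  expect_length(plan0$warnings, 0)
  expect_error(
    transfection_metadata(base, reagent_inputs = tibble::tibble(
      reagent = "x", stock_conc = 0, target_amount = 1
    )),
    class = "clonetrack_domain_error"
  )
})

test_that("filter_records matches a brute-force row scan, ledger unchanged", {
  tr <- random_history(11, n_transfections = 2, clones_per_transfection = 3)
  before <- tr$records
  got <- filter_records(tr, activity = "Freeze")
  manual <- before[before$activity == "Freeze", ]
  manual <- manual[order(manual$date, manual$seq), ]
  expect_identical(strip_report(got), manual)
  expect_identical(tr$records, before)
  expect_identical(nrow(filter_records(tr, predicate = function(r) rep(FALSE, nrow(r)))), 0L)
  # predicate composition equals manual subset
  p <- function(r) r$date >= as.Date("2021-03-05")
  expect_identical(
    strip_report(filter_records(tr, activity = "Passage", predicate = p)),
    {
      m <- before[before$activity == "Passage" & p(before), ]
      m[order(m$date, m$seq), ]
    }
  )
})

test_that("a saved store reloads to an identical tracker", {
  sr <- study_replica()
  dir <- withr::local_tempdir()
  save_tracker(sr$tracker, dir)
  tr2 <- load_tracker(dir)
  expect_identical(tr2$records, sr$tracker$records)
  expect_identical(tr2$registry, sr$tracker$registry)
  expect_identical(names(tr2$metadata), names(sr$tracker$metadata))
  expect_identical(
    tr2$metadata[[1]]$reagent_inputs,
    sr$tracker$metadata[[1]]$reagent_inputs
  )
})
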