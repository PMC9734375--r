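test_that("activity reports equal a brute-force scan and partition the ledger", {
  sr <- study_replica()
  tr <- sr$tracker
  tf <- activity_report(tr, "Transfect")
  expect_identical(nrow(tf), 3L) # one row per transfection
  for (act in c("Freeze", "Sort", "Discontinue")) {
    got <- activity_report(tr, act)
    manual <- tr$records[tr$records$activity == act, ]
    manual <- manual[order(manual$date, manual$seq), ]
    expect_identical(strip_report(got), manual)
  }
  # unused activity -> empty table with full schema
  none <- activity_report(tr, "Feed w mTeSR++Ri")
  expect_identical(nrow(none), 0L)
  expect_identical(names(none), names(tr$records))
  # row counts over all activities sum to ledger length
  counts <- vapply(tr$vocab$activities,
    function(a) nrow(activity_report(tr, a)), 0L)
  expect_identical(sum(counts), nrow(tr$records))
  expect_error(activity_report(tr, "Vortex"), class = "clonetrack_validation_error")
})

test_that("transfection reports cover exactly the lineage, Transfect row first", {
  sr <- study_replica()
  tr <- sr$tracker
  roots <- tr$registry$name[is.na(tr$registry$parent)]
  seen <- integer()
  for (r in roots) {
    rep <- transfection_report(tr, r)
    expect_identical(rep$activity[[1]], "Transfect")
    expect_identical(rep$sample[[1]], r)
    expect_true(all(rep$sample %in% transfection_members(tr, r)))
    expect_true(all(diff(order(rep$date, rep$seq)) == 1L))
    expect_length(intersect(seen, rep$seq), 0L) # disjoint roots, disjoint reports
    seen <- c(seen, rep$seq)
  }
  expect_identical(sort(seen), tr$records$seq) # and they cover everything
  # a just-created transfection reports exactly its Transfect row
  t0 <- clonetrack()
  t0 <- new_transfection(
    t0, transfection_metadata(sample_name("2022-05-01", "mCh", "OCT4", "sg2"))
  )
  expect_identical(nrow(transfection_report(t0, "20220501mChOCT4sg2")), 1L)
})

test_that("passage counts accumulate across freeze/thaw and read at milestones", {
  mt <- mini_tracker()
  tr <- mt$tracker
  acts <- c("Passage", "Passage", "Freeze", "Passage", "Thaw",
    "Passage", "Passage", "Send out for analysis")
  d <- as.Date("2021-01-05")
  for (i in seq_along(acts)) tr <- record_activity(tr, d + i, mt$clone, acts[[i]])
  pt <- passage_table(tr, mt$clone)
  expect_identical(pt$passages[pt$activity == "Freeze"], 2L)
  expect_identical(pt$passages[pt$activity == "Thaw"], 3L)
  expect_identical(pt$passages[pt$activity == "Send out for analysis"], 5L)
  # milestone-only histories count zero passages
  mt2 <- mini_tracker(well = "B2")
  tr2 <- record_activity(mt2$tracker, "2021-01-05", mt2$clone, "Freeze")
  expect_identical(passage_table(tr2, mt2$clone)$passages, 0L)
  # final count is monotone non-decreasing in ledger prefix length
  finals <- vapply(seq_len(nrow(tr$records)), function(k) {
    pre <- tr
    pre$records <- tr$records[1:k, ]
    pre$registry <- build_registry(pre$records, pre$vocab)
    if (!mt$clone %in% pre$registry$name) return(0L)
    p <- passage_table(pre, mt$clone)
    if (nrow(p) == 0L) 0L else p$passages[[nrow(p)]]
  }, 0L)
  expect_true(all(diff(finals) >= 0L))
})

test_that("clone-only lineage mode excludes pre-designation pool passages", {
  mt <- mini_tracker()
  tr <- record_activity(mt$tracker, "2021-01-02", mt$designator, "Passage")
  tr <- record_activity(tr, "2021-01-05", mt$clone, "Passage")
  full <- passage_table(tr, mt$clone)
  clone_only <- passage_table(tr, mt$clone, lineage = "clone")
  expect_identical(full$passages[[nrow(full)]], 2L)
  expect_identical(clone_only$passages[[nrow(clone_only)]], 1L)
})

test_that("clones summary collates status, sort depth, passages and results", {
  sr <- study_replica()
  cs <- clones_summary(sr$tracker, sr$results)
  expect_identical(nrow(cs), 15L)
  expect_identical(sum(cs$status == "active"), 5L)
  expect_identical(sum(cs$extra_insertion_flag, na.rm = TRUE), 2L)
  expect_identical(sum(cs$cnv_flag, na.rm = TRUE), 3L)
  expect_identical(sort(unique(cs$n_sorts[cs$status == "active"])), c(2L, 4L))
  expect_true(all(cs$n_sorts[cs$status == "discontinued"] == 0L))
  # analysis passage number matches the recomputed passage table
  active <- cs[cs$status == "active", ]
  expect_identical(active$passage_at_analysis, active$n_passages)
  # the data location is the nested workspace path
  expect_identical(
    cs$data_url[cs$clone == "20200113mChOCT4sg2_C6"],
    "20200113mChOCT4sg2/20200113mChOCT4sg2_C6"
  )
  bad <- sr$results
  bad$clone[1] <- "20991231mChOCT4sg2_A1"
  expect_error(clones_summary(sr$tracker, bad), class = "clonetrack_join_error")
})

test_that("refresh on an extended ledger extends, never reorders, prior rows", {
  sr <- study_replica()
  tr <- sr$tracker
  before <- activity_report(tr, "Passage")
  tr2 <- record_activity(
    tr, max(tr$records$date) + 5, "20200220mChOCT4sg2_C10_Sort4", "Passage"
  )
  after <- activity_report(tr2, "Passage")
  expect_identical(nrow(after), nrow(before) + 1L)
  expect_identical(
    strip_report(after[seq_len(nrow(before)), ]),
    strip_report(before)
  )
  # regeneration on an unchanged ledger is identical (pure function)
  expect_identical(activity_report(tr, "Passage"), before)
})
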