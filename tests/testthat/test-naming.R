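vocab <- default_vocabulary()

test_that("formatting composes date, tokens, well and sort suffixes", {
  base <- sample_name("2020-01-13", "mCh", "OCT4", "sg2")
  expect_identical(format_name(base), "20200113mChOCT4sg2")
  clone <- derive_clone_name(base, "C6")
  expect_identical(format_name(clone), "20200113mChOCT4sg2_C6")
  sorted <- sample_name("2020-01-13", "mCh", "OCT4", "sg2",
    well = "C6", sort_index = 4
  )
  expect_identical(format_name(sorted), "20200113mChOCT4sg2_C6_Sort4")
  # tokens with underscores or other path-unsafe characters are refused
  expect_error(sample_name("2020-01-13", "m_Ch", "OCT4", "sg2"),
    class = "clonetrack_name_error")
  expect_error(sample_name("2020-01-13", "mCh", "OCT/4", "sg2"),
    class = "clonetrack_name_error")
  # a sort index without a well is not constructible
  expect_error(sample_name("2020-01-13", "mCh", "OCT4", "sg2", sort_index = 1),
    class = "clonetrack_name_error")
})

test_that("vocabulary-driven parsing decomposes the delimiter-free base", {
  nm <- parse_name("20200220mChOCT4sg2", vocab)
  expect_identical(nm$date, as.Date("2020-02-20"))
  expect_identical(nm$fp, "mCh")
  expect_identical(nm$gene, "OCT4")
  expect_identical(nm$guide, "sg2")
  expect_null(nm$well)
  # fp matches case-insensitively, casing preserved as entered
  nm2 <- parse_name("20200120mCHOCT4sg2", vocab)
  expect_identical(nm2$fp, "mCH")
  expect_identical(format_name(nm2), "20200120mCHOCT4sg2")
  # suffixes
  nm3 <- parse_name("20200113mChOCT4sg2_C6_Sort4", vocab)
  expect_identical(well_label(nm3$well), "C6")
  expect_identical(nm3$sort_index, 4L)
})

test_that("parsing rejects vocabulary misses and malformed dates/suffixes", {
  expect_error(parse_name("20200113xyOCT4sg2", vocab),
    class = "clonetrack_unparseable_name_error")
  expect_error(parse_name("20201341mChOCT4sg2", vocab),
    class = "clonetrack_date_error")
  expect_error(parse_name("20200113mChOCT4sg2_C6_Sort0", vocab),
    class = "clonetrack_suffix_error")
  expect_error(parse_name("20200113mChOCT4sg2_Sort1", vocab),
    class = "clonetrack_suffix_error")
  expect_error(parse_name("20200113mChOCT4sg2_C6_X", vocab),
    class = "clonetrack_suffix_error")
  # unlisted guide accepted by letters+digits pattern, with a warning
  expect_warning(
    nm <- parse_name("20200113mChOCT4sg9", vocab),
    class = "clonetrack_guide_warning"
  )
  expect_identical(nm$guide, "sg9")
  expect_identical(nm$gene, "OCT4")
})

test_that("clone and sort derivation respect their levels and chain by one", {
  base <- parse_name("20200120mCHOCT4sg2", vocab)
  clone <- derive_clone_name(base, "B9")
  expect_identical(format_name(clone), "20200120mCHOCT4sg2_B9")
  expect_error(derive_clone_name(clone, "A1"), class = "clonetrack_derivation_error")
  expect_error(derive_sort_name(base), class = "clonetrack_derivation_error")
  expect_identical(derive_sort_name(clone)$sort_index, 1L)
  expect_identical(
    format_name(derive_sort_name(derive_sort_name(clone))),
    "20200120mCHOCT4sg2_B9_Sort2"
  )
  # k applications yield sort index k, strictly increasing in unit steps
  x <- clone
  for (k in 1:7) {
    x <- derive_sort_name(x)
    expect_identical(x$sort_index, k)
  }
})

test_that("short aliases are the 6-digit date plus well", {
  expect_identical(
    short_alias(parse_name("20200113mChOCT4sg2_C6", vocab)), "200113_C6"
  )
  expect_identical(
    short_alias(parse_name("20200220mChOCT4sg2_C10", vocab)), "200220_C10"
  )
  expect_error(short_alias(parse_name("20200113mChOCT4sg2", vocab)),
    class = "clonetrack_alias_error")
})

test_that("well parsing enforces plate bounds across formats", {
  w <- parse_well("C6")
  expect_identical(w$row, "C")
  expect_identical(w$column, 6L)
  expect_error(parse_well("I1"), class = "clonetrack_well_error")
  expect_error(parse_well("A13"), class = "clonetrack_well_error")
  expect_error(parse_well("c6"), class = "clonetrack_well_error")
  expect_error(parse_well("C6", 7), class = "clonetrack_well_error")
  # 24-well plate: rows A-D, columns 1-6
  expect_silent(parse_well("D6", 24))
  expect_error(parse_well("E1", 24), class = "clonetrack_well_error")
})

test_that("random names round-trip through format and parse", {
  v <- amend_vocabulary(vocab, "fluorescent_protein", "add", "GFP")
  v <- amend_vocabulary(v, "guide_rna", "add", "sg11")
  set.seed(7)
  for (i in 1:300) {
    x <- random_sample_name(v)
    txt <- format_name(x)
    expect_match(txt, "^[A-Za-z0-9_+]+$") # filesystem-safe alphabet
    y <- parse_name(txt, v)
    expect_true(same_sample_name(x, y))
  }
})
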