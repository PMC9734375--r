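# clonetrack

Contemporaneous sample tracking for the generation of genome-edited cell
lines.

Deriving a clonal knock-in cell line is a weeks-long sequence of dated manual
actions on a growing family of samples: transfect, plate into 96-well plates,
image for fluorescent colonies, designate clones, passage, iteratively
flow-sort to enrich the edited population, freeze, thaw, extract DNA, send
out for genomic analysis. clonetrack is an R toolkit for experimentalists and
lab data managers that captures this as an **append-only activity ledger**
restricted by controlled vocabularies, and recomputes everything else from
it:

- a **naming grammar** in which a sample name encodes its provenance —
  `20200113mChOCT4sg2` (date + fluorescent protein + gene + guide RNA),
  `_C6` for the clone designated in well C6, `_Sort3` after the third
  enrichment sort — with vocabulary-driven parsing and a proven
  `parse(format(x)) = x` round trip;
- a **lineage registry**: a derivation forest rebuilt deterministically by
  replaying the ledger (clones hang off transfections, sorted populations
  chain off clones);
- **directory scaffolding** that mirrors the lineage as nested folders, each
  folder a human-readable local persistent identifier for the sample's data;
- **reports**: per-activity and per-transfection tables, running passage
  counts (read the passage number at any freeze, thaw or send-out), and a
  per-clone summary joined with genomic analysis results;
- **lossless export** of any table to CSV (RFC 4180), XML and JSON, with
  exact round-trip import;
- deterministic **fixtures**: a study replica of a three-transfection
  campaign (15 clones, 5 carried through enrichment) and a seeded random
  history generator for property tests.

## Worked example

```r
library(clonetrack)

tr <- clonetrack() # default vocabulary: 12 calendar activities
meta <- transfection_metadata(
  sample_name("2020-01-13", "mCh", "OCT4", "sg2"),
  plasmid_components = c("pHDR-mCh-OCT4-donor", "pCas9-sg2"),
  reagent_inputs = data.frame(
    reagent = "donor", stock_conc = 100, target_amount = 500
  )
)
reagent_volumes(meta)$volumes$volume
#> [1] 5                                  # 500 ng at 100 ng/uL -> 5 uL

tr <- new_transfection(tr, meta)
tr <- designate_clone(tr, "20200113mChOCT4sg2", "C6", "2020-01-16")
tr <- sort_sample(tr, "20200113mChOCT4sg2_C6", "2020-01-20")
tr <- record_activity(tr, "2020-01-22", "20200113mChOCT4sg2_C6_Sort1",
  "Passage", note = "split 1:6")

list_samples(tr) # most recent first
#> [1] "20200113mChOCT4sg2_C6_Sort1" "20200113mChOCT4sg2_C6"
#> [3] "20200113mChOCT4sg2"

passage_table(tr, "20200113mChOCT4sg2_C6")[, c("sample", "activity", "passages")]
#> # A tibble: 1 × 3
#>   sample                      activity passages
#>   <chr>                       <chr>       <int>
#> 1 20200113mChOCT4sg2_C6_Sort1 Passage         1
```

The running `passages` count is read at milestone rows: after a history
`Passage, Passage, Freeze, Passage, Thaw, Passage, Passage, Send out for
analysis`, the counts at the Freeze, Thaw and Send rows are 2, 3 and 5 — the
passage number of the frozen bank and of the analyzed sample.

The study replica reproduces the shape of a real campaign:

```r
sr <- study_replica()
cs <- clones_summary(sr$tracker, sr$results)
nrow(cs); sum(cs$status == "active")
#> [1] 15
#> [1] 5
```

15 clones designated across 3 transfections, 5 still active after
enrichment, 2 flagged with extra inserted sequence and 3 with a copy-number
variant in the joined analysis results.

## Command line

A thin CLI over the same functions is installed at `exec/clonetrack` and
operates on a plain-text store directory (`ledger.csv`, `vocab.csv`,
`metadata.json`):

```sh
clonetrack --store s init
clonetrack --store s transfect --date 2020-01-13 --fp mCh --gene OCT4 --guide sg2
clonetrack --store s designate-clone 20200113mChOCT4sg2 C6 --date 2020-01-16
clonetrack --store s sort 20200113mChOCT4sg2_C6 --date 2020-01-20
clonetrack --store s report passages 20200113mChOCT4sg2_C6
clonetrack --store s workspace sync --root /data/lines
clonetrack --store s export --format json
```

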