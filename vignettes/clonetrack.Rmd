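---
title: "Tracking genome-edited cell lines with clonetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking genome-edited cell lines with clonetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deriving a clonal knock-in pluripotent stem-cell line takes weeks of small,
dated manual actions on an expanding family of samples: a transfection is
plated across a 96-well plate, wells with fluorescent colonies are designated
as clones, clones are expanded and iteratively flow-sorted to enrich the
edited population, intermediate populations are frozen and thawed, and banked
lines are sent out for genomic analysis. The details that later decide whether
a line is trustworthy — how many passages it had seen when it was frozen or
analyzed, how many sorts it took to reach a pure profile, which populations
were discontinued and why — are exactly the details that are lost when they
live in a paper notebook.

clonetrack models this workflow as an **event-sourced activity ledger**: an
append-only table of dated records (date, sample, activity, plate info, note),
constrained by controlled vocabularies, from which everything else — the
sample lineage, directory scaffolding, passage counts, clone summaries — is
recomputed deterministically.

```{r}
library(clonetrack)
```

## The naming grammar

Every sample name encodes its provenance. A transfection's base designator
concatenates, without delimiters, the date (`YYYYMMDD`), a
fluorescent-protein token, the edited gene, and the guide RNA:

```{r}
base <- sample_name("2020-01-13", "mCh", "OCT4", "sg2")
format_name(base)
```

Derivation appends underscore-delimited suffixes. Designating a clone by its
plate position appends the well; each flow sort appends (or increments) a sort
index:

```{r}
clone <- derive_clone_name(base, "C6")
format_name(derive_sort_name(derive_sort_name(clone)))
```

Because the base name has no delimiters, parsing is **vocabulary-driven**: the
fluorescent-protein token is the longest case-insensitive prefix match against
the vocabulary's fp list, the guide is the longest case-sensitive suffix
match against its guide list, and the residue between them is the gene. This
is unambiguous for every name the workflow prints; genuinely ambiguous text
raises an error rather than guessing. Two deliberate tolerances reflect real
worksheet data: fp matching is case-insensitive with as-entered casing
preserved (`mCH` and `mCh` name the same protein, and a parsed name re-formats
byte-identically), and an unlisted guide of the common letters-then-digits
shape (`sg9`) is accepted with a warning rather than rejected, because guide
lists in practice lag behind the bench.

A sort index is only valid on a clone-level name (one with a well): sorting in
this workflow happens after clone identification, and no valid name shows
`_Sort` without a well. A configuration relaxing this was considered and
rejected — it would create names the parser cannot attribute to a clone.

## Ledger, registry, and replay

A `clonetrack()` tracker couples the ledger, the vocabulary in force, the
transfection metadata sheets, and the **registry** — the forest linking every
sample to its parent. The registry is a pure function of the record sequence:
`build_registry(records, vocab)` replays the same state machine that
`record_activity()` applies incrementally, so a tracker reloaded from its
persisted CSV is identical to the one that wrote it, and two replays of the
same entry sequence produce byte-identical exports.

The state machine has four creation/mutation rules: `Transfect` on a new base
designator roots a tree; a record whose sample is an unregistered clone-level
name with a registered parent is a clone designation (this is how a
designation is stored in the fixed nine-column ledger schema — the record is
entered against the *new* name, mirroring the moment the name enters the
sample list); `Sort` on a registered clone-level sample derives a child with
the next sort index (a chain — `_Sort2`'s parent is `_Sort1`, matching the
nested sub-subfolders the workflow creates per sort); and `Discontinue` flips
a status flag. Nothing is ever deleted: corrections are new records, and
activities recorded against a discontinued sample warn and stamp the note
rather than fail, because retrospective entries are legitimate.

```{r}
tr <- clonetrack()
tr <- new_transfection(tr, transfection_metadata(base))
tr <- designate_clone(tr, "20200113mChOCT4sg2", "C6", "2020-01-16")
tr <- sort_sample(tr, "20200113mChOCT4sg2_C6", "2020-01-20")
list_samples(tr)
```

## Passage counting

`passage_table()` restricts a clone lineage's records to the
passage-relevant activities — `Passage`, `Freeze`, `Thaw`, plus the
`Extract DNA` and `Send out for analysis` milestones, included at zero count
so the passage number at analysis is readable — and annotates each row with
the running count of `Passage` events. Counting is cumulative across
freeze/thaw (a thawed vial resumes its history; there is no reset), and by
default includes passages of the clone's ancestors in the lineage, because
the passage history of the pre-designation pool is part of the culture age.
Whether pool passages *should* count is genuinely ambiguous in practice, so
`lineage = "clone"` restricts the count to the clone and its sort chain.

## Workspace scaffolding

`ensure_tree()` mirrors the registry as nested directories: each sample's
folder path is its ancestor chain, so the folder is a human-readable local
persistent identifier for the sample's image, cytometry and genomics files.
The operation is idempotent and strictly additive — folders are never
renamed, moved or removed, even for discontinued samples, because the
workspace is an archive. `audit_workspace()` reports the two possible
discrepancies (registered sample without folder; folder without registration)
as set differences.

## Export model

Reports and the ledger export to CSV (RFC 4180), XML
(`<records><record><field name="…">…`), and JSON (array of flat objects).
Tables are first canonicalized to text cells: dates render as ISO-8601
(decoupled from the designator's `YYYYMMDD`), numbers via `as.character`, and
the empty string is identified with `NA` — the two are indistinguishable in a
spreadsheet cell, and collapsing them makes round-trips exact. On canonical
tables `import_table(export_table(t, f), f)` is the identity for all three
formats, including cells with commas, quotes, embedded newlines and non-ASCII
text. The XML root carries a `columns` attribute so column order and all-NA
columns survive; a zero-row JSON array necessarily loses its schema, the one
documented asymmetry. Output bytes are deterministic: fixed field order, no
timestamps.

## The study-replica fixture

`study_replica()` deterministically replays a dataset with the shape of the
workflow's worked three-transfection example: roots `20200113mChOCT4sg2`,
`20200120mCHOCT4sg2` and `20200220mChOCT4sg2` (casing preserved as recorded);
15 designated clones; 10 discontinuations; 5 clones carried through
enrichment with at least two sorts each; and an analysis-results table with
exactly 2 surviving clones flagged for extra inserted sequence and 3 for a
copy-number variant.

The reference aggregates do not fix every detail, so the fixture makes
arbitrary-but-fixed choices, documented here and asserted by a golden-file
test: the 15 clones split 5/5/5 across transfections; the surviving wells are
C6 (first transfection), B9 (second) and A7/C6/C10 (third), the five reference
per-clone aliases; discontinued wells and daily scripts are fixed constants;
the extra-insertion flags sit on the two surviving C6 clones, the CNV flags on
those plus B9; and the deep-sort clone (four sorts, noted tendency to
differentiate, normal genome) is C10. One reference alias appears with a
seven-digit date (`2020220_A7`); the fixture normalizes it to the six-digit
convention (`200220_A7`).

`random_history(seed, ...)` complements the replica for property testing:
reproducible random transfections, wells and activity scripts in which every
record is vocabulary-valid and every generated name round-trips through the
grammar.

What passing tests on these fixtures shows — and does not. The fixtures
exercise the full grammar, the registry state machine and every report at the
scale of a real clone-derivation campaign (~10² records, ≤4 sort levels),
and the randomized histories add breadth the replica lacks. They do not
emulate multi-user entry, the ~10³-row ledgers of a long project (covered
only by the formats being O(n)), or free-text noise in vocabulary-controlled
columns, so conclusions about concurrent use or dirty legacy data are out of
reach by design.

## Numerical and scale choices

Everything here is exact integer/text computation; there are no tolerances to
tune. Test problem sizes were chosen to exercise the properties at depth
while keeping the suite quick on one CPU: 10^4 randomized names for the
parse∘format identity, 10^3 random single-clone histories against a
brute-force passage-count oracle, and a few dozen randomized tables per
export format.

## Limitations

- Names are local persistent identifiers, not global ones; two transfections
  on the same day with the same fp/gene/guide collide by design and must be
  distinguished by a token.
- Single writer: the store directory has no locking.
- The reagent calculator implements the generic amount ÷ concentration model
  with a vessel-capacity warning; bespoke formulas belong in user code.
- `short_alias()` truncates the year to two digits; aliases are only unique
  within a century and one transfection per day.
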