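---
title: "Adjudicating DNA barcode database search hits"
author: "BarcodeMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjudicating DNA barcode database search hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BarcodeMatch)
```

## The problem

DNA barcoding identifies an unknown specimen by searching a short
standardized gene region (COI for animals, ITS for fungi, rbcL and
matK — optionally trnH-psbA and ITS2 — for land plants) against a
public reference repository: the BOLD identification engine, which
reports a similarity percentage per hit, or GenBank BLAST (MegaBlast /
blastn), which reports an e-value, a bit score and a percent identity.
Public repositories inevitably carry erroneous records — specimens
misidentified at submission, records determined only to genus
("*Amanita* sp."), uncultured environmental sequences, and duplicate
names arising from synonymy — so the top of a hit list cannot be read
naively. When reference material with expert-vouched taxonomy is
searched, the pattern of agreement between the top hits and the known
identity measures the accuracy and reliability of the repository
itself.

BarcodeMatch implements that adjudication as a reusable pipeline. It
consumes archived or simulated search outputs (it never performs live
searches), so every stage is testable offline.

## Adjudication model

For each query the **top-match set** is the set of records sharing the
best match statistics. GenBank records are ranked lexicographically by
e-value (ascending), bit score (descending) and percent identity
(descending), and a record belongs to the set only when it ties the
best tuple on all three keys; BOLD records are ranked by similarity
alone. Ties use tolerances (defaults: relative 1e-9 for e-values, with
0 equal to 0; absolute 0.005 for bit score and percent statistics)
because search engines print these statistics to limited precision and
printed-equal values must adjudicate as equal.

Against the expected species (after resolving known synonyms through a
user-supplied table) each query receives exactly one status:

* **reliable_correct** — every tied record names the expected species;
* **ambiguous_correct** — the tied records include the expected
  species plus at least one other identity, categorised per co-hit as
  congeneric, heterogeneric, undetermined ("Genus sp.") or uncultured;
* **misidentified** — no tied record names the expected species; the
  assignment is rolled up to the deepest rank (genus, family, order,
  class) at which any tied record still matches the truth;
* **no_match** — the engine returned nothing usable.

Accuracy tables count ambiguous correct matches as correct and keep
no-match queries in the denominators. Query coverage is ignored
throughout: it exists only on the GenBank side, so it cannot enter a
comparison of the two databases.

Two interpretation choices were genuinely open:

* For a misidentified query the roll-up is taken as the deepest rank
  achieved by *any* tied member, rather than by a designated
  "best-ranked" member: tied members are by construction
  indistinguishable on the match statistics, and this choice keeps
  classifications invariant under record input order.
* A top set consisting solely of undetermined or uncultured records of
  the correct genus is **misidentified** at species level (rolled up to
  genus): no record carries the correct species name. Undetermined or
  uncultured records co-occurring with the correct species make the
  match ambiguous, not wrong.

## Taxon label parsing

Labels are normalised before comparison: genus capitalised, epithet
lowercased, whitespace collapsed, trinomials truncated to the
binomial. An identity is *undetermined* when the epithet is missing or
a placeholder (sp., spp., code-like epithets containing digits) and
*uncultured* when the label begins with "uncultured" or
"environmental". Open-nomenclature qualifiers (cf., aff., nr.) are
flagged and conservatively treated as undetermined. Synonym resolution
applies at species rank only and must be idempotent (no chains or
cycles); genus-level synonymy is out of scope.

## Multi-locus combination

Specimens searched at several loci (the 2-locus rbcL+matK and 4-locus
plant barcodes; ITS1/ITS2 alone versus combined) are scored by
`combineLoci()`. The default **intersection** strategy intersects the
per-locus top-set identity sets: a second locus can eliminate a
congener that tied at the first, which is how a multi-locus barcode
reduces ambiguity, but it can never introduce a species no locus
supports. Undetermined and uncultured co-hits are carried through the
set algebra as normalised placeholder identities ("Genus sp.",
"uncultured Genus") so that a single-locus combination reproduces that
locus's classification exactly. `union` and `best_locus` (fewest tied
identities, ties broken by a configurable locus priority, default
rbcL > matK > trnH-psbA > ITS2) are provided because the combination
operator for published multi-locus percentages is not standardised;
the choice is a config knob. No-match loci are dropped rather than
vetoing the specimen, so specimens with partial amplification success
still get scored.

The combined ITS mode is a distinct locus ("ITS") read from its own
hit tables — it is never synthesised from the subunit results.

## Summaries and tests

`accuracyTable()` reports percent correct per grouping cell and rank
(genus accuracy is necessarily at least species accuracy);
`ambiguitySummary()` reports, per cell, 100·ambiguous/(ambiguous +
reliable) and the cross-cell mean ± sample sd — the grouping cells for
that headline figure are a user choice (taxon group × database ×
locus-strategy by default) because the aggregation behind such
study-wide figures is rarely stated. `similaritySummary()` gives mean
± sd of the top similarity for any status subset; a low BOLD
similarity on a misidentified query is the practical signal of a bad
match, and `flagConfidence()` applies the 96% threshold below which
restricted BOLD sequence subsets tend to return no match at all
(the boundary itself counts as high confidence).

Hypothesis tests wrap the standard machinery: `twoSampleTTest()`
(Welch by default — the variant behind published p-values is usually
unstated, and Welch is the safer default; pooled available),
`oneWayANOVA()` (classical fixed-effects F). Degenerate inputs follow
explicit contracts rather than erroring: two constant equal samples
give t = 0, p = 1; an all-constant ANOVA gives F = 0. Run-to-run
comparisons (`compareRuns()`) align runs on shared queries, test
per-query binary correctness indicators (not per-group percentages —
both are representable, binary is the default), and flag queries whose
status changes between runs. No multiple-testing correction is
applied; raw p-values are reported.

## The simulator

`SimConfig()` / `generateStudyFixture()` generate a reference taxonomy
(default 3 classes × 2 orders × 2 families × 3 genera × 4 species =
288 species), a reference database (5 records per species) and query
sets, with controlled rates of:

* **mislabelRate** (default 0.10) — a record labelled as a uniformly
  chosen congener (confamilial fallback for monotypic genera); the
  default sits in the range estimated for unreliable records in public
  fungal sequence collections (up to ~20%);
* **undeterminedRate** (0.10) / **unculturedRate** (0.05) — records
  labelled "Genus sp." or "uncultured Genus";
* **missingSpeciesRate** (0.05) — species absent from the database
  entirely;
* **tieRate** (0.10) — the runner-up's statistics copied from the best
  hit, manufacturing the exact ties that drive ambiguity.

Percent identity is drawn per record from a truncated normal whose
mean falls with taxonomic distance (conspecific 99.5 ± 0.4, congeneric
96 ± 1.5, confamilial 92 ± 2, ordinal 88 ± 3, background 80 ± 5; means
must be strictly decreasing). Query lengths emulate an insect COI
study: 70% full-length (614 ± 34 bp) and 30% mid-length (340 ± 65 bp)
amplicons. GenBank-dialect statistics are produced by a generator
convention shaped like the Karlin–Altschul statistics — raw score with
MegaBlast reward/penalty (1, −2), bit score (1.28·s − ln 0.46)/ln 2,
e-value dbSize·L·2^−bitscore — chosen for realism of magnitudes and
strict monotonicity in percent identity; they are *not* claims about
BLAST internals. Fixture FASTA sequences are random because the
pipeline never aligns; only their recorded lengths matter.

What the simulator does **not** emulate: nucleotide-level evolution,
chimeras and pseudogenes (only their label-level consequences),
query-coverage effects, and the heavy-tailed similarity distributions
of real heterogeneric hits. Passing parameter-recovery tests therefore
demonstrates that the adjudication logic is correct under the stated
generative model, not that real repositories behave like the model.

## Numerical choices and problem sizes

* Tie tolerances as above; enlarging them can only grow a tie set
  (tested as a property).
* The tie-set oracle test compares against an exhaustive pairwise
  scan over 1,000 random tables of up to 50 hits.
* Parameter-recovery checks use tight score noise (sd 0.1) for the
  exact 100% / 0% contracts — with broad noise a congener can
  legitimately outscore a conspecific record, which is a feature of
  the model, not an adjudication error — and 10,000 single-query
  replicates against an independently coded Monte-Carlo oracle for the
  mislabel-displacement rate, compared inside a 99% binomial band.
* The acceptance script simulates the default 50-query scenario per
  database dialect; all sizes keep the full suite in the minutes
  range on one CPU.
* Length stratification defaults to the full-length barcode cutoff
  (≥ 640 bp) with everything below assigned to the mid-length stratum;
  with the default length model most 614 ± 34 bp amplicons fall just
  under the cutoff, which mirrors how a strict full-length subset
  definition behaves on real amplicon sets.

## Known limitations

* The archived-workbook dialect adapter reads rectangular
  header-plus-rows sheets (shared strings, inline strings, numbers);
  it is not a general spreadsheet parser, and a workbook's layout must
  be described by a dialect config authored against the file.
* Synonym tables are user-supplied and empty by default; no taxonomy
  service is consulted.
* Alignment coordinates in BLAST tabular input are carried through
  verbatim (1-based inclusive) and never interpreted.
* Statistics are taken as reported by the source engine; hits are
  never re-ranked by recomputed alignments.

## A small worked example

```{r example}
cfg <- SimConfig(seed = 42L, nQueries = 20L)
fixture <- generateStudyFixture(cfg, file.path(tempdir(), "demo"))
truth <- readTruthTable(fixture$truth)
synonyms <- readSynonymTable(fixture$synonyms)
tables <- readBlastTabular(fixture$genbank, locus = "COI")
cls <- lapply(tables, function(tb) {
  row <- truth[truth$specimen_id == queryId(tb), ]
  classifyHitTable(tb, Lineage(class_ = row$class, order = row$order,
                               family = row$family, genus = row$genus,
                               species = row$species),
                   synonyms = synonyms)
})
df <- classificationTable(cls)
table(df$status)
accuracyTable(df, groupKeys = "source_db")
```
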