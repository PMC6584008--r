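## Shared builders for tests. Everything is generated in code at test
## time; no stored binary fixtures.

HIT_COLUMNS_FOR_TEST <- c("subject_id", "subject_label", "pident",
                          "length", "evalue", "bitscore", "similarity")

## A GenBank-dialect hit table from parallel statistic vectors.
gbTable <- function(qid, labels, evalue, bitscore, pident,
                    locus = "COI", runId = "default",
                    queryLength = NA_integer_) {
  HitTable(qid, data.frame(
    subject_id = paste0("ACC", seq_along(labels)),
    subject_label = labels, pident = pident, length = 600,
    evalue = evalue, bitscore = bitscore, similarity = NA_real_,
    stringsAsFactors = FALSE
  ), sourceDb = "genbank", locus = locus, runId = runId,
  queryLength = queryLength)
}

## A BOLD-dialect hit table.
boldTable <- function(qid, labels, similarity, locus = "COI",
                      runId = "default") {
  HitTable(qid, data.frame(
    subject_id = paste0("BOLD", seq_along(labels)),
    subject_label = labels, similarity = similarity,
    stringsAsFactors = FALSE
  ), sourceDb = "bold", locus = locus, runId = runId)
}

## Random GenBank-dialect table for property tests; draws statistics
## from a small value pool so exact ties are frequent.
randomGbTable <- function(qid = "Q", maxHitsPool = 50) {
  n <- sample.int(maxHitsPool, 1)
  ev_pool <- c(0, 10^(-sample(5:60, 8, replace = TRUE)))
  bs_pool <- round(runif(6, 200, 1200), 2)
  pi_pool <- round(runif(6, 80, 100), 2)
  gbTable(qid, labels = paste("Aus", letters[sample.int(26, n,
                                                        replace = TRUE)]),
          evalue = sample(ev_pool, n, replace = TRUE),
          bitscore = sample(bs_pool, n, replace = TRUE),
          pident = sample(pi_pool, n, replace = TRUE))
}

## Independent exhaustive oracle for the top-match set: finds the best
## record by pairwise comparison, then scans every record against the
## best tuple. Shares no code with topMatchSet().
oracleTopSet <- function(table, policy = TiePolicy()) {
  h <- hits(table)
  if (nrow(h) == 0L) return(integer())
  rtol <- 1e-9; ptol <- 0.005; btol <- 0.005
  eEq <- function(a, b) (a == 0 && b == 0) || abs(a - b) <= rtol * max(a, b)
  if (sourceDb(table) == "genbank") {
    ## pairwise "a beats b" under (evalue asc, bitscore desc, pident desc)
    beats <- function(a, b) {
      if (!eEq(h$evalue[a], h$evalue[b]))
        return(h$evalue[a] < h$evalue[b])
      if (abs(h$bitscore[a] - h$bitscore[b]) > btol)
        return(h$bitscore[a] > h$bitscore[b])
      if (abs(h$pident[a] - h$pident[b]) > ptol)
        return(h$pident[a] > h$pident[b])
      FALSE
    }
    best <- 1L
    for (i in seq_len(nrow(h))[-1]) if (beats(i, best)) best <- i
    which(vapply(seq_len(nrow(h)), function(i)
      !beats(best, i) && !beats(i, best), TRUE))
  } else {
    best <- max(h$similarity)
    which(h$similarity >= best - ptol)
  }
}

## Truth lineage for one specimen id out of a truth table data.frame.
truthLineageFor <- function(truth, qid) {
  row <- truth[truth$specimen_id == qid, ][1, ]
  Lineage(class_ = row$class, order = row$order, family = row$family,
          genus = row$genus, species = row$species)
}

## Classify every table of a fixture bundle against its truth table.
classifyBundle <- function(tables, truth, synonyms = emptySynonymTable(),
                           threshold = 96) {
  lapply(tables, function(tb)
    classifyHitTable(tb, truthLineageFor(truth, queryId(tb)),
                     synonyms = synonyms,
                     confidenceThreshold = threshold))
}
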