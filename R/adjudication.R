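## Top-match adjudication: which records share the best match
## statistics, and what that set says about the identification.
##
## A query is correctly identified when a record with the expected
## taxonomic name carries the top match statistic (lowest e-value,
## highest bit score and highest percent identity for GenBank; highest
## similarity for BOLD). The identification is reliable when every
## record tied at the top names the expected species, and an ambiguous
## correct match when the tied records span more than one identity
## (a congener, a different genus, an undetermined "Genus sp." record
## or an uncultured record). When no tied record names the expected
## species the query is misidentified at species level, and the
## assignment is rolled up to the deepest rank that still matches.

#' @rdname TiePolicy-class
#' @param evalueRtol relative tolerance for e-value equality.
#' @param percentTol absolute tolerance for percent identity /
#'   similarity equality.
#' @param bitscoreTol absolute tolerance for bit score equality.
#' @export
TiePolicy <- function(evalueRtol = 1e-9, percentTol = 0.005,
                      bitscoreTol = 0.005) {
  new("TiePolicy", evalueRtol = evalueRtol, percentTol = percentTol,
      bitscoreTol = bitscoreTol)
}

## e-value equality under the policy: exact zeros compare equal, else
## relative difference within tolerance.
.evalueTied <- function(a, b, rtol) {
  (a == 0 & b == 0) | abs(a - b) <= rtol * pmax(a, b)
}

#' Compute the top-match set of a hit table
#'
#' Finds all records tied with the lexicographic best under the source
#' database's key order: GenBank ranks by e-value (ascending), then bit
#' score (descending), then percent identity (descending), and a record
#' is a member only when it ties the best tuple on all three keys; BOLD
#' ranks by similarity alone. Equality uses the
#' \linkS4class{TiePolicy} tolerances, so statistics that print equal
#' are tied. An empty table yields an empty set (the no-match case).
#'
#' @param table a \linkS4class{HitTable}.
#' @param policy a \linkS4class{TiePolicy}.
#' @return a \linkS4class{TopMatchSet}.
#' @export
topMatchSet <- function(table, policy = TiePolicy()) {
  stopifnot(is(table, "HitTable"), is(policy, "TiePolicy"))
  h <- hits(table)
  if (nrow(h) == 0L)
    return(new("TopMatchSet", queryId = queryId(table),
               members = h, best = list(), tieCount = 0L,
               sourceDb = sourceDb(table)))
  if (identical(sourceDb(table), "genbank")) {
    if (anyNA(h$evalue) || anyNA(h$bitscore) || anyNA(h$pident))
      stop("genbank records need evalue, bitscore and pident for adjudication")
    best_e <- min(h$evalue)
    sel <- .evalueTied(h$evalue, best_e, policy@evalueRtol)
    best_b <- max(h$bitscore[sel])
    sel <- sel & h$bitscore >= best_b - policy@bitscoreTol
    best_p <- max(h$pident[sel])
    sel <- sel & h$pident >= best_p - policy@percentTol
    best <- list(evalue = best_e, bitscore = best_b, pident = best_p)
  } else {
    if (anyNA(h$similarity))
      stop("bold records need similarity for adjudication")
    best_s <- max(h$similarity)
    sel <- h$similarity >= best_s - policy@percentTol
    best <- list(similarity = best_s)
  }
  memb <- h[sel, , drop = FALSE]
  rownames(memb) <- NULL
  new("TopMatchSet", queryId = queryId(table), members = memb,
      best = best, tieCount = sum(sel), sourceDb = sourceDb(table))
}

## Candidate identity of a parsed top-set member: the resolved
## canonical binomial when determined, otherwise a normalized
## placeholder that survives set algebra in the multilocus combination.
.memberIdentity <- function(parsed, resolved) {
  ifelse(nzchar(parsed$canonical_binomial), resolved,
         ifelse(parsed$is_uncultured,
                squish(paste("uncultured", parsed$genus)),
                squish(paste(parsed$genus, "sp."))))
}

## Deepest rank at which one member's reported taxonomy matches the
## truth; uses the parsed genus plus any class/order/family columns the
## record carries.
.memberDepths <- function(members, parsed, truth) {
  n <- nrow(members)
  depth <- rep(NA_integer_, n)
  for (rank in c("class", "order", "family")) {
    tv <- lineageRank(truth, rank)
    if (!nzchar(tv) || !rank %in% names(members)) next
    mv <- as.character(members[[rank]])
    mv[is.na(mv)] <- ""
    ok <- foldEq(mv, tv)
    depth[ok] <- pmax(depth[ok], rankDepth(rank), na.rm = TRUE)
  }
  gok <- foldEq(parsed$genus, lineageRank(truth, "genus"))
  depth[gok] <- pmax(depth[gok], rankDepth("genus"), na.rm = TRUE)
  depth
}

#' Classify one query from its top-match set
#'
#' Applies the adjudication rules: \emph{reliable_correct} when every
#' member of the top set names the expected species (after synonym
#' resolution); \emph{ambiguous_correct} when the set contains the
#' expected species plus at least one other identity, with per-member
#' ambiguity categories (congeneric, heterogeneric,
#' undetermined_species, uncultured); \emph{misidentified} when no
#' member names the expected species, rolled up to the deepest rank at
#' which any tied member still matches the truth; \emph{no_match} for
#' an empty set. The best similarity statistic (BOLD similarity or
#' GenBank percent identity) is reported and flagged low-confidence
#' below the threshold.
#'
#' @param top a \linkS4class{TopMatchSet}.
#' @param truth the expected \linkS4class{Lineage} (species filled).
#' @param synonyms a \linkS4class{SynonymTable}; known synonyms of the
#'   expected species are not counted as conflicting identities.
#' @param confidenceThreshold percent similarity below which a match is
#'   flagged low-confidence (default 96).
#' @param locus,runId,group labels for the resulting classification
#'   (defaulted from the hit table by \code{\link{classifyHitTable}}).
#' @return a \linkS4class{Classification}.
#' @export
classifyQuery <- function(top, truth, synonyms = emptySynonymTable(),
                          confidenceThreshold = 96,
                          locus = NA_character_, runId = "default",
                          group = NA_character_) {
  stopifnot(is(top, "TopMatchSet"), is(truth, "Lineage"))
  if (!nzchar(truth@species))
    stop("truth lineage must have species filled")
  truth_sp <- resolveSynonym(truth@species, synonyms)
  if (tieCount(top) == 0L)
    return(new("Classification", queryId = queryId(top), locus = locus,
               sourceDb = sourceDb(top), runId = runId, group = group,
               status = "no_match", truthSpecies = truth_sp,
               candidateSpecies = character()))
  memb <- members(top)
  parsed <- .parseTaxa(memb$subject_label)
  resolved <- resolveSynonym(parsed$canonical_binomial, synonyms)
  matches <- nzchar(parsed$canonical_binomial) & foldEq(resolved, truth_sp)
  ident <- .memberIdentity(parsed, resolved)
  sim <- if (identical(sourceDb(top), "bold")) memb$similarity
    else memb$pident
  top_sim <- if (all(is.na(sim))) NA_real_ else max(sim, na.rm = TRUE)
  low <- if (is.na(top_sim)) NA else top_sim < confidenceThreshold
  if (all(matches)) {
    status <- "reliable_correct"
    deepest <- "species"
    categories <- character()
  } else if (any(matches)) {
    status <- "ambiguous_correct"
    deepest <- "species"
    p <- parsed[!matches, , drop = FALSE]
    categories <- unique(ifelse(
      p$is_uncultured, "uncultured",
      ifelse(p$is_undetermined, "undetermined_species",
             ifelse(foldEq(p$genus, lineageRank(truth, "genus")),
                    "congeneric", "heterogeneric"))))
  } else {
    status <- "misidentified"
    categories <- character()
    depths <- .memberDepths(memb, parsed, truth)
    deepest <- if (all(is.na(depths))) NA_character_
      else BARCODE_RANKS[max(depths, na.rm = TRUE)]
  }
  new("Classification", queryId = queryId(top), locus = locus,
      sourceDb = sourceDb(top), runId = runId, group = group,
      status = status, deepestCorrectRank = deepest,
      categories = categories, topSimilarity = top_sim,
      lowConfidence = low,
      candidateSpecies = unique(ident), truthSpecies = truth_sp)
}

#' Adjudicate and classify a hit table in one step
#'
#' @param table a \linkS4class{HitTable}.
#' @param truth the expected \linkS4class{Lineage}.
#' @param synonyms a \linkS4class{SynonymTable}.
#' @param policy a \linkS4class{TiePolicy}.
#' @param confidenceThreshold see \code{\link{classifyQuery}}.
#' @return a \linkS4class{Classification}.
#' @export
classifyHitTable <- function(table, truth,
                             synonyms = emptySynonymTable(),
                             policy = TiePolicy(),
                             confidenceThreshold = 96) {
  classifyQuery(topMatchSet(table, policy), truth, synonyms,
                confidenceThreshold, locus = locusName(table),
                runId = runId(table), group = table@group)
}

#' Tabulate classifications
#'
#' Flattens a list of \linkS4class{Classification} objects into the
#' per-query classification table (one row per query); multi-valued
#' fields are ";"-joined.
#'
#' @param classifications list of \linkS4class{Classification}.
#' @return data.frame with columns query_id, locus, source_db, run_id,
#'   group, status, deepest_correct_rank, categories, top_similarity,
#'   low_confidence, candidate_species, truth_species.
#' @export
classificationTable <- function(classifications) {
  stopifnot(all(vapply(classifications, is, TRUE, "Classification")))
  data.frame(
    query_id = vapply(classifications, queryId, ""),
    locus = vapply(classifications, locusName, ""),
    source_db = vapply(classifications, sourceDb, ""),
    run_id = vapply(classifications, runId, ""),
    group = vapply(classifications, function(x) x@group, ""),
    status = vapply(classifications, classificationStatus, ""),
    deepest_correct_rank = vapply(classifications, deepestRank, ""),
    categories = vapply(classifications, function(x)
      paste(ambiguityCategories(x), collapse = ";"), ""),
    top_similarity = vapply(classifications, topSimilarity, 0),
    low_confidence = vapply(classifications, function(x)
      x@lowConfidence, NA),
    candidate_species = vapply(classifications, function(x)
      paste(candidateSpecies(x), collapse = ";"), ""),
    truth_species = vapply(classifications, function(x)
      x@truthSpecies, ""),
    stringsAsFactors = FALSE
  )
}

#' Flag low-confidence matches by similarity
#'
#' A match is low-confidence when the percent similarity falls below
#' the threshold. Queries returning <96\% similarity against the full
#' BOLD sequence subset become "no match" against the restricted
#' subsets, which motivates the default threshold of 96.
#'
#' @param similarity numeric vector of percent similarities in
#'   \code{[0, 100]}.
#' @param threshold percent threshold (default 96); the boundary is
#'   high-confidence (\code{similarity == threshold} is not low).
#' @return logical vector, \code{TRUE} = low confidence.
#' @export
flagConfidence <- function(similarity, threshold = 96) {
  stopifnot(all(similarity >= 0 & similarity <= 100, na.rm = TRUE))
  similarity < threshold
}

#' Stratify classifications by query length
#'
#' Partitions queries into full-length (\code{>= fullCutoff}) and
#' mid-length strata and reports the per-stratum species-level
#' misidentification rate. Queries between the two cutoffs are assigned
#' to the mid-length stratum.
#'
#' @param classifications a classification table
#'   (\code{\link{classificationTable}}) or list of
#'   \linkS4class{Classification}.
#' @param lengths named vector of query lengths in bases (e.g. from
#'   \code{\link{readQueryFasta}}).
#' @param fullCutoff full-length threshold in bases (default 640, the
#'   full-length COI barcode cutoff).
#' @param midCutoff mid-length threshold in bases (default 430).
#' @return list with \code{assignment} (named stratum per query) and
#'   \code{summary} (per-stratum n, misidentified count and rate in
#'   percent).
#' @export
stratifyByLength <- function(classifications, lengths,
                             fullCutoff = 640, midCutoff = 430) {
  df <- if (is.data.frame(classifications)) classifications
    else classificationTable(classifications)
  missing <- setdiff(df$query_id, names(lengths))
  if (length(missing))
    stop("no length for query id(s): ", paste(missing, collapse = ", "))
  len <- lengths[df$query_id]
  stratum <- ifelse(len >= fullCutoff, "full", "mid")
  summ <- do.call(rbind, lapply(c("full", "mid"), function(s) {
    idx <- stratum == s
    n <- sum(idx)
    n_mis <- sum(df$status[idx] == "misidentified")
    data.frame(stratum = s, n = n, n_misidentified = n_mis,
               misidentification_rate_pct =
                 if (n > 0) 100 * n_mis / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(assignment = setNames(stratum, df$query_id), summary = summ)
}
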