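## Multi-locus combination: one specimen, several barcode loci, one
## identification. The default strategy intersects the top-set identity
## sets across loci: a second locus can strip a congener that tied at
## the first locus (how the 4-locus plant barcode reduces ambiguity
## relative to the 2-locus barcode) but can never manufacture a species
## no locus supports.

DEFAULT_LOCUS_PRIORITY <- c("rbcL", "matK", "trnH-psbA", "ITS2")

.identityCategories <- function(identities, truthSpecies) {
  if (length(identities) == 0L) return(character())
  p <- .parseTaxa(identities)
  truth_genus <- strsplit(squish(truthSpecies), " ")[[1]][1]
  unique(ifelse(
    p$is_uncultured, "uncultured",
    ifelse(p$is_undetermined, "undetermined_species",
           ifelse(foldEq(p$genus, truth_genus),
                  "congeneric", "heterogeneric"))))
}

## Deepest rank supported by every locus: species for correct loci,
## the per-locus roll-up otherwise; NA as soon as one locus matched at
## no rank.
.sharedDepth <- function(classifications) {
  depths <- vapply(classifications, function(cl) {
    if (classificationStatus(cl) %in%
        c("reliable_correct", "ambiguous_correct"))
      return(rankDepth("species"))
    r <- deepestRank(cl)
    if (is.na(r)) NA_integer_ else rankDepth(r)
  }, 1L)
  if (anyNA(depths)) NA_character_ else BARCODE_RANKS[min(depths)]
}

#' Combine per-locus classifications for one specimen
#'
#' Combines the classifications of several barcode loci for one
#' specimen into a single multi-locus identification. Loci that
#' returned no match are dropped before combination (all-no_match input
#' is an error). Strategies:
#' \describe{
#'   \item{intersection (default)}{the candidate identity set is the
#'     intersection over loci of each locus's top-set identities;
#'     reliable when the intersection is exactly the expected species,
#'     ambiguous when it contains the expected species plus others,
#'     misidentified when it excludes it.}
#'   \item{union}{as above over the union of top-set identities.}
#'   \item{best_locus}{the single locus with the fewest tied
#'     identities decides; ties between loci are broken by
#'     \code{lociPriority}.}
#' }
#' When the combination is misidentified, the roll-up is the deepest
#' rank supported by every locus.
#'
#' @param perLocus list of \linkS4class{Classification} for one
#'   specimen, one per locus.
#' @param strategy "intersection", "union" or "best_locus".
#' @param lociPriority locus order used to break best_locus ties.
#' @return a \linkS4class{SpecimenClassification}.
#' @export
combineLoci <- function(perLocus,
                        strategy = c("intersection", "union",
                                     "best_locus"),
                        lociPriority = DEFAULT_LOCUS_PRIORITY) {
  strategy <- match.arg(strategy)
  stopifnot(length(perLocus) >= 1L,
            all(vapply(perLocus, is, TRUE, "Classification")))
  ids <- unique(vapply(perLocus, queryId, ""))
  if (length(ids) != 1L)
    stop("all classifications must belong to one specimen; got: ",
         paste(ids, collapse = ", "))
  kept <- Filter(function(cl)
    !identical(classificationStatus(cl), "no_match"), perLocus)
  if (length(kept) == 0L)
    stop("every locus returned no match for specimen '", ids, "'")
  truth <- kept[[1]]@truthSpecies
  loci <- vapply(kept, locusName, "")
  sets <- lapply(kept, candidateSpecies)

  if (strategy == "best_locus") {
    prio <- match(loci, lociPriority)
    prio[is.na(prio)] <- length(lociPriority) + seq_len(sum(is.na(prio)))
    pick <- order(lengths(sets), prio)[1]
    chosen <- kept[[pick]]
    return(new("SpecimenClassification", specimenId = ids,
               loci = loci, strategy = strategy,
               status = classificationStatus(chosen),
               deepestCorrectRank = deepestRank(chosen),
               categories = ambiguityCategories(chosen),
               candidateSpecies = candidateSpecies(chosen),
               truthSpecies = truth))
  }

  combined <- Reduce(if (strategy == "intersection") intersect else union,
                     sets)
  truth_in <- any(foldEq(combined, truth))
  if (truth_in && length(combined) == 1L) {
    status <- "reliable_correct"; deepest <- "species"
    categories <- character()
  } else if (truth_in) {
    status <- "ambiguous_correct"; deepest <- "species"
    categories <- .identityCategories(
      combined[!foldEq(combined, truth)], truth)
  } else {
    status <- "misidentified"
    deepest <- .sharedDepth(kept)
    categories <- character()
  }
  new("SpecimenClassification", specimenId = ids, loci = loci,
      strategy = strategy, status = status,
      deepestCorrectRank = deepest, categories = categories,
      candidateSpecies = combined, truthSpecies = truth)
}

#' Tabulate specimen-level classifications
#'
#' @param specimens list of \linkS4class{SpecimenClassification}.
#' @return data.frame mirroring the per-query classification table plus
#'   strategy and loci columns.
#' @export
specimenClassificationTable <- function(specimens) {
  stopifnot(all(vapply(specimens, is, TRUE, "SpecimenClassification")))
  data.frame(
    specimen_id = vapply(specimens, function(x) x@specimenId, ""),
    loci = vapply(specimens, function(x)
      paste(x@loci, collapse = ";"), ""),
    strategy = vapply(specimens, function(x) x@strategy, ""),
    status = vapply(specimens, classificationStatus, ""),
    deepest_correct_rank = vapply(specimens, deepestRank, ""),
    categories = vapply(specimens, function(x)
      paste(ambiguityCategories(x), collapse = ";"), ""),
    candidate_species = vapply(specimens, function(x)
      paste(candidateSpecies(x), collapse = ";"), ""),
    truth_species = vapply(specimens, function(x) x@truthSpecies, ""),
    stringsAsFactors = FALSE
  )
}

#' Compare ITS search modes per specimen
#'
#' Tabulates, side by side, the classification obtained from searching
#' ITS subunit 1 alone, subunit 2 alone, and the combined ITS1+ITS2
#' sequence (a distinct locus, "ITS", read from its own hit tables).
#' Discordance between modes is flagged; the combined-mode status is
#' reported as the headline when present.
#'
#' @param classifications list of \linkS4class{Classification} whose
#'   loci are among ITS1, ITS2 and ITS; may span several specimens.
#' @return data.frame with one row per specimen: per-mode status,
#'   \code{concordant} flag and \code{headline} status.
#' @export
itsModes <- function(classifications) {
  stopifnot(all(vapply(classifications, is, TRUE, "Classification")))
  loci <- vapply(classifications, locusName, "")
  ok <- loci %in% c("ITS1", "ITS2", "ITS")
  if (!all(ok))
    stop("unexpected locus for ITS comparison: ",
         paste(unique(loci[!ok]), collapse = ", "))
  sid <- vapply(classifications, queryId, "")
  rows <- lapply(unique(sid), function(s) {
    cls <- classifications[sid == s]
    lc <- vapply(cls, locusName, "")
    pick <- function(l) {
      i <- match(l, lc)
      if (is.na(i)) NA_character_ else classificationStatus(cls[[i]])
    }
    st <- c(ITS1 = pick("ITS1"), ITS2 = pick("ITS2"), ITS = pick("ITS"))
    present <- st[!is.na(st)]
    data.frame(specimen_id = s, status_its1 = st[["ITS1"]],
               status_its2 = st[["ITS2"]], status_its = st[["ITS"]],
               concordant = length(unique(present)) <= 1L,
               headline = if (!is.na(st[["ITS"]])) st[["ITS"]]
                 else present[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
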