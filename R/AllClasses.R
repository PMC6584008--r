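## S4 class definitions for the hit-adjudication model.

#' ParsedTaxon: a normalized taxon label
#'
#' Result of parsing a raw database taxon label into its genus and species
#' components, with flags for undetermined ("Amanita sp."), uncultured /
#' environmental, and qualified (cf., aff., nr.) identities.
#'
#' @slot rawLabel the label as read from the source.
#' @slot genus capitalized genus, or \code{""} when none could be parsed.
#' @slot speciesEpithet lowercased epithet, \code{""} for placeholders.
#' @slot isUndetermined \code{TRUE} when the epithet is absent or a
#'   placeholder token (sp., spp., numeric codes, qualifiers).
#' @slot isUncultured \code{TRUE} for uncultured/environmental records.
#' @slot isQualified \code{TRUE} for open-nomenclature qualifiers
#'   (cf., aff., nr.).
#' @slot canonicalBinomial "Genus epithet", or \code{""} unless both parts
#'   are present and the identity is determined.
#' @exportClass ParsedTaxon
setClass("ParsedTaxon",
  representation(
    rawLabel = "character",
    genus = "character",
    speciesEpithet = "character",
    isUndetermined = "logical",
    isUncultured = "logical",
    isQualified = "logical",
    canonicalBinomial = "character"
  )
)

setValidity("ParsedTaxon", function(object) {
  msgs <- character()
  complete <- nzchar(object@genus) && nzchar(object@speciesEpithet) &&
    !object@isUndetermined
  if (nzchar(object@canonicalBinomial) != complete)
    msgs <- c(msgs, "canonicalBinomial must be set iff genus and epithet are present and the identity is determined")
  if (!object@isUndetermined && !nzchar(object@speciesEpithet))
    msgs <- c(msgs, "empty epithet implies isUndetermined")
  if (length(msgs)) msgs else TRUE
})

#' Lineage: a five-rank taxonomic lineage
#'
#' Ranks are fixed, shallow to deep, as class, order, family, genus,
#' species (canonical binomial). An empty string means the rank is
#' unknown; an unknown rank never matches anything.
#'
#' @slot class_ class name ("" = unknown).
#' @slot order order name.
#' @slot family family name.
#' @slot genus genus name.
#' @slot species canonical binomial; when present it must begin with the
#'   genus.
#' @exportClass Lineage
setClass("Lineage",
  representation(
    class_ = "character",
    order = "character",
    family = "character",
    genus = "character",
    species = "character"
  ),
  prototype(class_ = "", order = "", family = "", genus = "", species = "")
)

setValidity("Lineage", function(object) {
  if (nzchar(object@species)) {
    if (!nzchar(object@genus))
      return("species set but genus unknown")
    if (!startsWith(tolower(object@species), tolower(object@genus)))
      return("species binomial must begin with the genus")
  }
  TRUE
})

#' SynonymTable: alias binomial to canonical binomial mapping
#'
#' Case-insensitive species-level synonymy. The mapping must be
#' idempotent after one application: a canonical name either maps to
#' itself or is absent, and no cycles are allowed.
#'
#' @slot map named character vector; names are lowercased alias
#'   binomials, values the canonical binomials.
#' @slot provenance free-text note per entry (same length as map).
#' @exportClass SynonymTable
setClass("SynonymTable",
  representation(map = "character", provenance = "character"),
  prototype(map = setNames(character(), character()),
            provenance = character())
)

setValidity("SynonymTable", function(object) {
  if (length(object@map) != length(object@provenance))
    return("provenance must parallel the mapping")
  if (length(object@map) == 0L) return(TRUE)
  if (is.null(names(object@map)) || any(!nzchar(names(object@map))))
    return("aliases must be named, nonempty strings")
  keys <- names(object@map)
  vals <- tolower(object@map)
  hit <- match(vals, keys)
  bad <- !is.na(hit) & tolower(object@map[hit]) != vals
  if (any(bad))
    return(paste0("mapping is not idempotent (chain or cycle) for: ",
                  paste(object@map[bad], collapse = ", ")))
  TRUE
})

#' HitTable: all retained search hits for one query
#'
#' One search-engine result set for a single query sequence, in the
#' order reported by the engine, truncated to \code{maxHits} records.
#' GenBank-dialect rows carry percent identity, e-value and bit score;
#' BOLD-dialect rows carry the similarity percentage.
#'
#' @slot queryId query (specimen) identifier.
#' @slot locus barcode locus (COI, rbcL, matK, trnH-psbA, ITS, ITS1, ITS2).
#' @slot sourceDb "genbank" or "bold".
#' @slot runId label of the search parameter set / sequence subset.
#' @slot group taxonomic group label (insects, macro-fungi, plants); may
#'   be \code{NA}.
#' @slot queryLength query length in bases, or \code{NA}.
#' @slot hits data.frame with columns subject_id, subject_label, pident,
#'   length, evalue, bitscore, similarity (plus optional rank columns
#'   class, order, family carried through from BOLD exports).
#' @exportClass HitTable
setClass("HitTable",
  representation(
    queryId = "character",
    locus = "character",
    sourceDb = "character",
    runId = "character",
    group = "character",
    queryLength = "integer",
    hits = "data.frame"
  ),
  prototype(locus = NA_character_, runId = "default", group = NA_character_,
            queryLength = NA_integer_)
)

HIT_COLUMNS <- c("subject_id", "subject_label", "pident", "length",
                 "evalue", "bitscore", "similarity")

setValidity("HitTable", function(object) {
  msgs <- character()
  if (!object@sourceDb %in% c("genbank", "bold"))
    msgs <- c(msgs, "sourceDb must be 'genbank' or 'bold'")
  h <- object@hits
  missing_cols <- setdiff(HIT_COLUMNS, names(h))
  if (length(missing_cols))
    return(paste0("hits is missing columns: ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(h)) {
    if (identical(object@sourceDb, "genbank")) {
      if (anyNA(h$pident) || anyNA(h$evalue) || anyNA(h$bitscore))
        msgs <- c(msgs, "genbank hits need pident, evalue and bitscore on every row")
    } else {
      if (anyNA(h$similarity))
        msgs <- c(msgs, "bold hits need similarity on every row")
    }
    pc <- c(h$pident, h$similarity)
    pc <- pc[!is.na(pc)]
    if (length(pc) && (any(pc < 0) || any(pc > 100)))
      msgs <- c(msgs, "percent statistics must lie in [0, 100]")
    ev <- h$evalue[!is.na(h$evalue)]
    if (length(ev) && any(ev < 0))
      msgs <- c(msgs, "e-values must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

#' TiePolicy: when two match statistics count as equal
#'
#' GenBank records are ranked on (e-value ascending, bit score
#' descending, percent identity descending); BOLD records on similarity
#' descending. Statistics within tolerance of the best tuple are tied:
#' search engines print e-values to limited precision and percent
#' statistics to two decimals, so printed-equal values are treated as
#' equal.
#'
#' @slot evalueRtol relative tolerance for e-value equality (0 == 0 is
#'   always equal).
#' @slot percentTol absolute tolerance for percent identity / similarity.
#' @slot bitscoreTol absolute tolerance for bit score.
#' @exportClass TiePolicy
setClass("TiePolicy",
  representation(evalueRtol = "numeric", percentTol = "numeric",
                 bitscoreTol = "numeric"),
  prototype(evalueRtol = 1e-9, percentTol = 0.005, bitscoreTol = 0.005)
)

setValidity("TiePolicy", function(object) {
  if (object@evalueRtol < 0 || object@percentTol < 0 ||
      object@bitscoreTol < 0)
    return("tolerances must be nonnegative")
  TRUE
})

#' TopMatchSet: the records sharing the best match statistics
#'
#' @slot queryId the query the set belongs to.
#' @slot members data.frame of tied records (possibly zero rows).
#' @slot best named list with the best statistics tuple.
#' @slot tieCount number of members.
#' @slot sourceDb dialect of the source table.
#' @exportClass TopMatchSet
setClass("TopMatchSet",
  representation(queryId = "character", members = "data.frame",
                 best = "list", tieCount = "integer",
                 sourceDb = "character")
)

setValidity("TopMatchSet", function(object) {
  if (object@tieCount != nrow(object@members))
    return("tieCount must equal the number of members")
  TRUE
})

#' Classification: the adjudicated outcome for one query
#'
#' @slot queryId,locus,sourceDb,runId,group identifiers copied from the
#'   hit table.
#' @slot status one of reliable_correct, ambiguous_correct,
#'   misidentified, no_match.
#' @slot deepestCorrectRank deepest rank at which the top set matches the
#'   truth, or \code{NA}.
#' @slot categories ambiguity categories (congeneric, heterogeneric,
#'   undetermined_species, uncultured); nonempty iff ambiguous_correct.
#' @slot topSimilarity best percent identity / similarity, or \code{NA}
#'   for no_match.
#' @slot lowConfidence \code{TRUE} when topSimilarity falls below the
#'   confidence threshold.
#' @slot candidateSpecies identities in the top set: canonical binomials,
#'   or normalized placeholders ("Genus sp.", "uncultured Genus") for
#'   undetermined / uncultured members.
#' @slot truthSpecies the expected canonical binomial.
#' @exportClass Classification
setClass("Classification",
  representation(
    queryId = "character", locus = "character", sourceDb = "character",
    runId = "character", group = "character",
    status = "character", deepestCorrectRank = "character",
    categories = "character", topSimilarity = "numeric",
    lowConfidence = "logical", candidateSpecies = "character",
    truthSpecies = "character"
  ),
  prototype(locus = NA_character_, runId = "default", group = NA_character_,
            deepestCorrectRank = NA_character_, categories = character(),
            topSimilarity = NA_real_, lowConfidence = NA)
)

setValidity("Classification", function(object) {
  msgs <- character()
  if (!object@status %in% CLASSIFICATION_STATUSES)
    msgs <- c(msgs, "unknown status")
  if (identical(object@status, "ambiguous_correct") &&
      length(object@categories) == 0L)
    msgs <- c(msgs, "ambiguous_correct requires at least one ambiguity category")
  if (!identical(object@status, "ambiguous_correct") &&
      length(object@categories) > 0L)
    msgs <- c(msgs, "only ambiguous_correct carries ambiguity categories")
  if (object@status %in% c("reliable_correct", "ambiguous_correct") &&
      !identical(object@deepestCorrectRank, "species"))
    msgs <- c(msgs, "correct statuses imply deepestCorrectRank == species")
  if (length(msgs)) msgs else TRUE
})

#' SpecimenClassification: a multi-locus identification
#'
#' @slot specimenId specimen identifier (shared query id across loci).
#' @slot loci the loci that entered the combination.
#' @slot strategy intersection, union or best_locus.
#' @slot status,deepestCorrectRank,categories as for
#'   \linkS4class{Classification}.
#' @slot candidateSpecies combined candidate identity set.
#' @slot truthSpecies the expected canonical binomial.
#' @exportClass SpecimenClassification
setClass("SpecimenClassification",
  representation(
    specimenId = "character", loci = "character", strategy = "character",
    status = "character", deepestCorrectRank = "character",
    categories = "character", candidateSpecies = "character",
    truthSpecies = "character"
  ),
  prototype(deepestCorrectRank = NA_character_, categories = character())
)

setValidity("SpecimenClassification", function(object) {
  if (length(object@loci) == 0L)
    return("at least one locus must enter the combination")
  if (!object@strategy %in% c("intersection", "union", "best_locus"))
    return("unknown combination strategy")
  if (!object@status %in% CLASSIFICATION_STATUSES)
    return("unknown status")
  TRUE
})

#' SimConfig: scenario parameters for the hit-table simulator
#'
#' Defaults emulate the study conditions the pipeline is meant to score:
#' a moderately sized reference taxonomy, ten retained hits per query,
#' an insect-like mix of full-length (614 +/- 34 bp) and mid-length
#' (340 +/- 65 bp) queries, and reference databases carrying realistic
#' rates of mislabelled, undetermined and uncultured records.
#'
#' @slot seed integer seed driving every random draw.
#' @slot nClasses,nOrdersPerClass,nFamiliesPerOrder,nGeneraPerFamily,nSpeciesPerGenus
#'   shape of the simulated taxonomy.
#' @slot recordsPerSpecies database records per species.
#' @slot mislabelRate probability a record is labelled as a congener.
#' @slot undeterminedRate probability a record is labelled "Genus sp.".
#' @slot unculturedRate probability a record is an uncultured record.
#' @slot missingSpeciesRate probability a species has no database records
#'   at all.
#' @slot similarityMeans,similaritySds mean/sd percent identity at each
#'   taxonomic distance (conspecific, congeneric, confamilial, ordinal,
#'   background); means must be strictly decreasing. An \code{NA} mean
#'   disables that distance class (records at it yield no hit).
#' @slot tieRate probability the runner-up's statistics are copied from
#'   the best hit (a manufactured exact tie).
#' @slot nQueries number of query specimens.
#' @slot maxHits retained hits per query.
#' @slot dbSizeForEvalue effective database size used by the e-value
#'   convention.
#' @slot fullLengthFraction,fullLengthMean,fullLengthSd,midLengthMean,midLengthSd
#'   query length model.
#' @slot synonymRate fraction of species given a synonym alias in the
#'   fixture synonym table.
#' @slot locus,runId labels stamped on generated tables.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer",
    nClasses = "integer", nOrdersPerClass = "integer",
    nFamiliesPerOrder = "integer", nGeneraPerFamily = "integer",
    nSpeciesPerGenus = "integer",
    recordsPerSpecies = "integer",
    mislabelRate = "numeric", undeterminedRate = "numeric",
    unculturedRate = "numeric", missingSpeciesRate = "numeric",
    similarityMeans = "numeric", similaritySds = "numeric",
    tieRate = "numeric", nQueries = "integer", maxHits = "integer",
    dbSizeForEvalue = "numeric",
    fullLengthFraction = "numeric", fullLengthMean = "numeric",
    fullLengthSd = "numeric", midLengthMean = "numeric",
    midLengthSd = "numeric",
    synonymRate = "numeric", locus = "character", runId = "character"
  )
)

SIM_DISTANCES <- c("conspecific", "congeneric", "confamilial",
                   "ordinal", "background")

setValidity("SimConfig", function(object) {
  msgs <- character()
  rates <- c(object@mislabelRate, object@undeterminedRate,
             object@unculturedRate, object@missingSpeciesRate,
             object@tieRate, object@synonymRate)
  if (any(rates < 0) || any(rates > 1))
    msgs <- c(msgs, "all rates must lie in [0, 1]")
  if (object@mislabelRate + object@undeterminedRate +
      object@unculturedRate > 1)
    msgs <- c(msgs, "error rates leave a negative probability of a correct record")
  mu <- object@similarityMeans
  if (length(mu) != 5L || length(object@similaritySds) != 5L)
    msgs <- c(msgs, "similarity model needs five distance classes")
  mu_ok <- mu[!is.na(mu)]
  if (length(mu_ok) > 1L && any(diff(mu_ok) >= 0))
    msgs <- c(msgs, "similarity means must strictly decrease with taxonomic distance")
  if (any(object@similaritySds < 0, na.rm = TRUE))
    msgs <- c(msgs, "similarity sds must be nonnegative")
  counts <- c(object@nClasses, object@nOrdersPerClass,
              object@nFamiliesPerOrder, object@nGeneraPerFamily,
              object@nSpeciesPerGenus, object@recordsPerSpecies,
              object@maxHits)
  if (any(counts < 1L))
    msgs <- c(msgs, "taxonomy shape, recordsPerSpecies and maxHits must be >= 1")
  if (object@nQueries < 0L)
    msgs <- c(msgs, "nQueries must be nonnegative")
  if (length(msgs)) msgs else TRUE
})
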