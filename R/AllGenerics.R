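## Generics and accessors. Slots are never reached into by user code;
## these accessors are the supported surface.

#' @rdname HitTable-class
#' @param x an object.
#' @aliases queryId,HitTable-method hits,HitTable-method
#'   sourceDb,HitTable-method locusName,HitTable-method
#'   runId,HitTable-method queryLength,HitTable-method
#'   nHits,HitTable-method
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))
#' @rdname HitTable-class
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @rdname HitTable-class
#' @export
setGeneric("sourceDb", function(x) standardGeneric("sourceDb"))
#' @rdname HitTable-class
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @rdname HitTable-class
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
#' @rdname HitTable-class
#' @export
setGeneric("queryLength", function(x) standardGeneric("queryLength"))
#' @rdname HitTable-class
#' @export
setGeneric("nHits", function(x) standardGeneric("nHits"))

#' @rdname TopMatchSet-class
#' @param x an object.
#' @aliases members,TopMatchSet-method tieCount,TopMatchSet-method
#'   bestStatistics,TopMatchSet-method queryId,TopMatchSet-method
#'   sourceDb,TopMatchSet-method
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname TopMatchSet-class
#' @export
setGeneric("tieCount", function(x) standardGeneric("tieCount"))
#' @rdname TopMatchSet-class
#' @export
setGeneric("bestStatistics", function(x) standardGeneric("bestStatistics"))

#' @rdname Classification-class
#' @param x an object.
#' @aliases classificationStatus,Classification-method
#'   deepestRank,Classification-method
#'   ambiguityCategories,Classification-method
#'   topSimilarity,Classification-method
#'   candidateSpecies,Classification-method
#'   queryId,Classification-method sourceDb,Classification-method
#'   locusName,Classification-method runId,Classification-method
#'   classificationStatus,SpecimenClassification-method
#'   deepestRank,SpecimenClassification-method
#'   ambiguityCategories,SpecimenClassification-method
#'   candidateSpecies,SpecimenClassification-method
#' @export
setGeneric("classificationStatus",
           function(x) standardGeneric("classificationStatus"))
#' @rdname Classification-class
#' @export
setGeneric("deepestRank", function(x) standardGeneric("deepestRank"))
#' @rdname Classification-class
#' @export
setGeneric("ambiguityCategories",
           function(x) standardGeneric("ambiguityCategories"))
#' @rdname Classification-class
#' @export
setGeneric("topSimilarity", function(x) standardGeneric("topSimilarity"))
#' @rdname Classification-class
#' @export
setGeneric("candidateSpecies", function(x) standardGeneric("candidateSpecies"))

setMethod("queryId", "HitTable", function(x) x@queryId)
setMethod("hits", "HitTable", function(x) x@hits)
setMethod("sourceDb", "HitTable", function(x) x@sourceDb)
setMethod("locusName", "HitTable", function(x) x@locus)
setMethod("runId", "HitTable", function(x) x@runId)
setMethod("queryLength", "HitTable", function(x) x@queryLength)
setMethod("nHits", "HitTable", function(x) nrow(x@hits))

setMethod("queryId", "TopMatchSet", function(x) x@queryId)
setMethod("members", "TopMatchSet", function(x) x@members)
setMethod("tieCount", "TopMatchSet", function(x) x@tieCount)
setMethod("bestStatistics", "TopMatchSet", function(x) x@best)
setMethod("sourceDb", "TopMatchSet", function(x) x@sourceDb)

setMethod("queryId", "Classification", function(x) x@queryId)
setMethod("sourceDb", "Classification", function(x) x@sourceDb)
setMethod("locusName", "Classification", function(x) x@locus)
setMethod("runId", "Classification", function(x) x@runId)
setMethod("classificationStatus", "Classification", function(x) x@status)
setMethod("deepestRank", "Classification", function(x) x@deepestCorrectRank)
setMethod("ambiguityCategories", "Classification", function(x) x@categories)
setMethod("topSimilarity", "Classification", function(x) x@topSimilarity)
setMethod("candidateSpecies", "Classification", function(x) x@candidateSpecies)

setMethod("classificationStatus", "SpecimenClassification",
          function(x) x@status)
setMethod("deepestRank", "SpecimenClassification",
          function(x) x@deepestCorrectRank)
setMethod("ambiguityCategories", "SpecimenClassification",
          function(x) x@categories)
setMethod("candidateSpecies", "SpecimenClassification",
          function(x) x@candidateSpecies)

setMethod("show", "ParsedTaxon", function(object) {
  cat("ParsedTaxon \"", object@rawLabel, "\"\n", sep = "")
  cat("  genus: ", ifelse(nzchar(object@genus), object@genus, "<none>"),
      "  epithet: ",
      ifelse(nzchar(object@speciesEpithet), object@speciesEpithet, "<none>"),
      "\n", sep = "")
  flags <- c("undetermined", "uncultured",
             "qualified")[c(object@isUndetermined, object@isUncultured,
                            object@isQualified)]
  cat("  flags: ", if (length(flags)) paste(flags, collapse = ", ")
      else "none", "\n", sep = "")
})

setMethod("show", "Lineage", function(object) {
  vals <- vapply(BARCODE_RANKS, function(r) lineageRank(object, r), "")
  vals[!nzchar(vals)] <- "?"
  cat("Lineage: ", paste(vals, collapse = " > "), "\n", sep = "")
})

setMethod("show", "HitTable", function(object) {
  cat("HitTable for query '", object@queryId, "' (", object@sourceDb,
      ", locus ", object@locus, ", run ", object@runId, "): ",
      nrow(object@hits), " hit(s)\n", sep = "")
})

setMethod("show", "TopMatchSet", function(object) {
  cat("TopMatchSet for query '", object@queryId, "': tieCount = ",
      object@tieCount, "\n", sep = "")
  if (object@tieCount > 0)
    cat("  labels: ",
        paste(unique(object@members$subject_label), collapse = "; "),
        "\n", sep = "")
})

setMethod("show", "Classification", function(object) {
  cat("Classification '", object@queryId, "' [", object@sourceDb, "/",
      object@locus, "]: ", object@status, sep = "")
  if (!is.na(object@deepestCorrectRank))
    cat(" (deepest correct rank: ", object@deepestCorrectRank, ")",
        sep = "")
  if (length(object@categories))
    cat(" categories: ", paste(object@categories, collapse = ","),
        sep = "")
  cat("\n")
})

setMethod("show", "SpecimenClassification", function(object) {
  cat("SpecimenClassification '", object@specimenId, "' (",
      object@strategy, " over ", paste(object@loci, collapse = "+"),
      "): ", object@status, "\n", sep = "")
})

setMethod("show", "SynonymTable", function(object) {
  cat("SynonymTable with ", length(object@map), " entr",
      ifelse(length(object@map) == 1, "y", "ies"), "\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  n_sp <- object@nClasses * object@nOrdersPerClass *
    object@nFamiliesPerOrder * object@nGeneraPerFamily *
    object@nSpeciesPerGenus
  cat("SimConfig: ", n_sp, " species, ", object@recordsPerSpecies,
      " record(s)/species, ", object@nQueries, " queries (seed ",
      object@seed, ")\n", sep = "")
  cat("  error rates: mislabel ", object@mislabelRate, ", undetermined ",
      object@undeterminedRate, ", uncultured ", object@unculturedRate,
      ", missing species ", object@missingSpeciesRate, ", tie ",
      object@tieRate, "\n", sep = "")
})
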