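## Parsing, normalizing and comparing taxon labels and lineages.
##
## Database taxon labels are messy: undetermined records ("Amanita sp."),
## uncultured environmental records ("uncultured fungus clone A7"),
## open-nomenclature qualifiers ("Aus cf. bus"), subspecific trinomials
## and inconsistent case all occur. Everything downstream (tie
## adjudication, ambiguity categories, rank roll-ups) keys off the
## normalized form produced here.

## Tokens that mark an epithet slot as a placeholder rather than a name.
PLACEHOLDER_EPITHETS <- c("sp", "sp.", "spp", "spp.")
QUALIFIER_TOKENS <- c("cf", "cf.", "aff", "aff.", "nr", "nr.")
UNCULTURED_LEAD_TOKENS <- c("uncultured", "environmental")

## Vectorized label parser; returns a data.frame with one row per label.
## parseTaxonName() wraps single labels into a ParsedTaxon object.
.parseTaxa <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  out <- data.frame(
    raw_label = labels,
    genus = character(n),
    species_epithet = character(n),
    is_undetermined = logical(n),
    is_uncultured = logical(n),
    is_qualified = logical(n),
    canonical_binomial = character(n),
    stringsAsFactors = FALSE
  )
  cleaned <- squish(labels)
  if (any(!nzchar(cleaned)))
    stop("taxon labels must be nonempty after trimming")
  toks <- strsplit(cleaned, " ", fixed = TRUE)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (tolower(tk[1]) %in% UNCULTURED_LEAD_TOKENS) {
      out$is_uncultured[i] <- TRUE
      out$is_undetermined[i] <- TRUE
      ## a capitalized Latin-looking second token is taken as the genus
      if (length(tk) >= 2 && grepl("^[A-Z][a-z-]+$", tk[2]))
        out$genus[i] <- tk[2]
      next
    }
    if (grepl("^[A-Za-z][A-Za-z-]*$", tk[1]))
      out$genus[i] <- capitalizeFirst(tk[1])
    if (length(tk) < 2) {
      out$is_undetermined[i] <- TRUE
      next
    }
    ep <- tolower(tk[2])
    if (ep %in% QUALIFIER_TOKENS) {
      ## "Aus cf. bus": flagged, and conservatively not a determined
      ## species-level identity
      out$is_qualified[i] <- TRUE
      out$is_undetermined[i] <- TRUE
      next
    }
    if (ep %in% PLACEHOLDER_EPITHETS || grepl("[0-9]", ep)) {
      out$is_undetermined[i] <- TRUE
      next
    }
    ep <- gsub("[^a-z-]", "", ep)
    if (!nzchar(ep)) {
      out$is_undetermined[i] <- TRUE
      next
    }
    ## trinomials are truncated to the binomial
    out$species_epithet[i] <- ep
  }
  ok <- nzchar(out$genus) & nzchar(out$species_epithet) &
    !out$is_undetermined
  out$canonical_binomial[ok] <-
    paste(out$genus[ok], out$species_epithet[ok])
  out
}

#' Parse a raw taxon label
#'
#' Normalizes a database taxon label into genus and species components.
#' Undetermined identities (epithets "sp.", "spp.", code-like epithets
#' containing digits, or a missing epithet), uncultured / environmental
#' records, and open-nomenclature qualifiers (cf., aff., nr.) are
#' flagged; a canonical binomial is reported only for determined
#' binomials. Subspecific trinomials are truncated to the binomial and
#' case is normalized (genus capitalized, epithet lowercased).
#'
#' @param rawLabel a single nonempty taxon label.
#' @return a \linkS4class{ParsedTaxon}.
#' @examples
#' parseTaxonName("Amanita sp.")
#' parseTaxonName("Chrysomya megacephala")
#' parseTaxonName("uncultured fungus clone A7")
#' @export
parseTaxonName <- function(rawLabel) {
  if (length(rawLabel) != 1L || is.na(rawLabel) ||
      !nzchar(squish(rawLabel)))
    stop("rawLabel must be a single nonempty string")
  p <- .parseTaxa(rawLabel)
  new("ParsedTaxon",
      rawLabel = p$raw_label, genus = p$genus,
      speciesEpithet = p$species_epithet,
      isUndetermined = p$is_undetermined,
      isUncultured = p$is_uncultured,
      isQualified = p$is_qualified,
      canonicalBinomial = p$canonical_binomial)
}

#' Construct a Lineage
#'
#' @param class_,order,family,genus,species rank values, shallow to
#'   deep; \code{""} means unknown. The species must be a canonical
#'   binomial beginning with the genus.
#' @return a \linkS4class{Lineage}.
#' @examples
#' Lineage(class_ = "Insecta", order = "Diptera",
#'         family = "Calliphoridae", genus = "Chrysomya",
#'         species = "Chrysomya megacephala")
#' @export
Lineage <- function(class_ = "", order = "", family = "", genus = "",
                    species = "") {
  new("Lineage", class_ = squish(class_), order = squish(order),
      family = squish(family), genus = squish(genus),
      species = squish(species))
}

#' Value of a lineage at a rank
#'
#' @param x a \linkS4class{Lineage}.
#' @param rank one of class, order, family, genus, species.
#' @return the (possibly empty) rank value.
#' @export
lineageRank <- function(x, rank) {
  stopifnot(is(x, "Lineage"))
  switch(match.arg(rank, BARCODE_RANKS),
         class = x@class_, order = x@order, family = x@family,
         genus = x@genus, species = x@species)
}

#' Construct a synonym table
#'
#' Species-level synonymy: each alias binomial maps to its accepted
#' canonical binomial. Lookups are case-insensitive; the table must be
#' idempotent (no chains, no cycles).
#'
#' @param alias character vector of alias binomials.
#' @param canonical parallel vector of accepted binomials.
#' @param provenance optional free-text note per entry.
#' @return a \linkS4class{SynonymTable}.
#' @examples
#' syn <- SynonymTable("Chrysomya saffranea", "Chrysomya megacephala")
#' resolveSynonym("chrysomya saffranea", syn)
#' @export
SynonymTable <- function(alias = character(), canonical = character(),
                         provenance = rep("", length(alias))) {
  stopifnot(length(alias) == length(canonical))
  map <- setNames(squish(canonical), tolower(squish(alias)))
  new("SynonymTable", map = map, provenance = as.character(provenance))
}

#' @rdname SynonymTable
#' @export
emptySynonymTable <- function() SynonymTable()

#' Read a synonym table from CSV
#'
#' Expects a header and at least two columns: alias, canonical; a third
#' column, when present, is kept as the provenance note.
#'
#' @param path path to the CSV file.
#' @return a \linkS4class{SynonymTable}.
#' @export
readSynonymTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("synonym CSV needs at least two columns (alias, canonical)")
  prov <- if (ncol(df) >= 3) as.character(df[[3]]) else rep("", nrow(df))
  SynonymTable(df[[1]], df[[2]], prov)
}

#' Resolve a species name through a synonym table
#'
#' Returns the mapped canonical binomial when the name is a known alias,
#' the input unchanged otherwise. Applying the resolution twice equals
#' applying it once.
#'
#' @param name character vector of canonical binomials.
#' @param table a \linkS4class{SynonymTable}.
#' @return character vector of resolved binomials.
#' @export
resolveSynonym <- function(name, table = emptySynonymTable()) {
  stopifnot(is(table, "SynonymTable"))
  name <- squish(as.character(name))
  if (length(table@map) == 0L) return(name)
  hit <- match(tolower(name), names(table@map))
  ifelse(is.na(hit), name, unname(table@map[hit]))
}

#' Compare two lineages at one rank
#'
#' \code{TRUE} iff both lineages carry a value at the rank and the
#' values match after case-folding; at species rank both sides are first
#' resolved through the synonym table. An unknown (empty) value never
#' matches.
#'
#' @param a,b \linkS4class{Lineage} objects.
#' @param rank one of class, order, family, genus, species.
#' @param synonyms a \linkS4class{SynonymTable}.
#' @return logical scalar.
#' @export
sameTaxonAtRank <- function(a, b, rank, synonyms = emptySynonymTable()) {
  stopifnot(is(a, "Lineage"), is(b, "Lineage"))
  if (length(rank) != 1L || !rank %in% BARCODE_RANKS)
    stop("rank must be one of: ", paste(BARCODE_RANKS, collapse = ", "))
  va <- lineageRank(a, rank)
  vb <- lineageRank(b, rank)
  if (identical(rank, "species")) {
    va <- resolveSynonym(va, synonyms)
    vb <- resolveSynonym(vb, synonyms)
  }
  isTRUE(foldEq(va, vb))
}

#' Deepest rank at which an assignment matches the truth
#'
#' Walks species, genus, family, order, class and returns the first
#' (deepest) rank at which \code{\link{sameTaxonAtRank}} holds;
#' \code{NA} when no rank matches.
#'
#' @param truth the expected \linkS4class{Lineage}; species must be
#'   filled.
#' @param assigned the assigned \linkS4class{Lineage}.
#' @param synonyms a \linkS4class{SynonymTable}.
#' @return a rank name or \code{NA_character_}.
#' @export
deepestCorrectRank <- function(truth, assigned,
                               synonyms = emptySynonymTable()) {
  stopifnot(is(truth, "Lineage"))
  if (!nzchar(truth@species))
    stop("truth lineage must have species filled")
  for (rank in rev(BARCODE_RANKS)) {
    if (sameTaxonAtRank(truth, assigned, rank, synonyms))
      return(rank)
  }
  NA_character_
}
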