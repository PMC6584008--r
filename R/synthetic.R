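## Seeded simulator for reference databases and hit tables. The
## generator emulates the error sources a public barcode repository is
## known to carry — records mislabelled as a congener, undetermined
## ("Genus sp.") and uncultured environmental records, species absent
## from the database altogether — plus the statistical structure the
## adjudicator keys on: percent identity falling with taxonomic
## distance, and exact ties among top records. The e-value / bit-score
## formulas are generator conventions shaped like the Karlin-Altschul
## statistics for realism; they are not claims about BLAST internals.

#' Construct a simulation scenario
#'
#' See \linkS4class{SimConfig} for the meaning of every parameter.
#' Defaults describe the study conditions the package is built to
#' score: a 288-species taxonomy, 5 records per species, 10 retained
#' hits, 70\% full-length (614 +/- 34 bp) and 30\% mid-length
#' (340 +/- 65 bp) queries, and error rates in the range reported for
#' public barcode repositories.
#'
#' @param seed integer seed.
#' @param nClasses,nOrdersPerClass,nFamiliesPerOrder,nGeneraPerFamily,nSpeciesPerGenus
#'   taxonomy shape.
#' @param recordsPerSpecies records per species.
#' @param mislabelRate,undeterminedRate,unculturedRate,missingSpeciesRate,tieRate
#'   error and tie rates in \code{[0, 1]}.
#' @param similarityMeans,similaritySds percent-identity model per
#'   taxonomic distance (conspecific, congeneric, confamilial, ordinal,
#'   background).
#' @param nQueries,maxHits,dbSizeForEvalue see \linkS4class{SimConfig}.
#' @param fullLengthFraction,fullLengthMean,fullLengthSd,midLengthMean,midLengthSd
#'   query length model in bases.
#' @param synonymRate fraction of species aliased in the fixture
#'   synonym table.
#' @param locus,runId labels stamped on generated tables.
#' @return a \linkS4class{SimConfig}.
#' @export
SimConfig <- function(seed = 1L,
                      nClasses = 3L, nOrdersPerClass = 2L,
                      nFamiliesPerOrder = 2L, nGeneraPerFamily = 3L,
                      nSpeciesPerGenus = 4L,
                      recordsPerSpecies = 5L,
                      mislabelRate = 0.10, undeterminedRate = 0.10,
                      unculturedRate = 0.05, missingSpeciesRate = 0.05,
                      similarityMeans = c(conspecific = 99.5,
                                          congeneric = 96,
                                          confamilial = 92,
                                          ordinal = 88,
                                          background = 80),
                      similaritySds = c(conspecific = 0.4,
                                        congeneric = 1.5,
                                        confamilial = 2,
                                        ordinal = 3,
                                        background = 5),
                      tieRate = 0.10, nQueries = 50L, maxHits = 10L,
                      dbSizeForEvalue = 1e12,
                      fullLengthFraction = 0.7, fullLengthMean = 614,
                      fullLengthSd = 34, midLengthMean = 340,
                      midLengthSd = 65,
                      synonymRate = 0.05, locus = "COI",
                      runId = "default") {
  new("SimConfig", seed = as.integer(seed),
      nClasses = as.integer(nClasses),
      nOrdersPerClass = as.integer(nOrdersPerClass),
      nFamiliesPerOrder = as.integer(nFamiliesPerOrder),
      nGeneraPerFamily = as.integer(nGeneraPerFamily),
      nSpeciesPerGenus = as.integer(nSpeciesPerGenus),
      recordsPerSpecies = as.integer(recordsPerSpecies),
      mislabelRate = mislabelRate, undeterminedRate = undeterminedRate,
      unculturedRate = unculturedRate,
      missingSpeciesRate = missingSpeciesRate,
      similarityMeans = unname(similarityMeans)[1:5],
      similaritySds = unname(similaritySds)[1:5],
      tieRate = tieRate, nQueries = as.integer(nQueries),
      maxHits = as.integer(maxHits),
      dbSizeForEvalue = dbSizeForEvalue,
      fullLengthFraction = fullLengthFraction,
      fullLengthMean = fullLengthMean, fullLengthSd = fullLengthSd,
      midLengthMean = midLengthMean, midLengthSd = midLengthSd,
      synonymRate = synonymRate, locus = locus, runId = runId)
}

## Pronounceable deterministic names: an index is written in base 14
## syllables, so every taxon gets a unique, purely alphabetic name
## (taxon labels containing digits would parse as code-like epithets).
.SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po",
                "ru", "sa", "te", "vi", "xo")

.latinRoot <- function(i, nsyl = 3L) {
  base <- length(.SYLLABLES)
  digits <- integer(nsyl)
  i <- i - 1L
  for (k in nsyl:1) {
    digits[k] <- i %% base
    i <- i %/% base
  }
  paste(.SYLLABLES[digits + 1L], collapse = "")
}

.simTaxonomy <- function(config) {
  grid <- expand.grid(
    sp = seq_len(config@nSpeciesPerGenus),
    gen = seq_len(config@nGeneraPerFamily),
    fam = seq_len(config@nFamiliesPerOrder),
    ord = seq_len(config@nOrdersPerClass),
    cls = seq_len(config@nClasses)
  )
  cls_id <- grid$cls
  ord_id <- (cls_id - 1) * config@nOrdersPerClass + grid$ord
  fam_id <- (ord_id - 1) * config@nFamiliesPerOrder + grid$fam
  gen_id <- (fam_id - 1) * config@nGeneraPerFamily + grid$gen
  sp_id <- seq_len(nrow(grid))
  genus <- capitalizeFirst(vapply(gen_id, .latinRoot, ""))
  epithet <- vapply(sp_id, function(i) paste0(.latinRoot(i), "ns"), "")
  data.frame(
    class = paste0(capitalizeFirst(vapply(cls_id, .latinRoot, "")), "ia"),
    order = paste0(capitalizeFirst(vapply(ord_id, .latinRoot, "")),
                   "iformes"),
    family = paste0(capitalizeFirst(vapply(fam_id, .latinRoot, "")),
                    "idae"),
    genus = genus,
    species = paste(genus, epithet),
    stringsAsFactors = FALSE
  )
}

## Swap a species to a uniformly chosen congener; genera with a single
## species fall back to a confamilial (then ordinal) swap.
.swapTarget <- function(idx, taxonomy) {
  for (rank in c("genus", "family", "order")) {
    pool <- which(taxonomy[[rank]] == taxonomy[[rank]][idx])
    pool <- setdiff(pool, idx)
    if (length(pool))
      return(pool[sample.int(length(pool), 1L)])
  }
  idx
}

.simReferenceDb <- function(config, taxonomy) {
  n_sp <- nrow(taxonomy)
  present <- runif(n_sp) >= config@missingSpeciesRate
  sp_idx <- rep(which(present), each = config@recordsPerSpecies)
  n_rec <- length(sp_idx)
  if (n_rec == 0L) {
    rec <- taxonomy[0, ]
    rec$record_id <- character()
    rec$label <- character()
    rec$error_type <- character()
    return(rec)
  }
  p_err <- c(config@mislabelRate, config@undeterminedRate,
             config@unculturedRate)
  type <- apply(stats::rmultinom(n_rec, 1L,
                                 c(p_err, 1 - sum(p_err))), 2,
                which.max)
  error_type <- c("mislabel", "undetermined", "uncultured",
                  "correct")[type]
  label <- taxonomy$species[sp_idx]
  label_idx <- sp_idx
  mis <- which(error_type == "mislabel")
  for (i in mis)
    label_idx[i] <- .swapTarget(sp_idx[i], taxonomy)
  label[mis] <- taxonomy$species[label_idx[mis]]
  und <- error_type == "undetermined"
  label[und] <- paste(taxonomy$genus[sp_idx[und]], "sp.")
  unc <- error_type == "uncultured"
  label[unc] <- paste("uncultured", taxonomy$genus[sp_idx[unc]])
  rec <- taxonomy[sp_idx, ]
  rec$record_id <- sprintf("REC%05d", seq_len(n_rec))
  rec$label <- label
  ## reported (label-side) higher taxonomy follows the labelled species
  rec$label_class <- taxonomy$class[label_idx]
  rec$label_order <- taxonomy$order[label_idx]
  rec$label_family <- taxonomy$family[label_idx]
  rec$error_type <- error_type
  rownames(rec) <- NULL
  rec
}

#' Simulate a reference database
#'
#' Builds the taxonomy defined by the config and, for every species not
#' dropped by \code{missingSpeciesRate}, \code{recordsPerSpecies}
#' database records; each record is independently mislabelled as a
#' congener (confamilial fallback for monotypic genera), relabelled
#' "Genus sp." (undetermined) or turned into an uncultured record at
#' the configured rates. Deterministic under the config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{taxonomy} (one row per species) and
#'   \code{records} (the database: true lineage, reported label and
#'   error type per record).
#' @export
simulateReferenceDb <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  taxonomy <- .simTaxonomy(config)
  list(taxonomy = taxonomy,
       records = .simReferenceDb(config, taxonomy))
}

.simQueries <- function(config, taxonomy) {
  n <- config@nQueries
  if (n == 0L)
    return(data.frame(specimen_id = character(), class = character(),
                      order = character(), family = character(),
                      genus = character(), species = character(),
                      query_length = integer(),
                      stringsAsFactors = FALSE))
  idx <- sample.int(nrow(taxonomy), n, replace = TRUE)
  full <- runif(n) < config@fullLengthFraction
  len <- ifelse(full,
                rnorm(n, config@fullLengthMean, config@fullLengthSd),
                rnorm(n, config@midLengthMean, config@midLengthSd))
  len <- pmax(100L, as.integer(round(len)))
  data.frame(specimen_id = sprintf("SP%04d", seq_len(n)),
             taxonomy[idx, ], query_length = len,
             stringsAsFactors = FALSE, row.names = NULL)
}

.recordDistance <- function(query, records) {
  d <- rep(5L, nrow(records))  # background
  d[records$order == query$order] <- 4L
  d[records$family == query$family] <- 3L
  d[records$genus == query$genus] <- 2L
  d[records$species == query$species] <- 1L
  d
}

## Generator convention for GenBank-style statistics: a raw match /
## mismatch score with MegaBlast reward/penalty (1, -2), a
## Karlin-Altschul-shaped bit score with constants lambda = 1.28,
## K = 0.46, and evalue = dbSize * L * 2^-bitscore.
.gbStatistics <- function(pident, L, dbSize) {
  m <- round(L * pident / 100)
  s <- m - 2 * (L - m)
  bitscore <- (1.28 * s - log(0.46)) / log(2)
  list(bitscore = bitscore, evalue = dbSize * L * 2^(-bitscore))
}

#' Simulate one hit table
#'
#' Scores every database record against a query by drawing a percent
#' identity from the taxonomic-distance model (truncated to
#' \code{[50, 100]}), keeps the top \code{maxHits} records under the
#' tie policy's key order, and with probability \code{tieRate} copies
#' the best record's statistics onto the runner-up (a manufactured
#' exact tie). GenBank-dialect tables get bit scores and e-values from
#' the generator's scoring convention; BOLD-dialect tables carry the
#' similarity percentage. Draws come from the current RNG state — seed
#' it (or use \code{\link{generateStudyFixture}}) for reproducibility.
#'
#' @param query one row of the query truth table (fields class, order,
#'   family, genus, species, specimen_id, query_length).
#' @param records the reference database
#'   (\code{\link{simulateReferenceDb}}\code{$records}).
#' @param config a \linkS4class{SimConfig}.
#' @param dialect "genbank" or "bold".
#' @return a \linkS4class{HitTable} (possibly empty when no record is
#'   scoreable — the valid no-match fixture).
#' @export
simulateHitTable <- function(query, records, config,
                             dialect = c("genbank", "bold")) {
  dialect <- match.arg(dialect)
  d <- .recordDistance(query, records)
  mu <- config@similarityMeans[d]
  sdv <- config@similaritySds[d]
  keep <- !is.na(mu)
  empty <- data.frame(subject_id = character(),
                      subject_label = character())
  if (!any(keep))
    return(HitTable(query$specimen_id, empty, sourceDb = dialect,
                    locus = config@locus, runId = config@runId,
                    queryLength = query$query_length))
  p <- pmin(100, pmax(50, rnorm(sum(keep), mu[keep], sdv[keep])))
  rec <- records[keep, , drop = FALSE]
  ord <- order(-p)
  take <- utils::head(ord, config@maxHits)
  p <- p[take]
  rec <- rec[take, , drop = FALSE]
  if (length(p) >= 2L && runif(1) < config@tieRate)
    p[2] <- p[1]
  L <- query$query_length
  h <- data.frame(subject_id = rec$record_id,
                  subject_label = rec$label,
                  class = rec$label_class, order = rec$label_order,
                  family = rec$label_family,
                  stringsAsFactors = FALSE)
  if (dialect == "genbank") {
    gb <- .gbStatistics(p, L, config@dbSizeForEvalue)
    h$pident <- p
    h$length <- L
    h$evalue <- gb$evalue
    h$bitscore <- gb$bitscore
  } else {
    h$similarity <- p
  }
  HitTable(query$specimen_id, h, sourceDb = dialect,
           locus = config@locus, runId = config@runId,
           queryLength = L)
}

.randomSequences <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), "")
}

.configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

#' Generate a complete study fixture on disk
#'
#' Runs the full simulation under the config seed and writes a file
#' bundle that loads through the readers with no special-casing:
#' \preformatted{
#'   <outDir>/queries.fasta          random sequences, recorded lengths
#'   <outDir>/genbank/<locus>_<run>.tsv   BLAST outfmt-6 (13 columns)
#'   <outDir>/bold/<locus>_<run>.csv      BOLD-dialect export
#'   <outDir>/truth.tsv              expected lineage per specimen
#'   <outDir>/synonyms.csv           alias -> canonical table
#'   <outDir>/config.yaml            the scenario that produced it
#' }
#' A fraction \code{synonymRate} of species receive a synonym alias;
#' correct database records of an aliased species are written under the
#' alias, so the bundle also exercises synonym resolution.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outDir output directory.
#' @param overwrite overwrite an existing non-empty directory.
#' @return named list of the paths written, invisibly.
#' @export
generateStudyFixture <- function(config, outDir, overwrite = FALSE) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
    stop("output directory exists and is not empty: ", outDir)
  dir.create(file.path(outDir, "genbank"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "bold"), showWarnings = FALSE)
  set.seed(config@seed)
  taxonomy <- .simTaxonomy(config)
  records <- .simReferenceDb(config, taxonomy)
  queries <- .simQueries(config, taxonomy)

  ## synonym aliases: "<genus> <epithet>i" -> canonical; correct
  ## records of aliased species are stored under the alias
  n_alias <- floor(config@synonymRate * nrow(taxonomy))
  alias_idx <- if (n_alias > 0)
    sample.int(nrow(taxonomy), n_alias) else integer()
  alias <- paste0(taxonomy$species[alias_idx], "i")
  names(alias) <- taxonomy$species[alias_idx]
  if (length(alias)) {
    swap <- records$error_type == "correct" &
      records$species %in% names(alias)
    records$label[swap] <- alias[records$species[swap]]
  }

  gb_tables <- vector("list", nrow(queries))
  bold_tables <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    gb_tables[[i]] <- simulateHitTable(q, records, config, "genbank")
    bold_tables[[i]] <- simulateHitTable(q, records, config, "bold")
  }

  paths <- list(
    queries = file.path(outDir, "queries.fasta"),
    genbank = file.path(outDir, "genbank",
                        paste0(config@locus, "_", config@runId, ".tsv")),
    bold = file.path(outDir, "bold",
                     paste0(config@locus, "_", config@runId, ".csv")),
    truth = file.path(outDir, "truth.tsv"),
    synonyms = file.path(outDir, "synonyms.csv"),
    config = file.path(outDir, "config.yaml")
  )

  fa <- character(0)
  if (nrow(queries))
    fa <- paste0(">", queries$specimen_id, "\n",
                 .randomSequences(queries$query_length))
  writeLines(fa, paths$queries)

  gb_lines <- unlist(lapply(gb_tables, function(tb) {
    h <- hits(tb)
    if (nrow(h) == 0L) return(character())
    m <- round(h$length * h$pident / 100)
    paste(queryId(tb), h$subject_id, formatC(h$pident, digits = 10,
                                             format = "g"),
          h$length, h$length - m, 0, 1, h$length, 1, h$length,
          formatC(h$evalue, digits = 10, format = "g"),
          formatC(h$bitscore, digits = 10, format = "g"),
          h$subject_label, sep = "\t")
  }))
  writeLines(as.character(gb_lines), paths$genbank)

  bold_rows <- do.call(rbind, lapply(bold_tables, function(tb) {
    h <- hits(tb)
    if (nrow(h) == 0L) return(NULL)
    parsed <- .parseTaxa(h$subject_label)
    data.frame(query_id = queryId(tb), subject_id = h$subject_id,
               class = h$class, order = h$order, family = h$family,
               genus = parsed$genus, species = h$subject_label,
               similarity = h$similarity, stringsAsFactors = FALSE)
  }))
  if (is.null(bold_rows))
    bold_rows <- data.frame(query_id = character(),
                            subject_id = character(),
                            class = character(), order = character(),
                            family = character(), genus = character(),
                            species = character(),
                            similarity = numeric())
  utils::write.csv(bold_rows, paths$bold, row.names = FALSE)

  truth <- data.frame(specimen_id = queries$specimen_id,
                      locus = rep(config@locus, nrow(queries)),
                      class = queries$class, order = queries$order,
                      family = queries$family, genus = queries$genus,
                      species = queries$species,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  syn_df <- data.frame(alias = unname(alias),
                       canonical = names(alias),
                       provenance = rep("simulated alias",
                                        length(alias)),
                       stringsAsFactors = FALSE)
  utils::write.csv(syn_df, paths$synonyms, row.names = FALSE)

  yaml::write_yaml(.configAsList(config), paths$config)
  invisible(paths)
}
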