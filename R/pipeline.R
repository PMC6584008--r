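## Pipeline commands: adjudicate, combine, summarize, simulate. Each
## command takes a run config (a YAML file or an equivalent named
## list), writes plain-text outputs under the configured output
## directory, and logs the "n =" bookkeeping at every stage so counts
## stay auditable. A thin command-line dispatcher over these functions
## ships in inst/scripts/barcode-adjudicate.

#' Read a run config
#'
#' @param config a YAML file path or a named list; returned as a list.
#' @return the config list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stopUsage("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stopUsage("config must be a YAML file or a named list")
  config
}

.tiePolicyFromConfig <- function(config) {
  tp <- config$tie_policy %||% list()
  TiePolicy(evalueRtol = tp$evalue_rtol %||% 1e-9,
            percentTol = tp$percent_tol %||% 0.005,
            bitscoreTol = tp$bitscore_tol %||% 0.005)
}

.readInputTables <- function(input, maxHits) {
  dialect <- input$dialect %||% "blast"
  locus <- input$locus %||% NA_character_
  run <- input$run_id %||% "default"
  grp <- input$group %||% NA_character_
  switch(dialect,
    blast = readBlastTabular(input$path, maxHits = maxHits,
                             locus = locus, runId = run, group = grp),
    bold = {
      map <- do.call(boldColumnMap, input$column_map %||% list())
      readBoldResults(input$path, maxHits = maxHits, columnMap = map,
                      locus = locus, runId = run, group = grp)
    },
    hits_tsv = readHitTables(input$path),
    archived = readArchivedOutputs(input$path, input$dialect_config,
                                   maxHits = maxHits),
    stopUsage("unknown input dialect: ", dialect)
  )
}

#' Read a truth table
#'
#' TSV with columns specimen_id, locus, class, order, family, genus,
#' species.
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
readTruthTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "species")
  bad <- setdiff(needed, names(df))
  if (length(bad))
    stop("truth table is missing column(s): ",
         paste(bad, collapse = ", "))
  for (col in c("locus", "class", "order", "family", "genus")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

.truthLineage <- function(row) {
  Lineage(class_ = row$class %||% "", order = row$order %||% "",
          family = row$family %||% "", genus = row$genus %||% "",
          species = row$species)
}

## Locate the truth row for a hit table: specimen id must match, locus
## must match when both sides declare one.
.matchTruth <- function(truth, qid, locus) {
  idx <- which(truth$specimen_id == qid)
  if (length(idx) > 1 && !is.na(locus) && any(nzchar(truth$locus[idx])))
    idx <- idx[truth$locus[idx] == locus | !nzchar(truth$locus[idx])]
  if (length(idx) == 0L) return(NA_integer_)
  idx[1]
}

#' Write / read a classification table
#'
#' @param df the classification table.
#' @param path file path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
writeClassifications <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeClassifications
#' @export
readClassifications <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  for (col in c("query_id", "locus", "source_db", "run_id", "group",
                "status", "deepest_correct_rank", "categories",
                "candidate_species", "truth_species"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  df
}

#' Adjudicate hit tables against a truth table
#'
#' Reads every configured hit-table input, adjudicates each query's
#' top-match set and classifies it against the expected lineage, then
#' writes the per-query classification table to
#' \code{<out_dir>/classifications.tsv}. Queries without a truth entry
#' are skipped with a warning and their count reported.
#'
#' @param config run config (path or list) with at least \code{inputs}
#'   (list of \code{path}/\code{dialect}/labels entries) and
#'   \code{truth}; optional \code{synonyms},
#'   \code{confidence_threshold}, \code{max_hits}, \code{tie_policy},
#'   \code{out_dir}.
#' @return invisibly, a list with \code{classifications} (data.frame),
#'   \code{skipped} (query ids without truth) and \code{path}.
#' @export
cmdAdjudicate <- function(config) {
  config <- readRunConfig(config)
  if (is.null(config$inputs) || length(config$inputs) == 0L)
    stopUsage("config must list at least one hit-table input")
  if (is.null(config$truth))
    stopUsage("config must name a truth table")
  truth <- readTruthTable(config$truth)
  synonyms <- if (!is.null(config$synonyms) &&
                  file.exists(config$synonyms))
    readSynonymTable(config$synonyms) else emptySynonymTable()
  policy <- .tiePolicyFromConfig(config)
  threshold <- config$confidence_threshold %||% 96
  maxHits <- config$max_hits %||% 10
  tables <- unlist(lapply(config$inputs, .readInputTables,
                          maxHits = maxHits), recursive = FALSE)
  message("adjudicate: ", length(tables), " hit table(s) read")
  skipped <- character()
  classifications <- list()
  for (tb in tables) {
    idx <- .matchTruth(truth, queryId(tb), locusName(tb))
    if (is.na(idx)) {
      skipped <- c(skipped, queryId(tb))
      next
    }
    cl <- classifyHitTable(tb, .truthLineage(truth[idx, ]),
                           synonyms = synonyms, policy = policy,
                           confidenceThreshold = threshold)
    classifications <- c(classifications, cl)
  }
  if (length(skipped))
    warning(length(skipped), " quer(ies) skipped without a truth ",
            "entry: ", paste(unique(skipped), collapse = ", "))
  df <- classificationTable(classifications)
  counts <- table(factor(df$status, levels = CLASSIFICATION_STATUSES))
  message("adjudicate: ",
          paste(names(counts), counts, sep = " = ", collapse = ", "))
  outDir <- config$out_dir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outDir, "classifications.tsv")
  writeClassifications(df, path)
  invisible(list(classifications = df, skipped = skipped, path = path))
}

.classificationFromRow <- function(row) {
  splitField <- function(x)
    if (is.na(x) || !nzchar(x)) character()
    else strsplit(x, ";", fixed = TRUE)[[1]]
  new("Classification", queryId = row$query_id,
      locus = if (is.na(row$locus)) NA_character_ else row$locus,
      sourceDb = row$source_db, runId = row$run_id,
      group = if (is.na(row$group)) NA_character_ else row$group,
      status = row$status,
      deepestCorrectRank = if (is.na(row$deepest_correct_rank))
        NA_character_ else row$deepest_correct_rank,
      categories = splitField(row$categories),
      topSimilarity = row$top_similarity,
      lowConfidence = row$low_confidence,
      candidateSpecies = splitField(row$candidate_species),
      truthSpecies = row$truth_species)
}

#' Combine per-locus classifications into specimen-level results
#'
#' Reads the per-query classification table, groups it by specimen
#' (query id) within each source database and run, combines the loci
#' under the configured strategy and writes
#' \code{<out_dir>/specimen_classifications.tsv}. Specimens whose every
#' locus returned no match get a no_match row and a warning.
#'
#' @param config run config with \code{classifications} (path;
#'   defaults to \code{<out_dir>/classifications.tsv}), optional
#'   \code{strategy} and \code{loci_priority}.
#' @return invisibly, a list with \code{specimens} (data.frame) and
#'   \code{path}.
#' @export
cmdCombine <- function(config) {
  config <- readRunConfig(config)
  outDir <- config$out_dir %||% "."
  clPath <- config$classifications %||%
    file.path(outDir, "classifications.tsv")
  if (!file.exists(clPath))
    stopUsage("classification table not found: ", clPath)
  df <- readClassifications(clPath)
  if (nrow(df) == 0L) stop("classification table is empty")
  strategy <- config$strategy %||% "intersection"
  priority <- unlist(config$loci_priority) %||% DEFAULT_LOCUS_PRIORITY
  key <- paste(df$query_id, df$source_db, df$run_id, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    cls <- lapply(seq_len(nrow(sub)), function(i)
      .classificationFromRow(sub[i, ]))
    sc <- tryCatch(
      combineLoci(cls, strategy = strategy, lociPriority = priority),
      error = function(e) {
        warning("specimen '", sub$query_id[1],
                "': all loci returned no match")
        new("SpecimenClassification", specimenId = sub$query_id[1],
            loci = sub$locus, strategy = strategy, status = "no_match",
            candidateSpecies = character(),
            truthSpecies = sub$truth_species[1])
      })
    out <- specimenClassificationTable(list(sc))
    out$source_db <- sub$source_db[1]
    out$run_id <- sub$run_id[1]
    out$group <- sub$group[1]
    out
  })
  out <- do.call(rbind, rows)
  message("combine: ", nrow(out), " specimen(s), strategy = ", strategy)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outDir, "specimen_classifications.tsv")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(list(specimens = out, path = path))
}

#' Summarise classifications
#'
#' Writes the accuracy table, ambiguity summary, similarity summaries
#' and (when several runs are present) the run comparison, as TSV files
#' plus a JSON report, under the configured output directory.
#'
#' @param config run config with \code{classifications} (path) and
#'   optional \code{group_keys}.
#' @return invisibly, the report list.
#' @export
cmdSummarize <- function(config) {
  config <- readRunConfig(config)
  outDir <- config$out_dir %||% "."
  clPath <- config$classifications %||%
    file.path(outDir, "classifications.tsv")
  if (!file.exists(clPath))
    stopUsage("classification table not found: ", clPath)
  df <- readClassifications(clPath)
  if (nrow(df) == 0L) stop("classification table is empty")
  groupKeys <- unlist(config$group_keys) %||% c("source_db", "locus")
  acc <- accuracyTable(df, groupKeys = groupKeys)
  amb <- ambiguitySummary(df, groupKeys = groupKeys)
  sim_all <- similaritySummary(df)
  sim_mis <- tryCatch(similaritySummary(df, "misidentified"),
                      error = function(e) NULL)
  runcmp <- if (length(unique(df$run_id)) >= 2)
    compareRuns(df) else NULL
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(acc, file.path(outDir, "accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(amb$perGroup, file.path(outDir, "ambiguity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    n = nrow(df),
    accuracy = acc,
    ambiguity = list(perGroup = amb$perGroup, mean = amb$mean,
                     sd = amb$sd),
    similarity = list(all = sim_all, misidentified = sim_mis),
    run_comparison = if (!is.null(runcmp))
      list(accuracy = runcmp$accuracy, agreement = runcmp$agreement,
           test = runcmp$test,
           changed_queries = runcmp$changedQueries)
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  message("summarize: ", nrow(df), " classification(s) summarised")
  invisible(report)
}

#' Simulate a study fixture from a run config
#'
#' @param config run config with a \code{sim} block of
#'   \code{\link{SimConfig}} fields (snake_case or the slot names) and
#'   an \code{out_dir}; \code{seed} at the top level overrides the sim
#'   seed.
#' @return invisibly, the list of paths written.
#' @export
cmdSimulate <- function(config) {
  config <- readRunConfig(config)
  sim <- config$sim %||% list()
  names(sim) <- gsub("_(\\w)", "\\U\\1", names(sim), perl = TRUE)
  known <- names(formals(SimConfig))
  sim <- sim[intersect(names(sim), known)]
  if (!is.null(config$seed)) sim$seed <- config$seed
  simConfig <- do.call(SimConfig, sim)
  outDir <- config$out_dir %||% stopUsage("simulate needs an out_dir")
  paths <- generateStudyFixture(simConfig, outDir,
                                overwrite = isTRUE(config$overwrite))
  message("simulate: fixture written under ", outDir)
  invisible(paths)
}
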