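## Readers and writers for search outputs: BLAST tabular (outfmt 6),
## BOLD identification-engine exports, query FASTA, and the package's
## canonical hit-table TSV. All readers funnel into the same HitTable
## model so adjudication never needs to know where a table came from.

BLAST_OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length",
                        "mismatch", "gapopen", "qstart", "qend",
                        "sstart", "send", "evalue", "bitscore")

## Optional per-hit rank columns carried through from BOLD exports (and
## archived workbooks) so roll-ups can use ranks above genus.
HIT_EXTRA_RANKS <- c("class", "order", "family")

#' Construct a HitTable
#'
#' @param queryId query identifier.
#' @param hits data.frame with columns subject_id, subject_label,
#'   pident, length, evalue, bitscore, similarity (missing statistic
#'   columns are added as \code{NA}).
#' @param sourceDb "genbank" or "bold".
#' @param locus barcode locus label.
#' @param runId search parameter set / sequence subset label.
#' @param group taxonomic group label, or \code{NA}.
#' @param queryLength query length in bases, or \code{NA}.
#' @return a \linkS4class{HitTable}.
#' @export
HitTable <- function(queryId, hits, sourceDb = c("genbank", "bold"),
                     locus = NA_character_, runId = "default",
                     group = NA_character_, queryLength = NA_integer_) {
  sourceDb <- match.arg(sourceDb)
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  for (col in HIT_COLUMNS) {
    if (!col %in% names(hits)) {
      fill <- if (col %in% c("subject_id", "subject_label"))
        NA_character_ else NA_real_
      hits[[col]] <- rep(fill, nrow(hits))
    }
  }
  keep <- c(HIT_COLUMNS, intersect(HIT_EXTRA_RANKS, names(hits)))
  hits <- hits[, keep, drop = FALSE]
  rownames(hits) <- NULL
  new("HitTable", queryId = as.character(queryId), hits = hits,
      sourceDb = sourceDb, locus = as.character(locus),
      runId = as.character(runId), group = as.character(group),
      queryLength = as.integer(queryLength))
}

## Shared grouping step: one HitTable per distinct query id, first-seen
## order preserved, truncated to maxHits.
.makeHitTables <- function(df, sourceDb, locus, runId, group, maxHits,
                           queryLengths = NULL) {
  if (nrow(df) == 0L) return(list())
  ids <- unique(df$query_id)
  lapply(ids, function(qid) {
    h <- df[df$query_id == qid, , drop = FALSE]
    h <- utils::head(h, maxHits)
    h$query_id <- NULL
    qlen <- NA_integer_
    if (!is.null(queryLengths) && qid %in% names(queryLengths))
      qlen <- as.integer(queryLengths[[qid]])
    HitTable(qid, h, sourceDb = sourceDb, locus = locus, runId = runId,
             group = group, queryLength = qlen)
  })
}

.parseNumericCol <- function(x, col, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & nzchar(x)
  if (any(bad))
    stop("non-numeric value in column '", col, "' on line ",
         lines[which(bad)[1]], ": '", x[which(bad)[1]], "'")
  out
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the 12 standard tab-separated columns (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' plus an optional 13th subject-scientific-name column. E-values in
#' scientific notation (and "0.0") are parsed; alignment coordinates are
#' carried through untouched (1-based inclusive, never interpreted).
#' One \linkS4class{HitTable} is produced per distinct query, in file
#' order, truncated to \code{maxHits} records.
#'
#' @param path path to the tabular file.
#' @param maxHits records retained per query (default 10, the MegaBlast
#'   default for the maximum number of aligned sequences written out).
#' @param locus,runId,group labels stamped on the resulting tables.
#' @param labelParser optional function applied to the subject id to
#'   recover a taxon label when no 13th column is present; by default
#'   the subject id itself is used as the label.
#' @return list of \linkS4class{HitTable}.
#' @export
readBlastTabular <- function(path, maxHits = 10, locus = NA_character_,
                             runId = "default", group = NA_character_,
                             labelParser = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad))
    stop("expected 12 or 13 tab-separated columns but found ", nf[bad[1]],
         " on line ", bad[1])
  has13 <- nf == 13L
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- BLAST_OUTFMT6_COLS
  lineno <- seq_along(lines)
  for (col in c("pident", "length", "mismatch", "gapopen", "qstart",
                "qend", "sstart", "send", "evalue", "bitscore"))
    df[[col]] <- .parseNumericCol(df[[col]], col, lineno)
  label <- ifelse(has13, vapply(fields, function(f) f[length(f)], ""),
                  NA_character_)
  if (any(!has13)) {
    fallback <- if (is.null(labelParser)) df$sseqid[!has13]
      else vapply(df$sseqid[!has13], labelParser, "")
    label[!has13] <- fallback
  }
  out <- data.frame(
    query_id = df$qseqid, subject_id = df$sseqid, subject_label = label,
    pident = df$pident, length = df$length, evalue = df$evalue,
    bitscore = df$bitscore, similarity = NA_real_,
    stringsAsFactors = FALSE
  )
  .makeHitTables(out, "genbank", locus, runId, group, maxHits)
}

#' Default column map for BOLD identification-engine exports
#'
#' Maps canonical field names to the column headers of the export.
#' \code{query_id}, \code{genus}, \code{species} and \code{similarity}
#' are required; \code{subject_id}, \code{class}, \code{order} and
#' \code{family} are used when present. Header matching is
#' case-insensitive.
#'
#' @param ... overrides, e.g. \code{similarity = "Similarity (\%)"}.
#' @return named list.
#' @export
boldColumnMap <- function(...) {
  map <- list(query_id = "query_id", subject_id = "subject_id",
              class = "class", order = "order", family = "family",
              genus = "genus", species = "species",
              similarity = "similarity")
  utils::modifyList(map, list(...))
}

#' Read BOLD identification-engine results
#'
#' Reads a delimited BOLD export carrying per-hit taxonomic rank columns
#' and a similarity percentage, through a configurable column map. The
#' subject label is assembled from the genus and species columns (genus
#' alone when the species column is empty, parsed as an undetermined
#' identity downstream); similarity is populated and e-value / bit
#' score left empty.
#'
#' @param path path to the CSV/TSV export.
#' @param maxHits records retained per query.
#' @param columnMap a \code{\link{boldColumnMap}}.
#' @param sep field separator; guessed from the file extension when
#'   \code{NULL} (".csv" = comma, otherwise tab).
#' @param locus,runId,group labels stamped on the resulting tables.
#' @return list of \linkS4class{HitTable}.
#' @export
readBoldResults <- function(path, maxHits = 10,
                            columnMap = boldColumnMap(), sep = NULL,
                            locus = NA_character_, runId = "default",
                            group = NA_character_) {
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  .boldFrameToTables(df, maxHits, columnMap, locus, runId, group)
}

## Shared between readBoldResults and the archived-workbook adapter.
.boldFrameToTables <- function(df, maxHits, columnMap, locus, runId,
                               group) {
  lookup <- function(field, required = FALSE) {
    header <- columnMap[[field]]
    if (is.null(header)) {
      if (required) stop("column map has no entry for '", field, "'")
      return(NULL)
    }
    idx <- match(tolower(header), tolower(names(df)))
    if (is.na(idx)) {
      if (required)
        stop("mapped column '", header, "' (", field,
             ") is absent from the input")
      return(NULL)
    }
    df[[idx]]
  }
  if (nrow(df) == 0L) return(list())
  qid <- as.character(lookup("query_id", required = TRUE))
  genus <- squish(as.character(lookup("genus", required = TRUE)))
  species <- squish(as.character(lookup("species", required = TRUE)))
  species[is.na(species)] <- ""
  genus[is.na(genus)] <- ""
  similarity <- suppressWarnings(as.numeric(lookup("similarity",
                                                   required = TRUE)))
  if (anyNA(similarity))
    stop("similarity column contains non-numeric or missing values")
  if (any(similarity < 0 | similarity > 100))
    stop("similarity values must lie in [0, 100]")
  ## "Amanita phalloides" when both parts present, else the genus alone
  label <- ifelse(nzchar(species),
                  ifelse(startsWith(tolower(species), tolower(genus)) &
                           nzchar(genus),
                         species, paste(genus, species)),
                  genus)
  label <- squish(label)
  sid <- lookup("subject_id")
  out <- data.frame(
    query_id = qid,
    subject_id = if (is.null(sid)) paste0("bold_hit_", seq_along(qid))
      else as.character(sid),
    subject_label = label, pident = NA_real_, length = NA_real_,
    evalue = NA_real_, bitscore = NA_real_, similarity = similarity,
    stringsAsFactors = FALSE
  )
  for (rank in HIT_EXTRA_RANKS) {
    v <- lookup(rank)
    if (!is.null(v)) out[[rank]] <- as.character(v)
  }
  .makeHitTables(out, "bold", locus, runId, group, maxHits)
}

#' Read query sequence lengths from FASTA
#'
#' Query ids are the first whitespace-delimited token of each header;
#' lengths count non-gap residues (alignment gap characters "-" and "."
#' are ignored).
#'
#' @param path path to a FASTA file.
#' @return named integer vector of lengths, one entry per query.
#' @export
readQueryFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate query id in FASTA: ",
         ids[which(duplicated(ids))[1]])
  chars <- as.character(seqs)
  lens <- nchar(gsub("[-.]", "", chars))
  if (any(lens == 0L))
    stop("empty sequence for query: ", ids[which(lens == 0L)[1]])
  setNames(as.integer(lens), ids)
}

#' Write hit tables to the canonical TSV
#'
#' Fixed header: query_id, locus, source_db, run_id, rank, subject_id,
#' subject_label, pident, length, evalue, bitscore, similarity, plus a
#' trailing query_length column so a re-read reproduces the tables
#' exactly. Empty cells encode \code{NA}.
#'
#' @param tables list of \linkS4class{HitTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHitTables <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    h <- hits(tb)
    n <- nrow(h)
    if (n == 0L) return(NULL)
    data.frame(
      query_id = queryId(tb), locus = locusName(tb),
      source_db = sourceDb(tb), run_id = runId(tb), rank = seq_len(n),
      subject_id = h$subject_id, subject_label = h$subject_label,
      pident = h$pident, length = h$length, evalue = h$evalue,
      bitscore = h$bitscore, similarity = h$similarity,
      query_length = queryLength(tb), stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(query_id = character(), locus = character(),
                     source_db = character(), run_id = character(),
                     rank = integer(), subject_id = character(),
                     subject_label = character(), pident = numeric(),
                     length = numeric(), evalue = numeric(),
                     bitscore = numeric(), similarity = numeric(),
                     query_length = integer())
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "", formatC(x, digits = 17, format = "g")))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read hit tables from the canonical TSV
#'
#' @param path path written by \code{\link{writeHitTables}}.
#' @return list of \linkS4class{HitTable}.
#' @export
readHitTables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (nrow(df) == 0L) return(list())
  key <- paste(df$query_id, df$source_db, df$run_id,
               ifelse(is.na(df$locus), "", df$locus), sep = "\r")
  out <- lapply(unique(key), function(k) {
    h <- df[key == k, , drop = FALSE]
    h <- h[order(h$rank), , drop = FALSE]
    HitTable(h$query_id[1],
             h[, c("subject_id", "subject_label", "pident", "length",
                   "evalue", "bitscore", "similarity")],
             sourceDb = h$source_db[1],
             locus = if (is.na(h$locus[1])) NA_character_ else h$locus[1],
             runId = h$run_id[1],
             queryLength = if ("query_length" %in% names(h))
               h$query_length[1] else NA_integer_)
  })
  out
}
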