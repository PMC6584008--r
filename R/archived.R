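## Dialect adapter for archived study outputs distributed as a
## spreadsheet workbook: each sheet holds the search output for one
## (database, taxonomic group, locus, run) combination, and a
## user-editable dialect config maps sheets and columns onto the
## canonical hit-table model. A directory of per-sheet CSV/TSV files is
## accepted interchangeably with an .xlsx workbook.
##
## The .xlsx reader below is deliberately minimal (shared strings,
## inline strings, numbers, A1 cell references); it exists because the
## adapter needs nothing more than rectangular header + rows sheets.

.colLetterToIndex <- function(ref) {
  letters_part <- gsub("[0-9]+$", "", ref)
  chars <- strsplit(letters_part, "")[[1]]
  as.integer(sum(match(chars, LETTERS) *
                   26 ^ (rev(seq_along(chars)) - 1)))
}

.readXlsxSheets <- function(path) {
  exdir <- tempfile("xlsx")
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  wb <- xml2::read_xml(file.path(exdir, "xl", "workbook.xml"))
  xml2::xml_ns_strip(wb)
  sheet_nodes <- xml2::xml_find_all(wb, ".//sheet")
  sheet_names <- xml2::xml_attr(sheet_nodes, "name")
  rids <- xml2::xml_attr(sheet_nodes, "id")

  rel_path <- file.path(exdir, "xl", "_rels", "workbook.xml.rels")
  rid_target <- NULL
  if (file.exists(rel_path)) {
    rels <- xml2::read_xml(rel_path)
    xml2::xml_ns_strip(rels)
    rel_nodes <- xml2::xml_find_all(rels, ".//Relationship")
    rid_target <- setNames(xml2::xml_attr(rel_nodes, "Target"),
                           xml2::xml_attr(rel_nodes, "Id"))
  }

  shared <- character()
  ss_path <- file.path(exdir, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::read_xml(ss_path)
    xml2::xml_ns_strip(ss)
    shared <- vapply(xml2::xml_find_all(ss, ".//si"), function(si) {
      paste(xml2::xml_text(xml2::xml_find_all(si, ".//t")),
            collapse = "")
    }, "")
  }

  readSheet <- function(target) {
    target <- sub("^/?(xl/)?", "", target)
    sh <- xml2::read_xml(file.path(exdir, "xl", target))
    xml2::xml_ns_strip(sh)
    rows <- xml2::xml_find_all(sh, ".//sheetData/row")
    if (length(rows) == 0L) return(data.frame())
    cells <- lapply(rows, function(row) {
      cs <- xml2::xml_find_all(row, "./c")
      if (length(cs) == 0L) return(NULL)
      ref <- xml2::xml_attr(cs, "r")
      type <- xml2::xml_attr(cs, "t")
      val <- vapply(cs, function(cc) {
        v <- xml2::xml_find_first(cc, "./v")
        if (!inherits(v, "xml_missing")) return(xml2::xml_text(v))
        is <- xml2::xml_find_first(cc, "./is")
        if (!inherits(is, "xml_missing")) return(xml2::xml_text(is))
        ""
      }, "")
      sval <- ifelse(!is.na(type) & type == "s",
                     shared[as.integer(val) + 1L], val)
      data.frame(col = vapply(ref, .colLetterToIndex, 1L),
                 value = sval, stringsAsFactors = FALSE)
    })
    cells <- Filter(Negate(is.null), cells)
    if (length(cells) == 0L) return(data.frame())
    ncol_max <- max(vapply(cells, function(x) max(x$col), 1L))
    mat <- matrix("", nrow = length(cells), ncol = ncol_max)
    for (i in seq_along(cells))
      mat[i, cells[[i]]$col] <- cells[[i]]$value
    header <- mat[1, ]
    body <- mat[-1, , drop = FALSE]
    df <- as.data.frame(body, stringsAsFactors = FALSE)
    names(df) <- ifelse(nzchar(header), header,
                        paste0("V", seq_len(ncol(df))))
    df
  }

  out <- vector("list", length(sheet_names))
  names(out) <- sheet_names
  for (i in seq_along(sheet_names)) {
    target <- if (!is.null(rid_target) && rids[i] %in% names(rid_target))
      rid_target[[rids[i]]] else paste0("worksheets/sheet", i, ".xml")
    out[[i]] <- readSheet(target)
  }
  out
}

## Directory-of-sheets form: each <name>.csv / <name>.tsv is a sheet.
.readSheetDir <- function(path) {
  files <- list.files(path, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  out <- lapply(files, function(f) {
    sep <- if (tolower(tools::file_ext(f)) == "csv") "," else "\t"
    utils::read.table(f, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "\"", comment.char = "",
                      colClasses = "character")
  })
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}

.genbankFrameToTables <- function(df, columns, maxHits, locus, runId,
                                  group) {
  lookup <- function(field, required = FALSE, numeric = FALSE) {
    header <- columns[[field]]
    if (is.null(header)) {
      if (required)
        stop("dialect config maps no '", field,
             "' column for a genbank sheet")
      return(NULL)
    }
    idx <- match(tolower(header), tolower(names(df)))
    if (is.na(idx))
      stop("dialect config references absent column '", header, "'")
    v <- df[[idx]]
    if (numeric) {
      out <- suppressWarnings(as.numeric(v))
      if (any(is.na(out) & nzchar(as.character(v))))
        stop("non-numeric value in mapped column '", header, "'")
      out
    } else as.character(v)
  }
  if (nrow(df) == 0L) return(list())
  out <- data.frame(
    query_id = lookup("query_id", required = TRUE),
    subject_label = lookup("subject_label", required = TRUE),
    pident = lookup("pident", required = TRUE, numeric = TRUE),
    evalue = lookup("evalue", required = TRUE, numeric = TRUE),
    bitscore = lookup("bitscore", required = TRUE, numeric = TRUE),
    similarity = NA_real_, stringsAsFactors = FALSE
  )
  sid <- lookup("subject_id")
  out$subject_id <- if (is.null(sid))
    paste0("gb_hit_", seq_len(nrow(out))) else sid
  len <- lookup("length", numeric = TRUE)
  out$length <- if (is.null(len)) NA_real_ else len
  for (rank in HIT_EXTRA_RANKS) {
    v <- lookup(rank)
    if (!is.null(v)) out[[rank]] <- v
  }
  .makeHitTables(out, "genbank", locus, runId, group, maxHits)
}

#' Read archived study outputs through a dialect config
#'
#' Adapts a workbook of archived search outputs (or, equivalently, a
#' directory holding one CSV/TSV file per sheet) into canonical hit
#' tables. The dialect config names each sheet and declares its source
#' database, taxonomic group, locus, run label and column mapping;
#' sheets present in the workbook but absent from the config are
#' skipped with a warning, while a config entry referencing an absent
#' sheet or column is an error. A sheet whose mapped statistic columns
#' do not match its declared source database (e.g. a "genbank" sheet
#' lacking e-value / bit score columns) is likewise an error.
#'
#' @param path path to an .xlsx workbook or to a directory of sheet
#'   files.
#' @param dialect a list with a \code{sheets} element (each entry:
#'   \code{sheet}, \code{source_db}, optional \code{group},
#'   \code{locus}, \code{run_id}, and \code{columns} mapping canonical
#'   fields — query_id, subject_label or genus/species, pident, evalue,
#'   bitscore, similarity, subject_id, length — to sheet headers), or a
#'   path to a YAML file holding that list.
#' @param maxHits records retained per query.
#' @return list of \linkS4class{HitTable} across all mapped sheets.
#' @export
readArchivedOutputs <- function(path, dialect, maxHits = 10) {
  if (is.character(dialect) && length(dialect) == 1L)
    dialect <- yaml::read_yaml(dialect)
  entries <- dialect$sheets %||% list()
  sheets <- if (dir.exists(path)) .readSheetDir(path)
    else .readXlsxSheets(path)
  mapped <- vapply(entries, function(e) e$sheet, "")
  unmapped <- setdiff(names(sheets), mapped)
  if (length(entries) == 0L || length(unmapped))
    warning("skipping unmapped sheet(s): ",
            if (length(unmapped)) paste(unmapped, collapse = ", ")
            else "(none present)")
  out <- list()
  for (e in entries) {
    if (!e$sheet %in% names(sheets))
      stop("dialect config references absent sheet '", e$sheet, "'")
    df <- sheets[[e$sheet]]
    src <- match.arg(e$source_db, c("genbank", "bold"))
    locus <- e$locus %||% NA_character_
    run <- e$run_id %||% "default"
    grp <- e$group %||% NA_character_
    cols <- e$columns %||% list()
    tabs <- if (src == "genbank") {
      .genbankFrameToTables(df, cols, maxHits, locus, run, grp)
    } else {
      .boldFrameToTables(df, maxHits,
                         utils::modifyList(boldColumnMap(), cols),
                         locus, run, grp)
    }
    out <- c(out, tabs)
  }
  out
}
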