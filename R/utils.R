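## Internal helpers shared across modules.

#' @importFrom methods new validObject slot slotNames is
#' @importFrom stats rnorm runif sd setNames aggregate
#' @importFrom utils read.delim write.table head unzip
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Collapse internal whitespace and trim both ends.
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

## The five ranks used throughout, shallow to deep.
BARCODE_RANKS <- c("class", "order", "family", "genus", "species")

## Depth of a rank name (1 = class ... 5 = species); NA-safe.
rankDepth <- function(rank) {
  match(rank, BARCODE_RANKS)
}

CLASSIFICATION_STATUSES <- c(
  "reliable_correct", "ambiguous_correct", "misidentified", "no_match"
)

AMBIGUITY_CATEGORIES <- c(
  "congeneric", "heterogeneric", "undetermined_species", "uncultured"
)

stopUsage <- function(...) {
  cond <- structure(
    class = c("barcodeUsageError", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  )
  stop(cond)
}

capitalizeFirst <- function(x) {
  ifelse(nchar(x) > 0,
         paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x)))),
         x)
}

## Case-fold comparison used for all taxon name matching.
foldEq <- function(a, b) {
  nzchar(a) & nzchar(b) & tolower(squish(a)) == tolower(squish(b))
}
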