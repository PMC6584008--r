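## Summary statistics over classification tables: accuracy by rank and
## group, ambiguity among correct matches, similarity summaries,
## run-to-run comparisons, and the supporting two-sample t-tests and
## one-way ANOVA. Ambiguous correct matches count as correct in
## accuracy tables; no-match queries stay in the denominators.

CORRECT_STATUSES <- c("reliable_correct", "ambiguous_correct")

.asClassificationDf <- function(classifications) {
  if (is.data.frame(classifications)) classifications
  else classificationTable(classifications)
}

.checkGroupKeys <- function(df, groupKeys) {
  bad <- setdiff(groupKeys, names(df))
  if (length(bad))
    stop("unknown group key(s): ", paste(bad, collapse = ", "))
}

.groupIndex <- function(df, groupKeys) {
  if (length(groupKeys) == 0L) return(rep("all", nrow(df)))
  do.call(paste, c(lapply(groupKeys, function(k) df[[k]]), sep = " / "))
}

## Species-level correctness and correctness at an arbitrary rank.
.correctAtRank <- function(df, rank) {
  species_ok <- df$status %in% CORRECT_STATUSES
  if (identical(rank, "species")) return(species_ok)
  depth <- rankDepth(df$deepest_correct_rank)
  species_ok | (!is.na(depth) & depth >= rankDepth(rank))
}

#' Accuracy table by group and rank
#'
#' For each grouping cell and each taxonomic rank, the percentage of
#' queries correctly identified at that rank. Correct at species means
#' status reliable_correct or ambiguous_correct; correct at a shallower
#' rank additionally admits misidentified queries whose roll-up reaches
#' at least that rank. No-match queries count as incorrect at every
#' rank. Percentages are unrounded; groups empty after filtering are
#' omitted.
#'
#' @param classifications classification table or list of
#'   \linkS4class{Classification}.
#' @param groupKeys column names to group by (e.g.
#'   \code{c("group", "source_db", "locus")}).
#' @param ranks ranks to report (default species and genus, deepest
#'   first).
#' @return data.frame with grouping columns, rank, n, n_correct,
#'   percent_correct, percent_ambiguous_of_correct and the mean / sd of
#'   top similarity within the group.
#' @export
accuracyTable <- function(classifications,
                          groupKeys = c("source_db", "locus"),
                          ranks = c("species", "genus")) {
  df <- .asClassificationDf(classifications)
  if (nrow(df) == 0L) stop("no classifications to summarise")
  .checkGroupKeys(df, groupKeys)
  stopifnot(all(ranks %in% BARCODE_RANKS))
  key <- .groupIndex(df, groupKeys)
  rows <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) return(NULL)
    n_rel <- sum(sub$status == "reliable_correct")
    n_amb <- sum(sub$status == "ambiguous_correct")
    amb_pct <- if (n_rel + n_amb > 0) 100 * n_amb / (n_rel + n_amb)
      else NA_real_
    sims <- sub$top_similarity[!is.na(sub$top_similarity)]
    per_rank <- lapply(ranks, function(r) {
      ok <- .correctAtRank(sub, r)
      cbind(
        sub[1, groupKeys, drop = FALSE],
        data.frame(rank = r, n = n, n_correct = sum(ok),
                   percent_correct = 100 * sum(ok) / n,
                   percent_ambiguous_of_correct = amb_pct,
                   mean_top_similarity =
                     if (length(sims)) mean(sims) else NA_real_,
                   sd_top_similarity =
                     if (length(sims) > 1) stats::sd(sims) else NA_real_,
                   stringsAsFactors = FALSE)
      )
    })
    do.call(rbind, per_rank)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ambiguity among correct matches
#'
#' Per grouping cell, the percentage of correct matches that were
#' ambiguous: 100 * ambiguous / (ambiguous + reliable). Cells with no
#' correct match contribute no term (a message records them). The
#' cross-cell mean and sample standard deviation (n - 1) summarise the
#' study-wide ambiguity level.
#'
#' @param classifications classification table or list.
#' @param groupKeys grouping columns defining the cells.
#' @return list with \code{perGroup} (data.frame of cell rates),
#'   \code{mean} and \code{sd} (NA when fewer than two cells).
#' @export
ambiguitySummary <- function(classifications,
                             groupKeys = c("group", "source_db",
                                           "locus")) {
  df <- .asClassificationDf(classifications)
  .checkGroupKeys(df, groupKeys)
  key <- .groupIndex(df, groupKeys)
  rows <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    n_rel <- sum(sub$status == "reliable_correct")
    n_amb <- sum(sub$status == "ambiguous_correct")
    if (n_rel + n_amb == 0L) {
      message("group '", k, "' has no correct matches; skipped")
      return(NULL)
    }
    cbind(sub[1, groupKeys, drop = FALSE],
          data.frame(n_correct = n_rel + n_amb, n_ambiguous = n_amb,
                     percent_ambiguous = 100 * n_amb / (n_rel + n_amb),
                     stringsAsFactors = FALSE))
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no group has a correct match")
  rownames(per) <- NULL
  list(perGroup = per,
       mean = mean(per$percent_ambiguous),
       sd = if (nrow(per) > 1) stats::sd(per$percent_ambiguous)
         else NA_real_)
}

#' Similarity summary over selected classifications
#'
#' Arithmetic mean and sample standard deviation of the top-set best
#' similarity (BOLD similarity or GenBank percent identity) among the
#' selected queries; e.g. restricted to misidentified queries, a low
#' BOLD similarity is a usable indicator of an incorrect match.
#'
#' @param classifications classification table or list.
#' @param statuses statuses to keep (default: all except no_match).
#' @return list with \code{mean}, \code{sd} (NA for a single value) and
#'   \code{n}.
#' @export
similaritySummary <- function(classifications,
                              statuses = setdiff(
                                CLASSIFICATION_STATUSES, "no_match")) {
  df <- .asClassificationDf(classifications)
  sel <- df[df$status %in% statuses, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no classifications match the filter")
  if (anyNA(sel$top_similarity))
    stop("selected classifications lack a top similarity")
  list(mean = mean(sel$top_similarity),
       sd = if (nrow(sel) > 1) stats::sd(sel$top_similarity)
         else NA_real_,
       n = nrow(sel))
}

#' Two-sample t-test
#'
#' Welch (default) or pooled-variance two-sample t-test, two-sided.
#' Two samples with zero variance and equal means are not an error:
#' they give t = 0, p = 1.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param variant "welch" or "pooled".
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
twoSampleTTest <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y))
      return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  res <- stats::t.test(x, y, var.equal = variant == "pooled")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (between /
#' within mean-square ratio), p-value from the F distribution. When
#' every observation is the same constant (zero between- and
#' within-group variance) F is defined as 0 with p = 1.
#'
#' @param groups list of numeric samples, each of size >= 2.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
oneWayANOVA <- function(groups) {
  if (length(groups) < 2)
    stop("need at least two groups")
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  if (stats::sd(values) == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  within_var <- sum(vapply(groups, function(v)
    sum((v - mean(v))^2), 0)) / df2
  if (within_var == 0)
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  res <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p = res$p.value)
}

#' Compare classifications across search runs
#'
#' Aligns the runs on their shared queries and reports the per-query
#' status matrix, per-run species-level accuracy, pairwise status
#' agreement, a test for a run effect on per-query correctness
#' (two-sample t-test for two runs, one-way ANOVA otherwise, on binary
#' 0/1 correctness indicators), and the queries whose status changes
#' between runs (e.g. correct against the full BOLD sequence subset but
#' "no match" against restricted subsets).
#'
#' @param classifications classification table or list spanning >= 2
#'   run_ids.
#' @param pairing column pairing queries across runs (default
#'   query_id).
#' @return list with \code{statusMatrix}, \code{accuracy},
#'   \code{agreement}, \code{test}, \code{changedQueries}.
#' @export
compareRuns <- function(classifications, pairing = "query_id") {
  df <- .asClassificationDf(classifications)
  runs <- unique(df$run_id)
  if (length(runs) < 2)
    stop("need classifications from at least two runs")
  by_run <- lapply(runs, function(r)
    df[df$run_id == r, , drop = FALSE])
  shared <- Reduce(intersect, lapply(by_run, function(d) d[[pairing]]))
  if (length(shared) == 0L)
    stop("runs share no queries (disjoint query sets)")
  mat <- vapply(by_run, function(d)
    d$status[match(shared, d[[pairing]])], character(length(shared)))
  mat <- matrix(mat, nrow = length(shared),
                dimnames = list(shared, runs))
  correct <- matrix(mat %in% CORRECT_STATUSES, nrow = nrow(mat),
                    dimnames = dimnames(mat))
  accuracy <- data.frame(
    run_id = runs,
    n = nrow(mat),
    percent_correct = 100 * colMeans(correct),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pairs <- utils::combn(runs, 2)
  agreement <- data.frame(
    run_a = pairs[1, ], run_b = pairs[2, ],
    agreement_pct = apply(pairs, 2, function(p)
      100 * mean(mat[, p[1]] == mat[, p[2]])),
    stringsAsFactors = FALSE
  )
  indicators <- lapply(runs, function(r) as.numeric(correct[, r]))
  test <- if (length(runs) == 2L)
    twoSampleTTest(indicators[[1]], indicators[[2]])
  else oneWayANOVA(indicators)
  changed <- shared[apply(mat, 1, function(s) length(unique(s)) > 1)]
  list(statusMatrix = mat, accuracy = accuracy, agreement = agreement,
       test = test, changedQueries = changed)
}
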