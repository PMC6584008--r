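## Builds a classification table directly (the summaries operate on
## the tabular form, so tests can state statuses explicitly).
clRow <- function(qid, status, deepest = NA_character_, sim = 99,
                  group = "insects", db = "genbank", locus = "COI",
                  run = "default") {
  data.frame(query_id = qid, locus = locus, source_db = db,
             run_id = run, group = group, status = status,
             deepest_correct_rank =
               if (status %in% c("reliable_correct",
                                 "ambiguous_correct")) "species"
               else deepest,
             categories = "", top_similarity = sim,
             low_confidence = FALSE, candidate_species = "",
             truth_species = "Aus bus", stringsAsFactors = FALSE)
}

test_that("accuracy counts correct-at-rank with no-match in denominators", {
  ## 17 queries, 9 species-correct (7 reliable + 2 ambiguous), plus
  ## misidentifications rolled up to genus, and 2 no-match
  df <- rbind(
    do.call(rbind, lapply(1:7, function(i)
      clRow(paste0("Q", i), "reliable_correct"))),
    do.call(rbind, lapply(8:9, function(i)
      clRow(paste0("Q", i), "ambiguous_correct"))),
    do.call(rbind, lapply(10:13, function(i)
      clRow(paste0("Q", i), "misidentified", deepest = "genus"))),
    do.call(rbind, lapply(14:15, function(i)
      clRow(paste0("Q", i), "misidentified", deepest = "class"))),
    do.call(rbind, lapply(16:17, function(i)
      clRow(paste0("Q", i), "no_match", sim = NA))))
  acc <- accuracyTable(df, groupKeys = c("source_db", "locus"))
  sp <- acc[acc$rank == "species", ]
  ge <- acc[acc$rank == "genus", ]
  expect_equal(sp$n, 17)
  expect_equal(sp$n_correct, 9)
  expect_equal(sp$percent_correct, 100 * 9 / 17, tolerance = 1e-12)
  ## 52.9% at the printed precision
  expect_equal(round(sp$percent_correct, 1), 52.9)
  ## genus-correct = 9 species-correct + 4 genus roll-ups
  expect_equal(ge$n_correct, 13)
  ## rank monotonicity
  expect_gte(ge$percent_correct, sp$percent_correct)
  expect_error(accuracyTable(df, groupKeys = "nope"), "group key")
})

test_that("all-correct groups score 100 percent at every rank", {
  df <- do.call(rbind, lapply(1:5, function(i)
    clRow(paste0("Q", i), "reliable_correct")))
  acc <- accuracyTable(df, groupKeys = "source_db",
                       ranks = c("species", "genus", "family",
                                 "order", "class"))
  expect_true(all(acc$percent_correct == 100))
})

test_that("ambiguity summary averages per-group rates with sample sd", {
  ## group A: 1 of 10 correct matches ambiguous (10%); group B: 34%
  mk <- function(grp, n_amb, n_rel) rbind(
    do.call(rbind, lapply(seq_len(n_amb), function(i)
      clRow(paste0(grp, "A", i), "ambiguous_correct", group = grp))),
    do.call(rbind, lapply(seq_len(n_rel), function(i)
      clRow(paste0(grp, "R", i), "reliable_correct", group = grp))))
  df <- rbind(mk("g1", 1, 9), mk("g2", 17, 33))
  amb <- ambiguitySummary(df, groupKeys = "group")
  expect_equal(sort(amb$perGroup$percent_ambiguous), c(10, 34))
  expect_equal(amb$mean, 22)
  expect_equal(amb$sd, 16.97056, tolerance = 1e-6)
  ## single group: sd undefined
  one <- ambiguitySummary(mk("g1", 1, 9), groupKeys = "group")
  expect_true(is.na(one$sd))
  ## all reliable: zero everywhere
  allrel <- ambiguitySummary(mk("g3", 0, 5), groupKeys = "group")
  expect_equal(allrel$mean, 0)
  ## a group with no correct matches contributes no term
  df2 <- rbind(mk("g1", 1, 9),
               clRow("QX", "misidentified", group = "gEmpty"))
  expect_message(res <- ambiguitySummary(df2, groupKeys = "group"),
                 "no correct matches")
  expect_equal(nrow(res$perGroup), 1)
})

test_that("similarity summaries report mean and sample sd", {
  df <- rbind(clRow("Q1", "misidentified", sim = 96),
              clRow("Q2", "misidentified", sim = 100))
  s <- similaritySummary(df, "misidentified")
  expect_equal(s$mean, 98)
  expect_equal(s$sd, 2.828427, tolerance = 1e-6)
  one <- similaritySummary(clRow("Q1", "misidentified", sim = 97),
                           "misidentified")
  expect_true(is.na(one$sd))
  expect_error(similaritySummary(df, "no_match"), "filter")
})

test_that("pooled two-sample t matches the textbook value", {
  res <- twoSampleTTest(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  ## identical samples: t = 0, p = 1
  same <- twoSampleTTest(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## Welch equals pooled with equal variances and sizes
  w <- twoSampleTTest(c(1, 2, 3), c(4, 5, 6), variant = "welch")
  expect_equal(w$t, res$t)
  expect_equal(w$df, res$df)
  ## relabeling negates t, p unchanged
  fl <- twoSampleTTest(c(4, 5, 6), c(1, 2, 3), variant = "pooled")
  expect_equal(fl$t, -res$t)
  expect_equal(fl$p, res$p)
  expect_error(twoSampleTTest(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  groups <- list(c(1, 2, 3), c(2, 4, 6, 8), c(5, 5, 8))
  res <- oneWayANOVA(groups)
  ## independent brute-force computation
  values <- unlist(groups)
  grand <- mean(values)
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, 0) - grand)^2)
  ss_within <- sum(unlist(lapply(groups, function(v)
    (v - mean(v))^2)))
  df1 <- length(groups) - 1
  df2 <- length(values) - length(groups)
  f_expected <- (ss_between / df1) / (ss_within / df2)
  expect_equal(res$F, f_expected, tolerance = 1e-9)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(res$p, stats::pf(f_expected, df1, df2,
                                lower.tail = FALSE),
               tolerance = 1e-9)
  ## two groups: F equals the square of the pooled t statistic
  t2 <- twoSampleTTest(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
  f2 <- oneWayANOVA(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(f2$F, t2$t^2, tolerance = 1e-9)
  ## all groups one constant: F defined as 0
  const <- oneWayANOVA(list(c(3, 3), c(3, 3, 3)))
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)
  ## invariance under group permutation
  perm <- oneWayANOVA(groups[c(3, 1, 2)])
  expect_equal(perm$F, res$F)
  expect_error(oneWayANOVA(list(c(1, 2))), "two groups")
  expect_error(oneWayANOVA(list(c(1, 2), 3)), "at least 2")
})

test_that("run comparison aligns shared queries and flags changes", {
  runA <- do.call(rbind, lapply(1:17, function(i)
    clRow(paste0("Q", i), "reliable_correct", run = "all")))
  runB <- runA
  runB$run_id <- "species_only"
  runB$status[1:2] <- "no_match"
  runB$top_similarity[1:2] <- NA
  cmp <- compareRuns(rbind(runA, runB))
  expect_equal(cmp$agreement$agreement_pct, 100 * 15 / 17,
               tolerance = 1e-12)
  expect_equal(round(cmp$agreement$agreement_pct, 1), 88.2)
  expect_setequal(cmp$changedQueries, c("Q1", "Q2"))
  expect_equal(cmp$accuracy$percent_correct[
    cmp$accuracy$run_id == "all"], 100)
  ## identical runs: full agreement, t = 0
  runC <- runA
  runC$run_id <- "rerun"
  cmp2 <- compareRuns(rbind(runA, runC))
  expect_equal(cmp2$agreement$agreement_pct, 100)
  expect_equal(cmp2$test$t, 0)
  expect_equal(cmp2$test$p, 1)
  ## disjoint query sets error
  runD <- do.call(rbind, lapply(18:20, function(i)
    clRow(paste0("Q", i), "reliable_correct", run = "other")))
  expect_error(compareRuns(rbind(runA, runD)), "disjoint")
})

test_that("restricted-subset runs flag exactly the low-similarity queries", {
  ## queries <96% similarity against the "all" subset come back as
  ## no-match from the restricted subsets
  sims <- c(99, 98, 60, 45, 97, 92)
  mkRun <- function(run, restricted) do.call(rbind, lapply(
    seq_along(sims), function(i) {
      low <- sims[i] < 96
      if (restricted && low)
        clRow(paste0("Q", i), "no_match", sim = NA, db = "bold",
              run = run)
      else clRow(paste0("Q", i),
                 ifelse(low, "misidentified", "reliable_correct"),
                 deepest = "genus", sim = sims[i], db = "bold",
                 run = run)
    }))
  df <- rbind(mkRun("all", FALSE), mkRun("full", TRUE),
              mkRun("public", TRUE), mkRun("species", TRUE))
  cmp <- compareRuns(df)
  expect_setequal(cmp$changedQueries,
                  paste0("Q", which(sims < 96)))
  expect_setequal(cmp$changedQueries,
                  paste0("Q", which(flagConfidence(sims, 96))))
})
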