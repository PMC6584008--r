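test_that("tied records on all keys form the top-match set", {
  tb <- gbTable("Q1", c("Aus bus", "Aus cus", "Aus dus"),
                evalue = c(1e-50, 1e-50, 1e-40),
                bitscore = c(1000, 1000, 900),
                pident = c(99.5, 99.5, 97))
  top <- topMatchSet(tb)
  expect_equal(tieCount(top), 2)
  expect_identical(members(top)$subject_label, c("Aus bus", "Aus cus"))
  single <- topMatchSet(gbTable("Q1", "Aus bus", 1e-50, 1000, 99.5))
  expect_equal(tieCount(single), 1)
  empty <- topMatchSet(HitTable("Q1", data.frame(),
                                sourceDb = "genbank"))
  expect_equal(tieCount(empty), 0)
})

test_that("a record must tie on every GenBank key to join the set", {
  ## equal e-value, lower bit score: not a member
  tb <- gbTable("Q1", c("Aus bus", "Aus cus"),
                evalue = c(1e-50, 1e-50), bitscore = c(1000, 990),
                pident = c(99.5, 99.5))
  expect_equal(tieCount(topMatchSet(tb)), 1)
  ## printed-equal statistics (within tolerance) are tied
  tb2 <- gbTable("Q1", c("Aus bus", "Aus cus"),
                 evalue = c(1e-50, 1e-50 * (1 + 1e-12)),
                 bitscore = c(1000, 1000.004),
                 pident = c(99.5, 99.496))
  expect_equal(tieCount(topMatchSet(tb2)), 2)
})

test_that("top-match set equals the exhaustive pairwise oracle", {
  set.seed(101)
  for (i in 1:200) {
    tb <- randomGbTable()
    got <- topMatchSet(tb)
    expect_identical(members(got)$subject_id,
                     hits(tb)$subject_id[oracleTopSet(tb)])
  }
})

test_that("enlarging tie tolerances never shrinks the tie count", {
  set.seed(202)
  for (i in 1:100) {
    tb <- randomGbTable()
    tight <- topMatchSet(tb, TiePolicy(evalueRtol = 0,
                                       percentTol = 0,
                                       bitscoreTol = 0))
    loose <- topMatchSet(tb, TiePolicy(evalueRtol = 1e-6,
                                       percentTol = 0.5,
                                       bitscoreTol = 0.5))
    expect_gte(tieCount(loose), tieCount(tight))
  }
})

test_that("adjudication is invariant under record input order", {
  set.seed(303)
  for (i in 1:50) {
    tb <- randomGbTable()
    h <- hits(tb)
    perm <- sample.int(nrow(h))
    tb2 <- HitTable(queryId(tb), h[perm, ], sourceDb = "genbank")
    truth <- Lineage(genus = "Aus", species = "Aus a")
    c1 <- classifyQuery(topMatchSet(tb), truth)
    c2 <- classifyQuery(topMatchSet(tb2), truth)
    expect_identical(classificationStatus(c1),
                     classificationStatus(c2))
    expect_identical(sort(candidateSpecies(c1)),
                     sort(candidateSpecies(c2)))
  }
})

test_that("every query gets exactly one status", {
  truth <- Lineage(genus = "Aus", species = "Aus bus")
  tables <- list(
    gbTable("Q1", "Aus bus", 1e-50, 1000, 99.5),
    gbTable("Q2", c("Aus bus", "Aus sp."), c(1e-50, 1e-50),
            c(1000, 1000), c(99.5, 99.5)),
    gbTable("Q3", "Aus cus", 1e-50, 1000, 99.5),
    HitTable("Q4", data.frame(), sourceDb = "genbank")
  )
  df <- classificationTable(lapply(tables, function(tb)
    classifyQuery(topMatchSet(tb), truth)))
  expect_equal(nrow(df), 4)
  expect_true(all(table(df$status) >= 0))
  expect_equal(sum(table(df$status)), 4)
  expect_identical(df$status,
                   c("reliable_correct", "ambiguous_correct",
                     "misidentified", "no_match"))
})

test_that("classification statuses follow the adjudication rules", {
  truth <- Lineage(class_ = "Agaricomycetes", order = "Agaricales",
                   family = "Amanitaceae", genus = "Amanita",
                   species = "Amanita phalloides")
  ## correct species plus an undetermined congener: ambiguous
  amb <- classifyQuery(topMatchSet(
    gbTable("Q1", c("Amanita phalloides", "Amanita sp."),
            c(1e-80, 1e-80), c(1200, 1200), c(99.9, 99.9))), truth)
  expect_identical(classificationStatus(amb), "ambiguous_correct")
  expect_identical(ambiguityCategories(amb), "undetermined_species")
  expect_identical(deepestRank(amb), "species")
  ## only correct members: reliable
  rel <- classifyQuery(topMatchSet(
    gbTable("Q2", c("Amanita phalloides", "Amanita phalloides"),
            c(1e-80, 1e-80), c(1200, 1200), c(99.9, 99.9))), truth)
  expect_identical(classificationStatus(rel), "reliable_correct")
  ## congener only: misidentified, rolled up to genus
  mis <- classifyQuery(topMatchSet(
    gbTable("Q3", "Amanita muscaria", 1e-80, 1200, 99.9)), truth)
  expect_identical(classificationStatus(mis), "misidentified")
  expect_identical(deepestRank(mis), "genus")
  expect_length(ambiguityCategories(mis), 0)
  ## a top set of only undetermined records of the right genus:
  ## misidentified at species, correct at genus
  und <- classifyQuery(topMatchSet(
    gbTable("Q4", "Amanita sp.", 1e-80, 1200, 99.9)), truth)
  expect_identical(classificationStatus(und), "misidentified")
  expect_identical(deepestRank(und), "genus")
})

test_that("ambiguity categories distinguish the co-hit identities", {
  truth <- Lineage(genus = "Amanita", species = "Amanita phalloides")
  top <- topMatchSet(gbTable(
    "Q1",
    c("Amanita phalloides", "Amanita muscaria", "Boletus edulis",
      "uncultured fungus", "Amanita sp."),
    rep(1e-80, 5), rep(1200, 5), rep(99.9, 5)))
  cl <- classifyQuery(top, truth)
  expect_identical(classificationStatus(cl), "ambiguous_correct")
  expect_setequal(ambiguityCategories(cl),
                  c("congeneric", "heterogeneric", "uncultured",
                    "undetermined_species"))
})

test_that("synonyms reconcile the expected name with database labels", {
  truth <- Lineage(genus = "Chrysomya",
                   species = "Chrysomya megacephala")
  syn <- SynonymTable("Chrysomya saffranea", "Chrysomya megacephala")
  tb <- gbTable("Q1", "Chrysomya saffranea", 1e-80, 1200, 99.9)
  without <- classifyQuery(topMatchSet(tb), truth)
  with_syn <- classifyQuery(topMatchSet(tb), truth, syn)
  expect_identical(classificationStatus(without), "misidentified")
  expect_identical(classificationStatus(with_syn), "reliable_correct")
})

test_that("similarity confidence uses an inclusive-high threshold", {
  expect_true(flagConfidence(95.9, 96))
  expect_false(flagConfidence(96.0, 96))
  expect_false(flagConfidence(100, 96))
  truth <- Lineage(genus = "Aus", species = "Aus bus")
  low <- classifyQuery(topMatchSet(boldTable("Q1", "Aus cus", 60)),
                       truth)
  expect_true(low@lowConfidence)
  expect_equal(topSimilarity(low), 60)
})

test_that("length strata partition queries and report misidentification", {
  truth <- Lineage(genus = "Aus", species = "Aus bus")
  cls <- list(
    classifyQuery(topMatchSet(gbTable("Q1", "Aus bus", 1e-50, 1000,
                                      99.5)), truth),
    classifyQuery(topMatchSet(gbTable("Q2", "Aus cus", 1e-50, 1000,
                                      99.5)), truth),
    classifyQuery(topMatchSet(gbTable("Q3", "Aus cus", 1e-50, 1000,
                                      99.5)), truth),
    classifyQuery(topMatchSet(gbTable("Q4", "Aus bus", 1e-50, 1000,
                                      99.5)), truth)
  )
  lens <- c(Q1 = 650, Q2 = 340, Q3 = 500, Q4 = 620)
  strat <- stratifyByLength(cls, lens, fullCutoff = 640,
                            midCutoff = 430)
  expect_identical(unname(strat$assignment),
                   c("full", "mid", "mid", "mid"))
  summ <- strat$summary
  ## 2 misidentified in the mid stratum of size 3
  expect_equal(summ$misidentification_rate_pct[summ$stratum == "mid"],
               100 * 2 / 3, tolerance = 1e-12)
  expect_equal(summ$misidentification_rate_pct[summ$stratum == "full"],
               0)
  expect_error(stratifyByLength(cls, lens[1:2]), "Q3")
})
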