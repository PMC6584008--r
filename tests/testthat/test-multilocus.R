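## Convenience: classification with a given top-set label list.
clFor <- function(qid, labels, truth, locus, statistic = 99.9) {
  tb <- gbTable(qid, labels, rep(1e-80, length(labels)),
                rep(1200, length(labels)),
                rep(statistic, length(labels)), locus = locus)
  classifyQuery(topMatchSet(tb), truth, locus = locus)
}

noMatchFor <- function(qid, truth, locus) {
  classifyQuery(topMatchSet(HitTable(qid, data.frame(),
                                     sourceDb = "genbank",
                                     locus = locus)),
                truth, locus = locus)
}

truthT <- Lineage(class_ = "Magnoliopsida", order = "Apiales",
                  family = "Apiaceae", genus = "Conium",
                  species = "Conium maculatum")

test_that("intersection strips a congener another locus rules out", {
  a <- clFor("SP1", c("Conium maculatum", "Conium chaerophylloides"),
             truthT, "rbcL")
  b <- clFor("SP1", "Conium maculatum", truthT, "matK")
  sc <- combineLoci(list(a, b))
  expect_identical(classificationStatus(sc), "reliable_correct")
  expect_identical(candidateSpecies(sc), "Conium maculatum")
  expect_identical(classificationStatus(a), "ambiguous_correct")
})

test_that("a single locus combines to itself under every strategy", {
  for (labels in list("Conium maculatum",
                      c("Conium maculatum", "Conium chaerophylloides"),
                      c("Conium maculatum", "Conium sp."))) {
    one <- clFor("SP1", labels, truthT, "rbcL")
    for (strategy in c("intersection", "union", "best_locus")) {
      sc <- combineLoci(list(one), strategy = strategy)
      expect_identical(classificationStatus(sc),
                       classificationStatus(one), label = strategy)
      expect_setequal(candidateSpecies(sc), candidateSpecies(one))
      expect_identical(ambiguityCategories(sc),
                       ambiguityCategories(one))
    }
  }
})

test_that("disjoint per-locus candidates without the truth are misidentified", {
  a <- clFor("SP1", "Conium chaerophylloides", truthT, "rbcL")
  b <- clFor("SP1", "Daucus carota", truthT, "matK")
  sc <- combineLoci(list(a, b))
  expect_identical(classificationStatus(sc), "misidentified")
  ## rbcL rolls up to genus, matK only to family: the combination
  ## supports family at best... matK hit is a different family entirely
  expect_true(is.na(deepestRank(sc)) ||
                deepestRank(sc) %in% c("class", "order", "family",
                                       "genus"))
})

test_that("no-match loci are dropped, all-no-match errors", {
  a <- noMatchFor("SP1", truthT, "rbcL")
  b <- clFor("SP1", "Conium maculatum", truthT, "matK")
  sc <- combineLoci(list(a, b))
  expect_identical(classificationStatus(sc), "reliable_correct")
  expect_identical(sc@loci, "matK")
  expect_error(combineLoci(list(a, noMatchFor("SP1", truthT, "matK"))),
               "no match")
})

test_that("best_locus picks the fewest tied identities, priority breaking ties", {
  a <- clFor("SP1", c("Conium maculatum", "Conium chaerophylloides"),
             truthT, "rbcL")
  b <- clFor("SP1", "Conium maculatum", truthT, "matK")
  sc <- combineLoci(list(a, b), strategy = "best_locus")
  expect_identical(classificationStatus(sc), "reliable_correct")
  ## equal set sizes: rbcL outranks matK in the default priority
  c1 <- clFor("SP1", "Conium maculatum", truthT, "rbcL")
  sc2 <- combineLoci(list(b, c1), strategy = "best_locus")
  expect_identical(classificationStatus(sc2), "reliable_correct")
})

test_that("intersection never exceeds any single locus's candidate count", {
  set.seed(404)
  species_pool <- c("Conium maculatum", "Conium chaerophylloides",
                    "Conium sp.", "Daucus carota", "uncultured Conium",
                    "Apium graveolens")
  for (i in 1:100) {
    n_loci <- sample(2:4, 1)
    cls <- lapply(seq_len(n_loci), function(j) {
      labels <- sample(species_pool, sample.int(4, 1))
      if (runif(1) < 0.6)
        labels <- unique(c("Conium maculatum", labels))
      clFor("SP1", labels, truthT,
            c("rbcL", "matK", "trnH-psbA", "ITS2")[j])
    })
    sc <- combineLoci(cls, strategy = "intersection")
    expect_lte(length(candidateSpecies(sc)),
               min(lengths(lapply(cls, candidateSpecies))))
    ## adding a locus containing the truth never turns a reliable
    ## intersection into a misidentification
    if (classificationStatus(sc) == "reliable_correct") {
      extra <- clFor("SP1", c("Conium maculatum", "Conium sp."),
                     truthT, "ITS2")
      sc2 <- combineLoci(c(cls, extra), strategy = "intersection")
      expect_false(identical(classificationStatus(sc2),
                             "misidentified"))
    }
  }
})

test_that("strategies agree when per-locus top sets are identical", {
  set.seed(505)
  for (labels in list("Conium maculatum",
                      c("Conium maculatum", "Daucus carota"),
                      "Conium chaerophylloides")) {
    cls <- lapply(c("rbcL", "matK"), function(l)
      clFor("SP1", labels, truthT, l))
    res <- lapply(c("intersection", "union", "best_locus"),
                  function(s) combineLoci(cls, strategy = s))
    statuses <- vapply(res, classificationStatus, "")
    expect_length(unique(statuses), 1)
  }
})

test_that("ITS subunit modes are tabulated with the combined run as headline", {
  truthF <- Lineage(genus = "Amanita", species = "Amanita phalloides")
  its1 <- clFor("SPX", "Amanita muscaria", truthF, "ITS1")
  its2 <- clFor("SPX", "Amanita phalloides", truthF, "ITS2")
  its <- clFor("SPX", "Amanita phalloides", truthF, "ITS")
  cmp <- itsModes(list(its1, its2, its))
  expect_equal(nrow(cmp), 1)
  expect_identical(cmp$status_its1, "misidentified")
  expect_false(cmp$concordant)
  expect_identical(cmp$headline, "reliable_correct")
  ## all concordant
  cmp2 <- itsModes(list(its2, its))
  expect_true(cmp2$concordant)
  ## missing subunit: comparison over available modes only
  cmp3 <- itsModes(list(its1, its))
  expect_true(is.na(cmp3$status_its2))
  expect_identical(cmp3$headline, "reliable_correct")
  expect_error(itsModes(list(clFor("SPX", "Aus bus", truthF, "COI"))),
               "locus")
})
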