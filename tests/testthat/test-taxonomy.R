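test_that("taxon labels parse into genus, epithet and determinacy flags", {
  cases <- list(
    list(label = "Amanita sp.", genus = "Amanita", epithet = "",
         undetermined = TRUE, uncultured = FALSE, canonical = ""),
    list(label = "Chrysomya megacephala", genus = "Chrysomya",
         epithet = "megacephala", undetermined = FALSE,
         uncultured = FALSE, canonical = "Chrysomya megacephala"),
    list(label = "uncultured fungus clone A7", genus = "",
         epithet = "", undetermined = TRUE, uncultured = TRUE,
         canonical = ""),
    list(label = "uncultured Amanita", genus = "Amanita", epithet = "",
         undetermined = TRUE, uncultured = TRUE, canonical = ""),
    list(label = "Amanita phalloides var. alba", genus = "Amanita",
         epithet = "phalloides", undetermined = FALSE,
         uncultured = FALSE, canonical = "Amanita phalloides"),
    list(label = "AMANITA PHALLOIDES", genus = "Amanita",
         epithet = "phalloides", undetermined = FALSE,
         uncultured = FALSE, canonical = "Amanita phalloides"),
    list(label = "Amanita sp. XJ-2017", genus = "Amanita",
         epithet = "", undetermined = TRUE, uncultured = FALSE,
         canonical = ""),
    list(label = "Fusarium sp1", genus = "Fusarium", epithet = "",
         undetermined = TRUE, uncultured = FALSE, canonical = "")
  )
  for (cs in cases) {
    p <- parseTaxonName(cs$label)
    expect_identical(p@genus, cs$genus, label = cs$label)
    expect_identical(p@speciesEpithet, cs$epithet, label = cs$label)
    expect_identical(p@isUndetermined, cs$undetermined,
                     label = cs$label)
    expect_identical(p@isUncultured, cs$uncultured, label = cs$label)
    expect_identical(p@canonicalBinomial, cs$canonical,
                     label = cs$label)
  }
})

test_that("open-nomenclature qualifiers are flagged and not determined", {
  p <- parseTaxonName("Aus cf. bus")
  expect_true(p@isQualified)
  expect_true(p@isUndetermined)
  expect_identical(p@canonicalBinomial, "")
})

test_that("empty labels are rejected", {
  expect_error(parseTaxonName(""), "nonempty")
  expect_error(parseTaxonName("   "), "nonempty")
})

test_that("synonym resolution is a one-step idempotent lookup", {
  empty <- emptySynonymTable()
  expect_identical(resolveSynonym("Aus bus", empty), "Aus bus")
  tab <- SynonymTable("Aus cus", "Aus bus")
  expect_identical(resolveSynonym("Aus cus", tab), "Aus bus")
  expect_identical(resolveSynonym("Aus bus", tab), "Aus bus")
  ## case-insensitive lookup
  expect_identical(resolveSynonym("AUS CUS", tab), "Aus bus")
  ## property: applying twice equals applying once, on random tables
  set.seed(7)
  for (i in 1:20) {
    n <- sample.int(8, 1)
    alias <- paste("Gen", letters[sample.int(26, n)], "sp", letters[1:n])
    canon <- paste("Gen canon", letters[sample.int(26, n, TRUE)])
    tab <- SynonymTable(alias, canon)
    names_in <- c(alias, canon, "Other thing")
    once <- resolveSynonym(names_in, tab)
    expect_identical(resolveSynonym(once, tab), once)
  }
})

test_that("chained or cyclic synonym tables are rejected", {
  expect_error(SynonymTable(c("A b", "C d"), c("C d", "E f")),
               "idempotent")
  expect_error(SynonymTable(c("A b", "C d"), c("C d", "A b")),
               "idempotent")
  ## canonical mapping to itself is fine
  expect_s4_class(SynonymTable(c("A b", "C d"), c("C d", "C d")),
                  "SynonymTable")
})

test_that("rank comparison matches only on shared, known values", {
  syn <- SynonymTable("Aus cus", "Aus bus")
  a <- Lineage(genus = "Aus", species = "Aus bus")
  b <- Lineage(genus = "Aus", species = "Aus cus")
  expect_true(sameTaxonAtRank(a, b, "genus"))
  expect_false(sameTaxonAtRank(a, b, "species"))
  expect_true(sameTaxonAtRank(a, b, "species", syn))
  ## unknown never matches
  expect_false(sameTaxonAtRank(a, Lineage(genus = "Aus"), "species"))
  expect_false(sameTaxonAtRank(Lineage(), Lineage(), "class"))
  expect_error(sameTaxonAtRank(a, b, "kingdom"), "rank")
})

test_that("deepest correct rank walks species to class", {
  truth <- Lineage(class_ = "Insecta", order = "Diptera",
                   family = "Calliphoridae", genus = "Chrysomya",
                   species = "Chrysomya megacephala")
  congener <- Lineage(class_ = "Insecta", order = "Diptera",
                      family = "Calliphoridae", genus = "Chrysomya",
                      species = "Chrysomya saffranea")
  expect_identical(deepestCorrectRank(truth, congener), "genus")
  expect_identical(deepestCorrectRank(truth, truth), "species")
  class_only <- Lineage(class_ = "Insecta", order = "Coleoptera",
                        family = "Carabidae", genus = "Carabus",
                        species = "Carabus auratus")
  expect_identical(deepestCorrectRank(truth, class_only), "class")
  unrelated <- Lineage(class_ = "Agaricomycetes", order = "Agaricales",
                       family = "Amanitaceae", genus = "Amanita",
                       species = "Amanita phalloides")
  expect_identical(deepestCorrectRank(truth, unrelated), NA_character_)
  expect_error(deepestCorrectRank(Lineage(genus = "Aus"), truth),
               "species")
})

test_that("roll-up is monotone for internally consistent lineages", {
  ## whenever species matches, every shallower filled rank matches too
  set.seed(11)
  ranks_shallow <- c("class", "order", "family", "genus")
  for (i in 1:50) {
    shared <- c(class_ = "Insecta", order = "Diptera",
                family = "Calliphoridae", genus = "Chrysomya")
    keep <- setNames(runif(4) < 0.8, names(shared))
    args <- as.list(ifelse(keep, shared, ""))
    args$species <- if (keep[["genus"]]) "Chrysomya megacephala" else ""
    if (!nzchar(args$species)) next
    truth <- do.call(Lineage, as.list(c(shared,
                                        species = "Chrysomya megacephala")))
    assigned <- do.call(Lineage, args)
    if (identical(deepestCorrectRank(truth, assigned), "species")) {
      for (r in ranks_shallow) {
        if (nzchar(lineageRank(assigned, r)))
          expect_true(sameTaxonAtRank(truth, assigned, r))
      }
    }
  }
})

test_that("lineage validity enforces genus-species consistency", {
  expect_error(Lineage(species = "Aus bus"), "genus")
  expect_error(Lineage(genus = "Aus", species = "Bus cus"),
               "begin with the genus")
  expect_s4_class(Lineage(genus = "Aus", species = "Aus bus"),
                  "Lineage")
})
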