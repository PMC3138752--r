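gafRow <- function(entity, term, qualifier = "", evidence = "EXP",
                   taxon = "taxon:9606", db = "FIX") {
  paste(db, entity, entity, qualifier, term, "REF:1", evidence, "", "P",
        "desc", "", "protein", taxon, "20110101", db, "", "", sep = "\t")
}

writeGAF <- function(rows) {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2", rows), path)
  path
}

test_that("GAF reading counts distinct entity-term pairs and honours filters", {
  # one NOT-qualified row among three
  c1 <- readGAF(writeGAF(c(
    gafRow("E1", "GO:0000002"),
    gafRow("E2", "GO:0000002", qualifier = "NOT"),
    gafRow("E2", "GO:0000003"))))
  expect_equal(sum(directCounts(c1)), 2)
  expect_equal(unname(directCounts(c1)["GO:0000002"]), 1)

  # the same entity annotated twice to one term counts once
  c2 <- readGAF(writeGAF(c(
    gafRow("E1", "GO:0000002"),
    gafRow("E1", "GO:0000002", evidence = "IDA"))))
  expect_equal(unname(directCounts(c2)["GO:0000002"]), 1)

  # taxon filtering keeps only matching rows (hand count: 2 human rows)
  mixed <- writeGAF(c(
    gafRow("E1", "GO:0000002", taxon = "taxon:9606"),
    gafRow("E2", "GO:0000002", taxon = "taxon:10090"),
    gafRow("E3", "GO:0000003", taxon = "taxon:9606|taxon:10090")))
  c3 <- readGAF(mixed, taxonFilter = 9606)
  expect_equal(sum(directCounts(c3)), 2)

  # IEA exclusion
  c4 <- readGAF(writeGAF(c(
    gafRow("E1", "GO:0000002", evidence = "IEA"),
    gafRow("E2", "GO:0000002"))), excludeIEA = TRUE)
  expect_equal(sum(directCounts(c4)), 1)
})

test_that("malformed GAF rows are skipped with a warning; all-bad input is fatal", {
  path <- writeGAF(c(gafRow("E1", "GO:0000002"), "short\trow"))
  expect_warning(cts <- readGAF(path), "1 malformed")
  expect_equal(sum(directCounts(cts)), 1)
  allNot <- writeGAF(gafRow("E1", "GO:0000002", qualifier = "NOT"))
  expect_error(suppressWarnings(readGAF(allNot)), "zero usable")
})

test_that("propagation follows the true-path rule with per-entity deduplication", {
  g <- chainGraph()
  c1 <- readGAF(writeGAF(gafRow("E1", "GO:0000003")))
  p1 <- propagatedCounts(propagateCounts(g, c1))
  expect_equal(p1[c("GO:0000001", "GO:0000002", "GO:0000003")],
               c("GO:0000001" = 1, "GO:0000002" = 1, "GO:0000003" = 1))

  # one entity on both children of a parent contributes once to the parent
  d <- diamondGraph()
  c2 <- readGAF(writeGAF(c(gafRow("E1", "GO:0000002"),
                           gafRow("E1", "GO:0000003"))))
  p2 <- propagatedCounts(propagateCounts(d, c2))
  expect_equal(unname(p2["GO:0000001"]), 1)
})

test_that("propagation matches the per-entity ancestor-union oracle", {
  ont <- randomOntology(50, seed = 201)
  ann <- randomAnnotations(ont$graph, 200, seed = 202)
  prop <- propagatedCounts(propagateCounts(ont$graph, ann$counts))

  oracle <- new.env()
  for (terms in ann$counts@entityTerms) {
    reach <- unique(unlist(lapply(unique(terms), function(t)
      c(t, oracleAncestors(ont$graph, t)))))
    for (t in reach)
      oracle[[t]] <- (if (is.null(oracle[[t]])) 0 else oracle[[t]]) + 1
  }
  for (t in ls(oracle))
    expect_equal(unname(prop[t]), oracle[[t]], info = t)
  expect_setequal(names(prop), ls(oracle))
})

test_that("annotations to unresolvable terms are dropped with a warning", {
  g <- chainGraph()
  cts <- readGAF(writeGAF(c(gafRow("E1", "GO:0000003"),
                            gafRow("E2", "GO:0999999"))))
  expect_warning(out <- propagateCounts(g, cts), "GO:0999999")
  expect_equal(unname(propagatedCounts(out)["GO:0000001"]), 1)
})

test_that("information content follows -log relative frequency", {
  fx <- fourEntityIC()
  ic <- fx$ic
  expect_equal(unname(termFrequency(ic, "GO:0000001")), 1)
  expect_equal(unname(termIC(ic, "GO:0000001")), 0)
  expect_equal(unname(termFrequency(ic, "GO:0000002")), 0.75)
  expect_equal(unname(termIC(ic, "GO:0000002")), -log(0.75))
  expect_equal(unname(termIC(ic, "GO:0000003")), -log(0.25))
})

test_that("unannotated terms get the pseudo-count-1 information content", {
  graph <- loadOBO(writeOBO(c(
    oboTerm("GO:0000001", "root"),
    oboTerm("GO:0000002", "A", isa = "GO:0000001"),
    oboTerm("GO:0000005", "unannotated", isa = "GO:0000001"))))
  counts <- readFrequencyTable(writeFreqTable(
    c("GO:0000001" = 4, "GO:0000002" = 1)))
  ic <- informationContent(graph, counts)
  # equals the IC of an annotated term with count 1
  expect_equal(unname(termIC(ic, "GO:0000005")),
               unname(termIC(ic, "GO:0000002")))
  expect_equal(unname(termIC(ic, "GO:0000005")), log(4))
})

test_that("IC is non-decreasing along every root-to-leaf path", {
  ont <- randomOntology(120, seed = 203)
  ann <- randomAnnotations(ont$graph, 300, seed = 204)
  ic <- informationContent(ont$graph,
                           propagateCounts(ont$graph, ann$counts))
  for (t in goTerms(ont$graph))
    for (p in parentTerms(ont$graph, t))
      expect_gte(termIC(ic, t), termIC(ic, p) - 1e-12)
})

test_that("reported percentages equal 100 p(t) to machine precision", {
  fx <- fourEntityIC()
  expect_identical(100 * unname(termFrequency(fx$ic, "GO:0000002")), 75)
})

test_that("frequency tables load verbatim and are validated", {
  cts <- readFrequencyTable(writeFreqTable(
    c("GO:0000001" = 4, "GO:0000002" = 3, "GO:0000003" = 1)))
  expect_equal(propagatedCounts(cts),
               c("GO:0000001" = 4, "GO:0000002" = 3, "GO:0000003" = 1))
  expect_length(directCounts(cts), 0)

  # child exceeding its parent is flagged with the offending edge
  g <- chainGraph()
  bad <- writeFreqTable(c("GO:0000001" = 2, "GO:0000002" = 5))
  expect_warning(readFrequencyTable(bad, graph = g),
                 "GO:0000002 > GO:0000001")

  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(readFrequencyTable(empty), "empty")
  expect_error(readFrequencyTable(writeFreqTable(c("GO:0000001" = -1))),
               "negative")
  dup <- tempfile()
  writeLines(c("GO:0000001\t2", "GO:0000001\t3"), dup)
  expect_error(readFrequencyTable(dup), "duplicate")
})
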