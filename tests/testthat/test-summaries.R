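twoBlockClusters <- function() {
  # four representatives in two loose groups
  ids <- sprintf("GO:%07d", 1:4)
  S <- matrix(0.01, 4, 4, dimnames = list(ids, ids))
  S[1, 2] <- S[2, 1] <- 0.5
  S[3, 4] <- S[4, 3] <- 0.5
  diag(S) <- 1
  m <- asSimilarityMatrix(S)
  rec <- termRecords(ids, value = c(1e-8, 1e-4, 1e-6, 1e-2),
                     valueKind = "p_value")
  cl <- reduceTerms(m, rec, reductionConfig(cutoff = 0.9))  # nothing merges
  list(m = m, rec = rec, cl = cl)
}

test_that("superclusters re-run the reduction at a looser cutoff", {
  fx <- twoBlockClusters()
  expect_length(representatives(fx$cl), 4)

  tree <- buildTreemap(fx$m, fx$cl, records = fx$rec, superCutoff = 0.10)
  expect_length(tree$children, 2)  # the two blocks
  memberSets <- lapply(tree$children, function(sc)
    sort(vapply(sc$children, `[[`, "", "accession")))
  expect_setequal(
    vapply(memberSets, paste, "", collapse = ","),
    c("GO:0000001,GO:0000002", "GO:0000003,GO:0000004"))
  # supercluster labels are the surviving (more significant) terms
  expect_setequal(vapply(tree$children, `[[`, "", "accession"),
                  c("GO:0000001", "GO:0000003"))

  # degenerate cutoff: one supercluster per representative
  flat <- buildTreemap(fx$m, fx$cl, records = fx$rec, superCutoff = 0)
  expect_length(flat$children, 4)
  expect_true(all(vapply(flat$children,
                         function(sc) length(sc$children), 0L) == 1))

  # a single representative yields one supercluster of one leaf
  one <- asSimilarityMatrix(matrix(1, 1, 1,
                                   dimnames = list("GO:0000001",
                                                   "GO:0000001")))
  rec1 <- termRecords("GO:0000001", value = 1e-3, valueKind = "p_value")
  cl1 <- reduceTerms(one, rec1, reductionConfig(cutoff = 0.5))
  t1 <- buildTreemap(one, cl1, records = rec1)
  expect_length(t1$children, 1)
  expect_length(t1$children[[1]]$children, 1)
})

test_that("supercluster count is bounded by the representative count", {
  for (seed in 1:5) {
    m <- randomSimMatrix(10, seed = 1400 + seed, hi = 0.6)
    rec <- termRecords(goTerms(m), valueKind = "none")
    cl <- reduceTerms(m, rec, reductionConfig(cutoff = 0.7))
    tree <- buildTreemap(m, cl, superCutoff = 0.10)
    expect_lte(length(tree$children), length(representatives(cl)))
  }
})

test_that("keyword enrichment scores the smoothed log-odds and drops ties", {
  user <- c("axon guidance", "axon fasciculation", "axon growth")
  bg <- c(user, "ribosome assembly", "proton transport",
          "lipid storage", "axon guidance")
  kw <- keywordEnrichment(user, bg, pseudo = 0.5)
  expect_equal(kw$keyword[1], "axon")
  expect_equal(kw$support[kw$keyword == "axon"], 3L)
  # hand-computed: f_list = 1, f_bg = 4/7
  expect_equal(kw$score[kw$keyword == "axon"],
               log2((1 + 0.5) / (4 / 7 + 0.5)))
  # token with equal fractions scores 0 and is excluded
  same <- keywordEnrichment("axon", "axon")
  expect_equal(nrow(same), 0)
  # ordering and case/whitespace are immaterial
  kw2 <- keywordEnrichment(rev(toupper(user)), bg)
  expect_equal(kw2$score[kw2$keyword == "axon"],
               kw$score[kw$keyword == "axon"])
})

test_that("stopwords and short tokens never appear as keywords", {
  kw <- keywordEnrichment(c("regulation of cell growth by the X"),
                          c("unrelated term"))
  expect_false(any(kw$keyword %in%
                     c("regulation", "cell", "of", "the", "by")))
})

test_that("keyword-value correlation matches the point-biserial formula", {
  nm <- c("synapse assembly", "synapse pruning", "synapse organization",
          "lipid storage", "lipid transport", "lipid oxidation")
  pv <- c(1e-8, 1e-7, 1e-9, 1e-2, 1e-3, 1e-1)
  rec <- termRecords(sprintf("GO:%07d", 1:6), value = pv,
                     valueKind = "p_value")
  kw <- keywordValueCorrelation(rec, nm)
  # independent oracle: r = (M1 - M0)/s_n * sqrt(n1 n0 / n^2)
  x <- -log10(pv)
  ind <- c(1, 1, 1, 0, 0, 0)  # "synapse"
  n <- 6; n1 <- 3; n0 <- 3
  sn <- sqrt(sum((x - mean(x))^2) / (n - 1))
  rOracle <- (mean(x[ind == 1]) - mean(x[ind == 0])) / sn *
    sqrt(n1 * n0 / (n * (n - 1)))
  expect_equal(kw$score[kw$keyword == "synapse"], rOracle,
               tolerance = 1e-9)
  # the token present only in the significant half scores positively
  expect_gt(kw$score[kw$keyword == "synapse"], 0)
  expect_lt(kw$score[kw$keyword == "lipid"], 0)

  # constant values carry no signal
  recConst <- termRecords(sprintf("GO:%07d", 1:6),
                          value = rep(1e-3, 6), valueKind = "p_value")
  kwConst <- keywordValueCorrelation(recConst, nm)
  expect_true(all(kwConst$score == 0))

  expect_error(
    keywordValueCorrelation(termRecords(sprintf("GO:%07d", 1:6),
                                        valueKind = "none"), nm),
    "values")
})

test_that("treemaps serialize to JSON and TSV and sizes follow the mode", {
  fx <- twoBlockClusters()
  ids <- goTerms(fx$m)
  graph <- loadOBO(writeOBO(c(
    oboTerm("GO:0000001", "rootish"),
    oboTerm("GO:0000002", "a", isa = "GO:0000001"),
    oboTerm("GO:0000003", "b", isa = "GO:0000001"),
    oboTerm("GO:0000004", "c", isa = "GO:0000001"))))
  ic <- informationContent(graph, readFrequencyTable(writeFreqTable(
    c("GO:0000001" = 10, "GO:0000002" = 5,
      "GO:0000003" = 2, "GO:0000004" = 1))))

  tv <- buildTreemap(fx$m, fx$cl, records = fx$rec, ic = ic,
                     sizeMode = "value")
  tf <- buildTreemap(fx$m, fx$cl, records = fx$rec, ic = ic,
                     sizeMode = "frequency")
  leafSize <- function(tree, acc) {
    for (sc in tree$children)
      for (leaf in sc$children)
        if (leaf$accession == acc) return(leaf$size)
    NA_real_
  }
  expect_equal(leafSize(tv, "GO:0000002"), -log10(1e-4))
  expect_equal(leafSize(tf, "GO:0000002"), 100 * 5 / 10)
  # structure is unchanged by the size mode
  expect_equal(vapply(tv$children, `[[`, "", "accession"),
               vapply(tf$children, `[[`, "", "accession"))

  jsonPath <- tempfile(fileext = ".json")
  writeTreemap(tv, jsonPath, format = "json")
  back <- jsonlite::fromJSON(jsonPath, simplifyVector = FALSE)
  expect_equal(back$label, "root")
  expect_length(back$children, length(tv$children))
  expect_equal(back$children[[1]]$children[[1]]$size,
               tv$children[[1]]$children[[1]]$size)

  tsvPath <- tempfile(fileext = ".tsv")
  writeTreemap(tv, tsvPath, format = "tsv")
  tab <- read.delim(tsvPath)
  expect_equal(nrow(tab), 4)  # one row per leaf
  expect_equal(names(tab), c("supercluster", "representative", "size"))

  # a one-leaf tree writes a single row
  one <- list(label = "root", children = list(
    list(label = "x", accession = "GO:0000001", children = list(
      list(label = "x", accession = "GO:0000001", size = 2)))))
  p1 <- tempfile(fileext = ".tsv")
  writeTreemap(one, p1, format = "tsv")
  expect_equal(nrow(read.delim(p1)), 1)
})
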