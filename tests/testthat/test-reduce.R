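test_that("uniqueness is the negative mean off-diagonal similarity", {
  n <- 4
  ids <- sprintf("GO:%07d", 1:n)
  S <- matrix(0.5, n, n, dimnames = list(ids, ids)); diag(S) <- 1
  m <- asSimilarityMatrix(S)
  expect_equal(unname(termUniqueness(m, ids[2])), -0.5)

  Z <- matrix(0, n, n, dimnames = list(ids, ids)); diag(Z) <- 1
  expect_equal(unname(termUniqueness(asSimilarityMatrix(Z), ids)),
               rep(0, n))

  # hand-computed row means on an asymmetric-looking but symmetric matrix
  V <- matrix(c(1, .2, .4, .6,
                .2, 1, .1, .3,
                .4, .1, 1, .5,
                .6, .3, .5, 1), n, n, dimnames = list(ids, ids))
  u <- termUniqueness(asSimilarityMatrix(V))
  expect_equal(unname(u[ids[1]]), -(0.2 + 0.4 + 0.6) / 3)
  expect_equal(unname(u[ids[4]]), -(0.6 + 0.3 + 0.5) / 3)

  expect_error(termUniqueness(m, "GO:9999999"), "not in similarity matrix")
})

test_that("the loser cascade honours pinning, values, generality and ancestry", {
  cfg <- reductionConfig(cutoff = 0.5)

  # pinning beats everything, including a much better p-value
  rec <- termRecords(c("GO:0000002", "GO:0000003"),
                     value = c(1e-10, 1e-2), valueKind = "p_value",
                     pinned = c(FALSE, TRUE))
  expect_equal(chooseLoser("GO:0000002", "GO:0000003", rec, cfg),
               "GO:0000002")
  recBoth <- termRecords(c("GO:0000002", "GO:0000003"),
                         value = c(1e-10, 1e-2), valueKind = "p_value",
                         pinned = c(TRUE, TRUE))
  expect_error(chooseLoser("GO:0000002", "GO:0000003", recBoth, cfg),
               "pinned")

  # decisively different p-values: the weaker one loses
  rec2 <- termRecords(c("GO:0000002", "GO:0000003"),
                      value = c(1e-6, 1e-2), valueKind = "p_value")
  expect_equal(chooseLoser("GO:0000002", "GO:0000003", rec2, cfg),
               "GO:0000003")

  # a very general term is avoided as representative even when more significant
  fx <- fourEntityIC()  # A has frequency 0.75 > 0.25, B has 0.25
  rec3 <- termRecords(c("GO:0000002", "GO:0000003"),
                      value = c(1e-9, 1e-2), valueKind = "p_value")
  expect_equal(chooseLoser("GO:0000002", "GO:0000003", rec3, cfg,
                           graph = fx$graph, ic = fx$ic),
               "GO:0000002")

  # close p-values + ancestry: the child is removed, keeping the parent
  g <- loadOBO(writeOBO(c(
    oboTerm("GO:0000001", "root"),
    oboTerm("GO:0000002", "parent", isa = "GO:0000001"),
    oboTerm("GO:0000003", "child", isa = "GO:0000002"))))
  icLow <- informationContent(g, readFrequencyTable(writeFreqTable(
    c("GO:0000001" = 100, "GO:0000002" = 20, "GO:0000003" = 10))))
  rec4 <- termRecords(c("GO:0000002", "GO:0000003"),
                      value = c(1e-4, 2e-4), valueKind = "p_value")
  expect_equal(chooseLoser("GO:0000002", "GO:0000003", rec4, cfg,
                           graph = g, ic = icLow),
               "GO:0000003")

  # ... unless the child makes up >75% of the parent: the parent is rejected
  icHigh <- informationContent(g, readFrequencyTable(writeFreqTable(
    c("GO:0000001" = 100, "GO:0000002" = 20, "GO:0000003" = 18))))
  expect_equal(chooseLoser("GO:0000002", "GO:0000003", rec4, cfg,
                           graph = g, ic = icHigh),
               "GO:0000002")
})

test_that("the worked example reduces to four clusters with the published dispensability", {
  fx <- workedExampleFixture()
  cl <- reduceTerms(fx$matrix, fx$records, reductionConfig(cutoff = 0.5))
  expect_length(representatives(cl), 4)
  sizes <- table(memberOf(cl))
  expect_equal(sum(sizes == 1), 2)
  expect_setequal(names(sizes)[sizes == 1], c("GO:0042053", "GO:0007606"))
  expect_setequal(representatives(cl),
                  c("GO:0021537", "GO:0045686", "GO:0042053", "GO:0007606"))
  expect_equal(unname(dispensability(cl)["GO:0021895"]), 0.72)
  expect_equal(unname(memberOf(cl)["GO:0021895"]), "GO:0021537")
  # merge log in decreasing-similarity order
  expect_equal(mergeLog(cl)$similarity, c(0.74, 0.72, 0.62))
})

test_that("with all similarities below C every term is its own representative", {
  m <- randomSimMatrix(6, seed = 401, hi = 0.3)
  rec <- termRecords(goTerms(m), valueKind = "none")
  cl <- reduceTerms(m, rec, reductionConfig(cutoff = 0.5))
  expect_setequal(representatives(cl), goTerms(m))
  expect_equal(nrow(mergeLog(cl)), 0)
  expect_equal(unname(memberOf(cl)), names(memberOf(cl)))
})

test_that("without values, uniqueness decides and outliers survive", {
  ids <- sprintf("GO:%07d", 1:3)
  S <- matrix(c(1, .8, .1,
                .8, 1, .15,
                .1, .15, 1), 3, 3, dimnames = list(ids, ids))
  m <- asSimilarityMatrix(S)
  rec <- termRecords(ids, valueKind = "none")
  cl <- reduceTerms(m, rec, reductionConfig(cutoff = 0.5))
  # the outlier (lowest mean similarity) is a representative
  expect_true(ids[3] %in% representatives(cl))
  # of the merged pair, the more unique member survives
  u <- termUniqueness(m)
  merged <- mergeLog(cl)
  expect_equal(merged$removed,
               ids[which.min(u[1:2])])

  ranking <- uniquenessRanking(m, rec)
  expect_equal(ranking[1], names(which.max(u)))
  expect_error(uniquenessRanking(m, termRecords(ids, value = c(.1, .2, .3),
                                                valueKind = "p_value")),
               "no user values")
})

test_that("equal uniqueness falls back to the lexicographic tie-break", {
  ids <- c("GO:0000001", "GO:0000002")
  S <- matrix(c(1, .9, .9, 1), 2, 2, dimnames = list(ids, ids))
  rec <- termRecords(ids, valueKind = "none")
  cl <- reduceTerms(asSimilarityMatrix(S), rec,
                    reductionConfig(cutoff = 0.5))
  expect_equal(representatives(cl), "GO:0000001")
})

test_that("three-term reduction matches a brute-force cascade enumeration", {
  ids <- sprintf("GO:%07d", 1:3)
  S <- matrix(c(1, .9, .6,
                .9, 1, .7,
                .6, .7, 1), 3, 3, dimnames = list(ids, ids))
  m <- asSimilarityMatrix(S)
  rec <- termRecords(ids, valueKind = "none")
  C <- 0.5

  # independent re-enactment: repeatedly merge the top pair, keeping the
  # higher-uniqueness term (uniqueness from the full matrix)
  u <- termUniqueness(m)
  reps <- ids
  repeat {
    if (length(reps) < 2) break
    sub <- S[reps, reps, drop = FALSE]; diag(sub) <- -Inf
    if (max(sub) < C) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- sort(reps[hit])
    loser <- pair[which.min(u[pair])]
    reps <- setdiff(reps, loser)
  }
  cl <- reduceTerms(m, rec, reductionConfig(cutoff = C))
  expect_setequal(representatives(cl), reps)
})

test_that("no two final representatives are as similar as the cutoff", {
  for (seed in 1:8) {
    m <- randomSimMatrix(15, seed = 500 + seed)
    set.seed(600 + seed)
    rec <- termRecords(goTerms(m), value = 10^-runif(15, 0.1, 10),
                       valueKind = "p_value")
    for (C in c(0.9, 0.5)) {
      cl <- reduceTerms(m, rec, reductionConfig(cutoff = C))
      reps <- representatives(cl)
      if (length(reps) > 1) {
        sub <- simValues(m)[reps, reps]; diag(sub) <- 0
        expect_lt(max(sub), C)
      }
      expect_true(all(dispensability(cl)[reps] < C))
      removed <- setdiff(goTerms(m), reps)
      expect_true(all(dispensability(cl)[removed] >= C))
      # termination bound: at most n - 1 merges
      expect_lte(nrow(mergeLog(cl)), 14)
    }
  }
})

test_that("representative counts never increase as C tightens", {
  cuts <- c(0.9, 0.7, 0.5, 0.4)
  for (seed in 1:20) {
    m <- randomSimMatrix(12, seed = 700 + seed)
    set.seed(800 + seed)
    rec <- termRecords(goTerms(m), value = 10^-runif(12, 0.1, 8),
                       valueKind = "p_value")
    counts <- vapply(cuts, function(C)
      length(representatives(reduceTerms(m, rec,
                                         reductionConfig(cutoff = C)))),
      0L)
    expect_true(all(diff(counts) <= 0),
                info = paste("seed", seed, ":",
                             paste(counts, collapse = " ")))
  }
})

test_that("pinned terms always end as representatives", {
  for (seed in 1:10) {
    m <- randomSimMatrix(10, seed = 900 + seed)
    set.seed(1000 + seed)
    pin <- sample(10, 1)
    rec <- termRecords(goTerms(m), value = 10^-runif(10, 0.1, 8),
                       valueKind = "p_value",
                       pinned = seq_len(10) == pin)
    cl <- tryCatch(
      reduceTerms(m, rec, reductionConfig(cutoff = 0.5)),
      error = function(e) NULL)  # only an (impossible) double pin may fail
    expect_false(is.null(cl))
    expect_true(goTerms(m)[pin] %in% representatives(cl))
  }
})

test_that("dispensability and uniqueness are anticorrelated on average", {
  cors <- vapply(1:50, function(seed) {
    m <- randomSimMatrix(12, seed = 1100 + seed)
    set.seed(1200 + seed)
    rec <- termRecords(goTerms(m), value = 10^-runif(12, 0.1, 8),
                       valueKind = "p_value")
    cl <- reduceTerms(m, rec, reductionConfig(cutoff = 0.5))
    suppressWarnings(cor(dispensability(cl)[goTerms(m)],
                         termUniqueness(cl)[goTerms(m)],
                         method = "spearman"))
  }, 0)
  expect_lte(mean(cors, na.rm = TRUE), 0)
})

test_that("empty input yields an empty result", {
  m <- randomSimMatrix(3, seed = 1)
  cl <- reduceTerms(m, termRecords(character(0), valueKind = "none"),
                    reductionConfig(cutoff = 0.5))
  expect_length(representatives(cl), 0)
  expect_equal(nrow(mergeLog(cl)), 0)
})
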