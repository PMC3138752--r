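# Shared fixture builders and independent oracles.

writeOBO <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

oboTerm <- function(id, name = id, ns = "biological_process",
                    isa = character(0), rel = character(0),
                    extra = character(0)) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    if (!is.na(ns)) paste0("namespace: ", ns),
    paste0("is_a: ", isa), paste0("relationship: ", rel), extra, "")
}

# root <- mid <- leaf via is_a
chainGraph <- function() {
  loadOBO(writeOBO(c(
    oboTerm("GO:0000001", "root"),
    oboTerm("GO:0000002", "mid", isa = "GO:0000001"),
    oboTerm("GO:0000003", "leaf", isa = "GO:0000002"))))
}

# leaf with two parents sharing a single grandparent (the root)
diamondGraph <- function() {
  loadOBO(writeOBO(c(
    oboTerm("GO:0000001", "grandparent"),
    oboTerm("GO:0000002", "parentA", isa = "GO:0000001"),
    oboTerm("GO:0000003", "parentB", isa = "GO:0000001"),
    oboTerm("GO:0000004", "leaf", isa = c("GO:0000002", "GO:0000003")))))
}

writeFreqTable <- function(counts) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(names(counts), counts, sep = "\t"), path)
  path
}

# root(4) with children A(3) and B(1): the hand-arithmetic IC fixture
fourEntityIC <- function() {
  graph <- loadOBO(writeOBO(c(
    oboTerm("GO:0000001", "root"),
    oboTerm("GO:0000002", "A", isa = "GO:0000001"),
    oboTerm("GO:0000003", "B", isa = "GO:0000001"))))
  counts <- readFrequencyTable(writeFreqTable(
    c("GO:0000001" = 4, "GO:0000002" = 3, "GO:0000003" = 1)))
  list(graph = graph, ic = informationContent(graph, counts))
}

# independent recursive parent-walk oracle for ancestor sets
oracleAncestors <- function(graph, acc) {
  par <- parentTerms(graph, acc)
  if (!length(par)) return(character(0))
  sort(unique(c(par, unlist(lapply(par, oracleAncestors, graph = graph)))))
}

# brute-force MICA over the intersection of ancestor-or-self sets
oracleMica <- function(graph, ic, a, b) {
  common <- intersect(c(a, oracleAncestors(graph, a)),
                      c(b, oracleAncestors(graph, b)))
  if (!length(common)) return(NA_character_)
  icc <- termIC(ic, common)
  sort(common[icc == max(icc)])[1]
}

# random symmetric similarity matrix in [0, 0.95] with unit diagonal
randomSimMatrix <- function(n, seed, hi = 0.95) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  R <- matrix(runif(n * n, 0, hi), n, n)
  S <- (R + t(R)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  asSimilarityMatrix(S)
}
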