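#' Generate a random single-namespace ontology
#'
#' Builds a rooted DAG of \code{nTerms} terms in one namespace: the first
#' term is the root and every later term attaches to one or (with
#' probability \code{prob2Parents}) two uniformly chosen earlier terms,
#' which guarantees acyclicity and a single root.  The ontology is emitted
#' as OBO 1.2 text and re-parsed through \code{\link{loadOBO}}, so the
#' returned graph is exactly what the production reader yields.  Fully
#' deterministic under the seed.
#'
#' @param nTerms number of terms (>= 3).
#' @param seed mandatory integer seed.
#' @param prob2Parents probability a non-root term gets a second parent
#'   (default 0.3).
#' @param namespace namespace name for all terms.
#' @param prefix accession prefix (default \code{"GO"}); ids are
#'   zero-padded to seven digits starting at 7000001 so they cannot clash
#'   with real GO accessions in mixed fixtures.
#' @return list with \code{obo} (character vector of OBO lines) and
#'   \code{graph} (the parsed \linkS4class{OntologyGraph}).
#' @export
randomOntology <- function(nTerms, seed, prob2Parents = 0.3,
                           namespace = "biological_process",
                           prefix = "GO") {
  stopifnot(nTerms >= 3)
  if (missing(seed)) stop("a seed is required")
  ids <- sprintf("%s:%07d", prefix, 7000000L + seq_len(nTerms))
  parents <- vector("list", nTerms)
  .withSeed(seed, {
    for (i in seq_len(nTerms)[-1]) {
      nPar <- if (i > 2 && stats::runif(1) < prob2Parents) 2L else 1L
      parents[[i]] <- ids[sample.int(i - 1L, min(nPar, i - 1L))]
    }
  })
  lines <- c("format-version: 1.2", "ontology: synthetic-fixture", "")
  for (i in seq_len(nTerms)) {
    lines <- c(lines, "[Term]",
               paste0("id: ", ids[i]),
               paste0("name: synthetic term ", i),
               paste0("namespace: ", namespace))
    for (p in parents[[i]])
      lines <- c(lines, paste0("is_a: ", p, " ! parent"))
    lines <- c(lines, "")
  }
  obo <- tempfile(fileext = ".obo")
  writeLines(lines, obo)
  graph <- loadOBO(obo)
  unlink(obo)
  list(obo = lines, graph = graph)
}

#' Generate random annotations for a fixture ontology
#'
#' Annotates \code{nEntities} synthetic entities to terms of the graph
#' with leaf-biased, power-law popularity: term weights follow
#' rank^(-concentration) over a seeded permutation of the non-root terms,
#' with leaves upweighted threefold, so a higher concentration focuses the
#' corpus on fewer terms and spreads the information-content distribution.
#' Each entity receives one to three annotations.  The corpus is emitted
#' as GAF 2.2 text and parsed back through \code{\link{readGAF}}.
#'
#' @param graph an \linkS4class{OntologyGraph} (from
#'   \code{\link{randomOntology}}).
#' @param nEntities number of annotated entities.
#' @param seed mandatory integer seed.
#' @param concentration power-law exponent (default 1.5); larger values
#'   concentrate annotations on fewer terms.
#' @param taxon taxon id written in the GAF rows (default 9606).
#' @return list with \code{gaf} (character vector of GAF lines) and
#'   \code{counts} (the parsed \linkS4class{AnnotationCounts}).
#' @export
randomAnnotations <- function(graph, nEntities, seed, concentration = 1.5,
                              taxon = 9606) {
  if (missing(seed)) stop("a seed is required")
  live <- graph@terms[!graph@obsolete]
  roots <- unlist(graph@roots, use.names = FALSE)
  cand <- setdiff(live, roots)
  if (!length(cand)) cand <- live
  hasChild <- unique(unlist(graph@parents[live], use.names = FALSE))
  isLeaf <- !(cand %in% hasChild)

  rows <- character(0)
  .withSeed(seed, {
    rank <- sample.int(length(cand))
    w <- rank^(-concentration) * ifelse(isLeaf, 3, 1)
    w <- w / sum(w)
    for (e in seq_len(nEntities)) {
      k <- sample.int(3L, 1L)
      terms <- sample(cand, min(k, length(cand)), prob = w)
      ent <- sprintf("E%05d", e)
      rows <- c(rows, vapply(terms, function(t) paste(
        "FIX", ent, ent, "", t, "FIX:ref", "EXP", "", "P",
        paste("synthetic entity", e), "", "protein",
        paste0("taxon:", taxon), "20110101", "FIX", "", "",
        sep = "\t"), ""))
    }
  })
  gaf <- c("!gaf-version: 2.2", rows)
  path <- tempfile(fileext = ".gaf")
  writeLines(gaf, path)
  counts <- readGAF(path)
  unlink(path)
  list(gaf = gaf, counts = counts)
}

#' The seven-term worked example
#'
#' A reconstruction of the published table of seven gene-functional
#' categories co-expressed with the human transcription factor ZNF417
#' (brain-development biology), used throughout as a compact end-to-end
#' fixture.  The similarity matrix contains the published SimRel values:
#' cerebral cortex neuron differentiation vs telencephalon development
#' 0.72, astrocyte differentiation vs negative regulation of glial cell
#' differentiation 0.74, negative regulation of neuron differentiation vs
#' the same 0.62, and the highest remaining similarity 0.40 placed between
#' the two non-singleton cluster representatives (telencephalon
#' development and negative regulation of glial cell differentiation).
#' All other off-diagonal entries are set to 0.10, well below every
#' published value and every preset cutoff.  The p-values are synthetic:
#' only their ordering is known (the representatives are the more
#' significant terms), so they are spaced two orders of magnitude apart to
#' keep every comparison decisively outside the value-closeness tolerance,
#' matching the published narrative in which significance alone selects
#' the representatives.
#'
#' At cutoff C = 0.5 the reduction yields four clusters, two of them
#' singletons (regulation of dopamine metabolic process and sensory
#' perception of chemical stimulus), with dispensability 0.72 for the
#' merged cortex term.
#'
#' @return list with \code{matrix} (a \linkS4class{SimilarityMatrix}),
#'   \code{records} (term records with p-values) and \code{names} (named
#'   character, accession -> term name).
#' @export
workedExampleFixture <- function() {
  acc <- c(telencephalon = "GO:0021537",
           cortex = "GO:0021895",
           astrocyte = "GO:0048708",
           negNeuron = "GO:0045665",
           negGlial = "GO:0045686",
           dopamine = "GO:0042053",
           sensory = "GO:0007606")
  nms <- c("telencephalon development",
           "cerebral cortex neuron differentiation",
           "astrocyte differentiation",
           "negative regulation of neuron differentiation",
           "negative regulation of glial cell differentiation",
           "regulation of dopamine metabolic process",
           "sensory perception of chemical stimulus")
  names(nms) <- unname(acc)

  n <- length(acc)
  M <- matrix(0.10, n, n, dimnames = list(unname(acc), unname(acc)))
  diag(M) <- 1
  set <- function(i, j, v) {
    M[acc[[i]], acc[[j]]] <<- v
    M[acc[[j]], acc[[i]]] <<- v
  }
  set("cortex", "telencephalon", 0.72)
  set("astrocyte", "negGlial", 0.74)
  set("negNeuron", "negGlial", 0.62)
  set("telencephalon", "negGlial", 0.40)

  pvals <- c(telencephalon = 1e-9, cortex = 1e-7,
             astrocyte = 1e-6, negNeuron = 1e-5, negGlial = 1e-8,
             dopamine = 1e-4, sensory = 1e-3)

  records <- termRecords(unname(acc), value = unname(pvals[names(acc)]),
                         valueKind = "p_value")
  list(matrix = asSimilarityMatrix(M, measure = "simrel"),
       records = records,
       names = nms)
}
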