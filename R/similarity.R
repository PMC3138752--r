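.SIM_MEASURES <- c("simrel", "lin", "resnik", "jiang_conrath")

#' Most informative common ancestor (MICA) of two terms
#'
#' The shared ancestor of \code{a} and \code{b} (each term counts as its own
#' ancestor, so a term subsuming the other can itself be the MICA) with the
#' maximal information content; ties are broken by the lexicographically
#' smallest accession.  Terms of different namespaces share no ancestors
#' and raise an error.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param ic an \linkS4class{ICTable}.
#' @param a,b accessions in the same namespace.
#' @return the MICA accession, or \code{NA_character_} when the two terms
#'   share no ancestor (possible in multi-rooted fixture namespaces).
#' @export
mica <- function(graph, ic, a, b) {
  .checkKnown(graph, c(a, b))
  if (graph@termNamespace[[a]] != graph@termNamespace[[b]])
    stop("MICA is undefined across namespaces: ", a, " vs ", b)
  common <- intersect(c(a, ancestors(graph, a)), c(b, ancestors(graph, b)))
  if (!length(common)) return(NA_character_)
  icc <- termIC(ic, common)
  best <- common[icc == max(icc)]
  sort(best)[1]
}

.similarityFromIC <- function(icA, icB, icM, pM, measure) {
  switch(measure,
    resnik = icM,
    lin = if (icA + icB <= 0) 0 else 2 * icM / (icA + icB),
    simrel = {
      lin <- if (icA + icB <= 0) 0 else 2 * icM / (icA + icB)
      lin * (1 - pM)
    },
    jiang_conrath = 1 / (1 + icA + icB - 2 * icM),
    stop("unknown similarity measure: ", measure))
}

#' Pairwise semantic similarity between two terms
#'
#' With m the most informative common ancestor of \code{a} and \code{b}:
#' \itemize{
#'   \item Resnik: IC(m)
#'   \item Lin: 2 IC(m) / (IC(a) + IC(b)), defined as 0 when both IC are 0
#'   \item SimRel: Lin's score multiplied by (1 - p(m)), which down-weights
#'     pairs whose only shared ancestors are frequent, shallow terms
#'   \item Jiang-Conrath: the distance IC(a) + IC(b) - 2 IC(m) mapped to the
#'     bounded similarity 1/(1 + d)
#' }
#' All four are symmetric and deterministic.  Terms of different
#' namespaces raise an error (their similarity is 0 by convention in
#' \code{\link{similarityMatrix}}).
#'
#' @param ic an \linkS4class{ICTable}.
#' @param graph an \linkS4class{OntologyGraph}.
#' @param a,b accessions in the same namespace.
#' @param measure one of \code{"simrel"} (default), \code{"lin"},
#'   \code{"resnik"}, \code{"jiang_conrath"}.
#' @return a numeric score.
#' @export
termSimilarity <- function(ic, graph, a, b,
                           measure = c("simrel", "lin", "resnik",
                                       "jiang_conrath")) {
  measure <- match.arg(measure)
  m <- mica(graph, ic, a, b)
  icA <- unname(termIC(ic, a)); icB <- unname(termIC(ic, b))
  if (is.na(m)) {
    icM <- 0; pM <- 1  # no shared information
  } else {
    icM <- unname(termIC(ic, m)); pM <- unname(termFrequency(ic, m))
  }
  .similarityFromIC(icA, icB, icM, pM, measure)
}

#' Pairwise similarity matrix over a term list
#'
#' Computes all pairwise scores under one measure.  The ordering of the
#' input list is preserved; entries between terms of different namespaces
#' are 0; the diagonal carries the measure's self-similarity (Lin/SimRel by
#' their formulas, Resnik the term's own IC) but is never consulted by the
#' downstream clustering.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param ic an \linkS4class{ICTable}.
#' @param terms character vector of accessions (no duplicates).
#' @param measure similarity measure, default \code{"simrel"}.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
similarityMatrix <- function(graph, ic, terms,
                             measure = c("simrel", "lin", "resnik",
                                         "jiang_conrath")) {
  measure <- match.arg(measure)
  if (anyDuplicated(terms))
    stop("duplicate accession in term list: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  .checkKnown(graph, terms)
  n <- length(terms)
  vals <- matrix(0, n, n, dimnames = list(terms, terms))
  if (n) {
    anc <- .ancestorSets(graph, terms)
    nsv <- graph@termNamespace[terms]
    icv <- termIC(ic, terms)
    for (i in seq_len(n)) {
      selfM <- terms[i]
      vals[i, i] <- .similarityFromIC(
        icv[[i]], icv[[i]], icv[[i]],
        unname(termFrequency(ic, selfM)), measure)
      if (i == n) next
      withI <- c(terms[i], anc[[i]])
      for (j in seq(i + 1L, n)) {
        if (nsv[[i]] != nsv[[j]]) next
        common <- intersect(withI, c(terms[j], anc[[j]]))
        if (!length(common)) {
          icM <- 0; pM <- 1
        } else {
          icc <- termIC(ic, common)
          m <- sort(common[icc == max(icc)])[1]
          icM <- unname(termIC(ic, m)); pM <- unname(termFrequency(ic, m))
        }
        s <- .similarityFromIC(icv[[i]], icv[[j]], icM, pM, measure)
        vals[i, j] <- s
        vals[j, i] <- s
      }
    }
  }
  new("SimilarityMatrix", terms = terms, values = vals, measure = measure)
}

#' Construct a SimilarityMatrix from precomputed values
#'
#' Lets externally supplied or published similarity values (for instance a
#' printed worked example) be injected into the reduction pipeline without
#' an ontology.
#'
#' @param values symmetric numeric matrix with accession dimnames.
#' @param measure the measure the values were computed under.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
asSimilarityMatrix <- function(values, measure = "simrel") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  new("SimilarityMatrix",
      terms = rownames(values), values = values, measure = measure)
}

#' Background similarity quantile from random term pairs
#'
#' Draws random within-namespace pairs of distinct, non-obsolete terms
#' (uniformly, with replacement across draws) and returns the similarity
#' value exceeded by exactly \code{percentile} percent of the sampled
#' pairs — the empirical upper quantile of the background similarity
#' distribution.  This calibrates the cutoff C against chance: a cutoff at
#' the 1 percent background quantile means above-background similarity
#' within clusters at the 99 percent level.  The threshold depends on the
#' ontology and annotation snapshot in use.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param ic an \linkS4class{ICTable}.
#' @param measure similarity measure, default \code{"simrel"}.
#' @param percentile upper-tail percentage in (0, 100).
#' @param nPairs number of sampled pairs (>= 100).
#' @param seed integer seed; the draw is fully reproducible.
#' @return the similarity threshold (numeric scalar).
#' @export
backgroundQuantile <- function(graph, ic,
                               measure = c("simrel", "lin", "resnik",
                                           "jiang_conrath"),
                               percentile = 1, nPairs = 10000, seed) {
  measure <- match.arg(measure)
  stopifnot(percentile > 0, percentile <= 100)
  if (nPairs < 100) stop("nPairs must be at least 100")
  if (missing(seed)) stop("a seed is required for reproducible sampling")

  live <- graph@terms[!graph@obsolete]
  byNs <- split(live, graph@termNamespace[live])
  byNs <- byNs[vapply(byNs, length, 0L) >= 2]
  if (!length(byNs))
    stop("ontology has fewer than 2 non-obsolete terms in every namespace")

  pool <- unlist(byNs, use.names = FALSE)
  nsOf <- graph@termNamespace[pool]
  sims <- numeric(nPairs)
  .withSeed(seed, {
    aIdx <- sample.int(length(pool), nPairs, replace = TRUE)
    for (k in seq_len(nPairs)) {
      a <- pool[aIdx[k]]
      mates <- byNs[[nsOf[aIdx[k]]]]
      repeat {
        b <- mates[sample.int(length(mates), 1L)]
        if (b != a) break
      }
      sims[k] <- termSimilarity(ic, graph, a, b, measure)
    }
  })
  unname(stats::quantile(sims, probs = 1 - percentile / 100,
                         type = 1, names = FALSE))
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
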