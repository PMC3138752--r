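#' Accessions of the terms in an object
#' @param x an \linkS4class{OntologyGraph}, \linkS4class{SimilarityMatrix}
#'   or \linkS4class{TermClusters}.
#' @param ... unused.
#' @return character vector of accessions.
#' @export
setGeneric("goTerms", function(x, ...) standardGeneric("goTerms"))

#' Human-readable term names
#' @param x an \linkS4class{OntologyGraph}.
#' @param accession accessions to look up; defaults to all terms.
#' @return named character vector.
#' @export
setGeneric("termName", function(x, accession) standardGeneric("termName"))

#' Namespace of terms
#' @param x an \linkS4class{OntologyGraph}.
#' @param accession accessions to look up; defaults to all terms.
#' @return named character vector.
#' @export
setGeneric("termNamespace",
           function(x, accession) standardGeneric("termNamespace"))

#' Direct parent terms used for traversal
#' @param x an \linkS4class{OntologyGraph}.
#' @param accession a single accession.
#' @return character vector of parent accessions.
#' @export
setGeneric("parentTerms", function(x, accession) standardGeneric("parentTerms"))

#' All ancestors of a term
#'
#' Every term reachable from \code{accession} by repeatedly following parent
#' edges, excluding the query term itself; the namespace root is included.
#'
#' @param x an \linkS4class{OntologyGraph}.
#' @param accession a single resolvable, non-obsolete accession.
#' @return character vector of ancestor accessions (possibly empty).
#' @export
setGeneric("ancestors", function(x, accession) standardGeneric("ancestors"))

#' Namespace roots
#' @param x an \linkS4class{OntologyGraph}.
#' @return named list, namespace -> root accessions.
#' @export
setGeneric("nsRoots", function(x) standardGeneric("nsRoots"))

#' Direct annotation counts
#' @param x an \linkS4class{AnnotationCounts}.
#' @return named numeric vector.
#' @export
setGeneric("directCounts", function(x) standardGeneric("directCounts"))

#' Propagated annotation counts
#' @param x an \linkS4class{AnnotationCounts}.
#' @return named numeric vector.
#' @export
setGeneric("propagatedCounts",
           function(x) standardGeneric("propagatedCounts"))

#' Relative annotation frequency p(t)
#' @param x an \linkS4class{ICTable}.
#' @param accession accessions to look up; defaults to all.
#' @return named numeric vector in (0, 1].
#' @export
setGeneric("termFrequency",
           function(x, accession) standardGeneric("termFrequency"))

#' Information content IC(t) = -log p(t)
#' @param x an \linkS4class{ICTable}.
#' @param accession accessions to look up; defaults to all.
#' @return named numeric vector.
#' @export
setGeneric("termIC", function(x, accession) standardGeneric("termIC"))

#' Similarity measure of a matrix
#' @param x a \linkS4class{SimilarityMatrix}.
#' @return a length-1 character.
#' @export
setGeneric("simMeasure", function(x) standardGeneric("simMeasure"))

#' Numeric values of a similarity matrix
#' @param x a \linkS4class{SimilarityMatrix}.
#' @return symmetric numeric matrix with accession dimnames.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' Cluster representatives
#' @param x a \linkS4class{TermClusters}.
#' @return character vector of representative accessions.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' Cluster membership map
#' @param x a \linkS4class{TermClusters}.
#' @return named character, accession -> representative accession.
#' @export
setGeneric("memberOf", function(x) standardGeneric("memberOf"))

#' Dispensability values
#' @param x a \linkS4class{TermClusters}.
#' @return named numeric, accession -> dispensability in [0, 1].
#' @export
setGeneric("dispensability", function(x) standardGeneric("dispensability"))

#' Uniqueness: negative mean similarity to all other terms
#'
#' For a \linkS4class{SimilarityMatrix} the value is computed as the
#' negative of the mean off-diagonal similarity involving each term (0 for a
#' single-term matrix); for a \linkS4class{TermClusters} the stored values
#' are returned.
#'
#' @param x a \linkS4class{SimilarityMatrix} or \linkS4class{TermClusters}.
#' @param accession optional accessions to restrict to.
#' @return named numeric vector.
#' @export
setGeneric("termUniqueness",
           function(x, accession) standardGeneric("termUniqueness"))

#' Merge log of a reduction run
#' @param x a \linkS4class{TermClusters}.
#' @return data.frame with columns removed, absorber, similarity.
#' @export
setGeneric("mergeLog", function(x) standardGeneric("mergeLog"))

setMethod("goTerms", "OntologyGraph", function(x, ...) x@terms)
setMethod("goTerms", "SimilarityMatrix", function(x, ...) x@terms)
setMethod("goTerms", "TermClusters", function(x, ...) names(x@memberOf))

setMethod("termName", "OntologyGraph", function(x, accession) {
  if (missing(accession)) return(x@termName)
  .checkKnown(x, accession)
  x@termName[accession]
})

setMethod("termNamespace", "OntologyGraph", function(x, accession) {
  if (missing(accession)) return(x@termNamespace)
  .checkKnown(x, accession)
  x@termNamespace[accession]
})

setMethod("parentTerms", "OntologyGraph", function(x, accession) {
  stopifnot(length(accession) == 1)
  .checkKnown(x, accession)
  x@parents[[accession]]
})

setMethod("nsRoots", "OntologyGraph", function(x) x@roots)

setMethod("directCounts", "AnnotationCounts", function(x) x@direct)
setMethod("propagatedCounts", "AnnotationCounts", function(x) x@propagated)

setMethod("termFrequency", "ICTable", function(x, accession) {
  if (missing(accession)) return(x@frequency)
  .checkICKnown(x, accession)
  x@frequency[accession]
})

setMethod("termIC", "ICTable", function(x, accession) {
  if (missing(accession)) return(x@ic)
  .checkICKnown(x, accession)
  x@ic[accession]
})

setMethod("simMeasure", "SimilarityMatrix", function(x) x@measure)
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

setMethod("representatives", "TermClusters", function(x) x@representatives)
setMethod("memberOf", "TermClusters", function(x) x@memberOf)
setMethod("dispensability", "TermClusters", function(x) x@dispensability)
setMethod("mergeLog", "TermClusters", function(x) x@mergeLog)

setMethod("termUniqueness", "SimilarityMatrix", function(x, accession) {
  n <- length(x@terms)
  if (n == 0) return(setNames(numeric(0), character(0)))
  if (n == 1) {
    u <- setNames(0, x@terms)
  } else {
    v <- x@values
    diag(v) <- 0
    u <- -rowSums(v) / (n - 1)
  }
  if (missing(accession)) return(u)
  unknown <- setdiff(accession, x@terms)
  if (length(unknown))
    stop("term(s) not in similarity matrix: ",
         paste(unknown, collapse = ", "))
  u[accession]
})

setMethod("termUniqueness", "TermClusters", function(x, accession) {
  if (missing(accession)) return(x@termUniqueness)
  x@termUniqueness[accession]
})

.checkKnown <- function(graph, accession) {
  unknown <- setdiff(accession, graph@terms)
  if (length(unknown))
    stop("unknown accession(s): ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

.checkICKnown <- function(ic, accession) {
  unknown <- setdiff(accession, names(ic@ic))
  if (length(unknown))
    stop("accession(s) absent from IC table: ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}
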