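#' @import methods
NULL

#' OntologyGraph: a parsed ontology DAG
#'
#' Holds the terms of an OBO ontology together with the parent relation used
#' for traversal (by default \code{is_a} plus \code{part_of}), the namespace
#' of each term, obsolete/replacement bookkeeping, alternative identifiers,
#' and the root term(s) of every namespace.  Traversal edges never cross
#' namespaces, so each namespace forms its own rooted DAG.
#'
#' @slot terms character vector of primary accessions (includes obsolete terms).
#' @slot termName named character, term accession -> human-readable name.
#' @slot termNamespace named character, accession -> namespace.
#' @slot parents named list, accession -> character vector of parent
#'   accessions (empty for roots and obsolete terms).
#' @slot obsolete named logical.
#' @slot replacedBy named character, accession -> replacement accession
#'   (\code{NA} when none).
#' @slot altIds named character, alternative accession -> primary accession.
#' @slot roots named list, namespace -> character vector of root accessions.
#'
#' @seealso \code{\link{loadOBO}}, \code{\link{ancestors}},
#'   \code{\link{resolveTerm}}
#' @exportClass OntologyGraph
setClass("OntologyGraph",
  representation(
    terms = "character",
    termName = "character",
    termNamespace = "character",
    parents = "list",
    obsolete = "logical",
    replacedBy = "character",
    altIds = "character",
    roots = "list"
  )
)

setValidity("OntologyGraph", function(object) {
  msgs <- character(0)
  n <- length(object@terms)
  if (anyDuplicated(object@terms))
    msgs <- c(msgs, "term accessions must be unique")
  for (sl in c("termName", "termNamespace", "obsolete", "replacedBy")) {
    v <- slot(object, sl)
    if (length(v) != n || !identical(names(v), object@terms))
      msgs <- c(msgs, sprintf("slot '%s' must be named by the terms", sl))
  }
  if (length(object@parents) != n ||
      !identical(names(object@parents), object@terms))
    msgs <- c(msgs, "slot 'parents' must be named by the terms")
  bad <- setdiff(unlist(object@parents, use.names = FALSE), object@terms)
  if (length(bad))
    msgs <- c(msgs, paste("parent accessions not in ontology:",
                          paste(bad, collapse = ", ")))
  if (length(object@altIds)) {
    if (anyDuplicated(names(object@altIds)))
      msgs <- c(msgs, "alt_ids must map injectively into primary accessions")
    if (!all(object@altIds %in% object@terms))
      msgs <- c(msgs, "alt_ids must map to primary accessions")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnnotationCounts: direct and propagated annotation counts
#'
#' Direct counts record, per term, the number of distinct annotated entities
#' naming the term itself; propagated counts additionally include every
#' entity annotated to any descendant (true-path rule), deduplicated per
#' entity.  The entity-to-term incidence from the annotation source is kept
#' so that propagation can deduplicate entities that reach an ancestor
#' through several annotations.
#'
#' @slot direct named numeric, accession -> direct count.
#' @slot propagated named numeric, accession -> propagated count
#'   (length zero until \code{\link{propagateCounts}} is called, unless the
#'   counts were loaded pre-propagated from a frequency table).
#' @slot entityTerms named list, entity identifier -> character vector of
#'   directly annotated accessions (may be empty for table-loaded counts).
#'
#' @seealso \code{\link{readGAF}}, \code{\link{readFrequencyTable}},
#'   \code{\link{propagateCounts}}
#' @exportClass AnnotationCounts
setClass("AnnotationCounts",
  representation(
    direct = "numeric",
    propagated = "numeric",
    entityTerms = "list"
  )
)

setValidity("AnnotationCounts", function(object) {
  msgs <- character(0)
  if (length(object@direct) && is.null(names(object@direct)))
    msgs <- c(msgs, "direct counts must be named by accession")
  if (length(object@propagated) && is.null(names(object@propagated)))
    msgs <- c(msgs, "propagated counts must be named by accession")
  if (any(object@direct < 0) || any(object@propagated < 0))
    msgs <- c(msgs, "annotation counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ICTable: relative annotation frequencies and information content
#'
#' For every (non-obsolete) term of the ontology, the relative annotation
#' frequency p(t) = propagated count / root count of the term's namespace,
#' and the information content IC(t) = -log p(t) (natural logarithm).  Terms
#' absent from the annotation corpus receive pseudo-count 1 so their IC is
#' finite.
#'
#' @slot frequency named numeric in (0, 1].
#' @slot ic named numeric, IC(t) = -log(frequency), >= 0.
#' @slot rootCount named numeric, namespace -> number of distinct annotated
#'   entities under that namespace's root.
#'
#' @seealso \code{\link{informationContent}}
#' @exportClass ICTable
setClass("ICTable",
  representation(
    frequency = "numeric",
    ic = "numeric",
    rootCount = "numeric"
  )
)

setValidity("ICTable", function(object) {
  msgs <- character(0)
  if (!identical(names(object@frequency), names(object@ic)))
    msgs <- c(msgs, "frequency and ic must cover the same terms")
  if (length(object@frequency) &&
      (any(object@frequency <= 0) || any(object@frequency > 1 + 1e-12)))
    msgs <- c(msgs, "frequencies must lie in (0, 1]")
  if (length(object@ic) && any(object@ic < -1e-12))
    msgs <- c(msgs, "information content must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SimilarityMatrix: pairwise semantic similarities
#'
#' A symmetric matrix of pairwise term similarities under one of the four
#' most-informative-common-ancestor measures.  Lin and SimRel scores lie in
#' [0, 1]; Resnik scores are information contents; the Jiang-Conrath
#' distance is mapped to the bounded similarity 1/(1 + d).  Entries between
#' terms of different namespaces are 0.
#'
#' @slot terms ordered character vector of accessions.
#' @slot values symmetric numeric matrix with \code{terms} as dimnames.
#' @slot measure one of \code{"simrel"}, \code{"lin"}, \code{"resnik"},
#'   \code{"jiang_conrath"}.
#'
#' @seealso \code{\link{similarityMatrix}}, \code{\link{termSimilarity}}
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(
    terms = "character",
    values = "matrix",
    measure = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  msgs <- character(0)
  n <- length(object@terms)
  if (!identical(dim(object@values), c(n, n)))
    msgs <- c(msgs, "matrix dimensions must match the term list")
  if (n && (!identical(rownames(object@values), object@terms) ||
            !identical(colnames(object@values), object@terms)))
    msgs <- c(msgs, "matrix dimnames must equal the term list")
  if (anyDuplicated(object@terms))
    msgs <- c(msgs, "duplicate accession in term list")
  if (n && isTRUE(max(abs(object@values - t(object@values))) > 1e-8))
    msgs <- c(msgs, "similarity matrix must be symmetric")
  if (!object@measure %in% c("simrel", "lin", "resnik", "jiang_conrath"))
    msgs <- c(msgs, "unknown similarity measure")
  if (object@measure %in% c("simrel", "lin") && n &&
      isTRUE(min(object@values) < -1e-9 || max(object@values) > 1 + 1e-9))
    msgs <- c(msgs, "lin/simrel scores must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' TermClusters: the result of redundancy reduction
#'
#' Output of \code{\link{reduceTerms}}: the surviving cluster
#' representatives, the representative every input term belongs to, each
#' term's dispensability (the similarity at which it was merged away; for
#' representatives, the maximal similarity to any other final
#' representative, which is below the cutoff by construction), each term's
#' uniqueness (negative mean similarity to all other input terms), and the
#' ordered merge log.
#'
#' @slot representatives ordered character vector of surviving accessions.
#' @slot memberOf named character, accession -> representative accession.
#' @slot dispensability named numeric in [0, 1].
#' @slot termUniqueness named numeric.
#' @slot mergeLog data.frame with columns \code{removed}, \code{absorber},
#'   \code{similarity}, in merge order.
#' @slot cutoff the similarity cutoff C used.
#'
#' @seealso \code{\link{reduceTerms}}
#' @exportClass TermClusters
setClass("TermClusters",
  representation(
    representatives = "character",
    memberOf = "character",
    dispensability = "numeric",
    termUniqueness = "numeric",
    mergeLog = "data.frame",
    cutoff = "numeric"
  )
)

setValidity("TermClusters", function(object) {
  msgs <- character(0)
  terms <- names(object@memberOf)
  if (!all(object@representatives %in% object@memberOf))
    msgs <- c(msgs, "every representative must be a cluster target")
  if (!all(object@memberOf %in% object@representatives) && length(terms))
    msgs <- c(msgs, "every term must map to a representative")
  if (!identical(sort(names(object@dispensability)), sort(terms)))
    msgs <- c(msgs, "dispensability must cover every input term")
  if (length(object@cutoff) != 1 || object@cutoff <= 0 || object@cutoff >= 1)
    msgs <- c(msgs, "cutoff must lie in (0, 1)")
  reps <- object@representatives
  if (length(reps) &&
      any(object@dispensability[reps] >= object@cutoff - 1e-12))
    msgs <- c(msgs, "representatives must have dispensability below the cutoff")
  if (length(msgs)) msgs else TRUE
})

#' ReductionConfig: tunable thresholds of the reduction algorithm
#'
#' @slot cutoff similarity cutoff C in (0, 1); presets 0.9, 0.7 (default),
#'   0.5, 0.4 correspond to large/medium/small/tiny result lists.
#' @slot generalFrequencyThreshold relative annotation frequency above which
#'   a term counts as "very general" and is avoided as a representative
#'   (default 0.25).
#' @slot parentAbsorptionRatio when a parent/child pair with close values is
#'   merged, the parent is rejected instead of the child if the child
#'   accounts for more than this fraction of the parent's annotations
#'   (default 0.75).
#' @slot valueClosenessLog10 two user values count as "quite close" when
#'   their log10 difference does not exceed this tolerance (default 1.0).
#'
#' @seealso \code{\link{reductionConfig}}, \code{\link{reduceTerms}}
#' @exportClass ReductionConfig
setClass("ReductionConfig",
  representation(
    cutoff = "numeric",
    generalFrequencyThreshold = "numeric",
    parentAbsorptionRatio = "numeric",
    valueClosenessLog10 = "numeric"
  ),
  prototype(
    cutoff = 0.7,
    generalFrequencyThreshold = 0.25,
    parentAbsorptionRatio = 0.75,
    valueClosenessLog10 = 1.0
  )
)

setValidity("ReductionConfig", function(object) {
  msgs <- character(0)
  inUnit <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x < 1
  if (!inUnit(object@cutoff))
    msgs <- c(msgs, "cutoff must lie in (0, 1)")
  if (!inUnit(object@generalFrequencyThreshold))
    msgs <- c(msgs, "generalFrequencyThreshold must lie in (0, 1)")
  if (!inUnit(object@parentAbsorptionRatio))
    msgs <- c(msgs, "parentAbsorptionRatio must lie in (0, 1)")
  if (length(object@valueClosenessLog10) != 1 ||
      object@valueClosenessLog10 <= 0)
    msgs <- c(msgs, "valueClosenessLog10 must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Create a ReductionConfig
#'
#' @param cutoff similarity cutoff C in (0, 1); default 0.7.
#' @param generalFrequencyThreshold "very general" frequency threshold,
#'   default 0.25.
#' @param parentAbsorptionRatio child/parent annotation-count ratio above
#'   which the parent is rejected, default 0.75.
#' @param valueClosenessLog10 log10 tolerance for "quite close" user values,
#'   default 1.0.
#' @return a validated \linkS4class{ReductionConfig}.
#' @examples
#' reductionConfig(cutoff = 0.5)
#' @export
reductionConfig <- function(cutoff = 0.7,
                            generalFrequencyThreshold = 0.25,
                            parentAbsorptionRatio = 0.75,
                            valueClosenessLog10 = 1.0) {
  new("ReductionConfig",
      cutoff = cutoff,
      generalFrequencyThreshold = generalFrequencyThreshold,
      parentAbsorptionRatio = parentAbsorptionRatio,
      valueClosenessLog10 = valueClosenessLog10)
}

setMethod("show", "OntologyGraph", function(object) {
  live <- sum(!object@obsolete)
  cat(sprintf("OntologyGraph with %d terms (%d obsolete)\n",
              length(object@terms), length(object@terms) - live))
  for (ns in names(object@roots))
    cat(sprintf("  namespace %s: %d terms, root(s): %s\n", ns,
                sum(object@termNamespace == ns & !object@obsolete),
                paste(object@roots[[ns]], collapse = ", ")))
  if (length(object@altIds))
    cat(sprintf("  %d alternative identifiers\n", length(object@altIds)))
  invisible(NULL)
})

setMethod("show", "AnnotationCounts", function(object) {
  cat(sprintf("AnnotationCounts: %d terms with direct counts", length(object@direct)))
  if (length(object@entityTerms))
    cat(sprintf(", %d entities", length(object@entityTerms)))
  if (length(object@propagated))
    cat(sprintf(", propagated over %d terms", length(object@propagated)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "ICTable", function(object) {
  cat(sprintf("ICTable over %d terms; IC range [%.3f, %.3f]\n",
              length(object@ic),
              if (length(object@ic)) min(object@ic) else NA,
              if (length(object@ic)) max(object@ic) else NA))
  invisible(NULL)
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s) over %d terms\n",
              object@measure, length(object@terms)))
  invisible(NULL)
})

setMethod("show", "TermClusters", function(object) {
  nSingle <- sum(table(object@memberOf) == 1)
  cat(sprintf(
    "TermClusters: %d terms in %d clusters (%d singletons), cutoff C = %g\n",
    length(object@memberOf), length(object@representatives), nSingle,
    object@cutoff))
  invisible(NULL)
})

setMethod("show", "ReductionConfig", function(object) {
  cat(sprintf(
    "ReductionConfig: C = %g, general-term frequency > %g, parent absorption > %g, value closeness %g log10\n",
    object@cutoff, object@generalFrequencyThreshold,
    object@parentAbsorptionRatio, object@valueClosenessLog10))
  invisible(NULL)
})
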