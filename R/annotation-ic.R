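#' Read annotation evidence from a GAF 2.x file
#'
#' Counts distinct (entity, term) pairs from a tab-separated Gene
#' Association File.  Comment lines start with \code{'!'}.  Rows whose
#' qualifier contains \code{NOT} are skipped, as are rows failing the
#' optional taxon filter and, when requested, rows with IEA (electronically
#' inferred) evidence.  Malformed rows are skipped with a warning reporting
#' their number.  Species-specific annotation subsets are obtained by taxon
#' filtering rather than separate databases.
#'
#' @param path path to a GAF 2.x file.
#' @param taxonFilter optional vector of NCBI taxon ids (e.g. \code{9606});
#'   rows are kept when any of their taxon ids matches.
#' @param excludeIEA skip rows with evidence code IEA.
#' @return an \linkS4class{AnnotationCounts} with direct counts and the
#'   entity-term incidence filled; propagated counts are left empty until
#'   \code{\link{propagateCounts}}.
#' @export
readGAF <- function(path, taxonFilter = NULL, excludeIEA = FALSE) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop("no usable annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)

  nBad <- 0L
  pairs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 13 || !nzchar(f[2]) || !nzchar(f[5])) {
      nBad <- nBad + 1L
      next
    }
    qualifier <- f[4]
    if (grepl("(^|\\|)NOT(\\||$)", qualifier)) next
    if (excludeIEA && f[7] == "IEA") next
    if (!is.null(taxonFilter)) {
      taxa <- sub("^taxon:", "",
                  strsplit(f[13], "|", fixed = TRUE)[[1]])
      if (!any(taxa %in% as.character(taxonFilter))) next
    }
    pairs[[i]] <- c(paste(f[1], f[2], sep = ":"), f[5])
  }
  if (nBad > 0L)
    warning(nBad, " malformed GAF row(s) skipped")
  pairs <- pairs[!vapply(pairs, is.null, TRUE)]
  if (!length(pairs)) stop("zero usable annotation rows in ", path)

  entity <- vapply(pairs, `[`, "", 1L)
  term <- vapply(pairs, `[`, "", 2L)
  keep <- !duplicated(paste(entity, term, sep = "\r"))
  entity <- entity[keep]; term <- term[keep]

  direct <- table(term)
  entityTerms <- split(term, entity)
  new("AnnotationCounts",
      direct = setNames(as.numeric(direct), names(direct)),
      propagated = numeric(0),
      entityTerms = entityTerms)
}

#' Read a pre-propagated term frequency table
#'
#' A two-column tab-separated table (accession, propagated count) lets the
#' information-content machinery run without a GAF corpus.  When a graph is
#' supplied, count monotonicity along parent-child edges is checked and
#' violations are reported as a warning listing the offending edges.
#'
#' @param path path to the TSV (no header; \code{'#'} comment lines allowed).
#' @param graph optional \linkS4class{OntologyGraph} used for the
#'   monotonicity check.
#' @return an \linkS4class{AnnotationCounts} with propagated counts filled
#'   and no direct counts.
#' @export
readFrequencyTable <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("frequency table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty frequency table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 2))
    stop("frequency table rows must have two tab-separated columns")
  acc <- vapply(parts, `[`, "", 1L)
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(cnt)) stop("non-numeric count in frequency table")
  if (any(cnt < 0)) stop("negative count in frequency table")
  if (anyDuplicated(acc))
    stop("duplicate accession in frequency table: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  counts <- setNames(cnt, acc)
  if (!is.null(graph)) {
    badEdges <- character(0)
    for (id in intersect(acc, graph@terms)) {
      for (p in graph@parents[[id]]) {
        if (p %in% acc && counts[[id]] > counts[[p]])
          badEdges <- c(badEdges, paste0(id, " > ", p))
      }
    }
    if (length(badEdges))
      warning("count monotonicity violated on edge(s): ",
              paste(badEdges, collapse = "; "))
  }
  new("AnnotationCounts",
      direct = numeric(0), propagated = counts, entityTerms = list())
}

#' Propagate direct annotations up the ontology (true-path rule)
#'
#' An entity annotated to a term is implicitly annotated to all of the
#' term's ancestors.  Each entity contributes at most once to every term,
#' even when several of its annotations share an ancestor.  Annotations to
#' identifiers that cannot be resolved to a live term are dropped with a
#' warning; alternative and replaced identifiers are mapped to their
#' primary terms first.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param counts an \linkS4class{AnnotationCounts} holding the entity-term
#'   incidence (from \code{\link{readGAF}}).
#' @return the \linkS4class{AnnotationCounts} with propagated counts filled.
#' @export
propagateCounts <- function(graph, counts) {
  if (!length(counts@entityTerms))
    stop("no entity-level annotations to propagate; ",
         "table-loaded counts are already propagated")
  ancCache <- .ancestorSets(graph, intersect(
    unique(unlist(counts@entityTerms, use.names = FALSE)), graph@terms))
  dropped <- character(0)
  tally <- new.env(parent = emptyenv())
  for (terms in counts@entityTerms) {
    reach <- character(0)
    for (raw in unique(terms)) {
      res <- tryCatch(resolveTerm(graph, raw),
                      error = function(e) list(accession = NA, status = "bad"))
      if (is.na(res$accession)) {
        dropped <- c(dropped, raw)
        next
      }
      acc <- res$accession
      anc <- if (!is.null(ancCache[[acc]])) ancCache[[acc]]
             else ancestors(graph, acc)
      reach <- c(reach, acc, anc)
    }
    for (t in unique(reach))
      tally[[t]] <- (if (is.null(tally[[t]])) 0 else tally[[t]]) + 1
  }
  if (length(dropped))
    warning("dropped annotations to unresolvable term(s): ",
            paste(unique(dropped), collapse = ", "))
  ids <- ls(tally)
  counts@propagated <- setNames(
    vapply(ids, function(t) tally[[t]], 0), ids)
  validObject(counts)
  counts
}

#' Information content from propagated annotation counts
#'
#' The relative annotation frequency of a term is its propagated count
#' divided by the propagated count of its namespace root, and the
#' information content is the negative natural logarithm of that
#' frequency: IC(t) = -log p(t).  The namespace root has p = 1 and IC = 0.
#' Terms of the ontology absent from the annotation corpus receive
#' pseudo-count 1, i.e. the largest finite IC the corpus can support, so
#' user lists may mention unannotated terms.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param counts an \linkS4class{AnnotationCounts} with propagated counts
#'   (see \code{\link{propagateCounts}} or
#'   \code{\link{readFrequencyTable}}).
#' @return an \linkS4class{ICTable} over all non-obsolete terms of the
#'   graph.
#' @export
informationContent <- function(graph, counts) {
  prop <- counts@propagated
  if (!length(prop))
    stop("propagated counts are required; call propagateCounts() first")
  live <- graph@terms[!graph@obsolete]

  rootCount <- numeric(0)
  for (ns in names(graph@roots)) {
    rc <- prop[graph@roots[[ns]]]
    rc <- rc[!is.na(rc)]
    if (!length(rc))
      stop("no annotated root for namespace '", ns, "'")
    rootCount[[ns]] <- max(rc)
  }

  cnt <- prop[live]
  cnt[is.na(cnt) | cnt == 0] <- 1  # pseudo-count for unannotated terms
  denom <- rootCount[graph@termNamespace[live]]
  p <- pmin(cnt / denom, 1)
  ic <- -log(p)
  new("ICTable",
      frequency = setNames(as.numeric(p), live),
      ic = setNames(as.numeric(ic), live),
      rootCount = rootCount)
}
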