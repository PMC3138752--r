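#' Parse a user-supplied GO term list
#'
#' The input is plain text, one term per line: a term accession optionally
#' followed by whitespace and a numeric value (p-value or enrichment).
#' \code{'#'} starts a comment.  Identifiers are resolved through the
#' ontology: alternative identifiers map to their primary accession and
#' obsolete terms to their replacement (each with a warning); obsolete
#' terms without replacement and unknown identifiers are dropped with a
#' warning.  When an accession occurs more than once, the most significant
#' value is kept (smallest p-value / largest enrichment) with a warning.
#'
#' @param input path to a file, or a character vector of lines.
#' @param graph an \linkS4class{OntologyGraph} used for resolution.
#' @param valueKind \code{"p_value"} (default), \code{"enrichment"} or
#'   \code{"none"}.
#' @return a term-record data.frame (see \code{\link{termRecords}}).
#' @export
parseTermList <- function(input, graph,
                          valueKind = c("p_value", "enrichment", "none")) {
  valueKind <- match.arg(valueKind)
  lines <- if (length(input) == 1 && file.exists(input))
    readLines(input, warn = FALSE) else input
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))

  accs <- character(0); vals <- numeric(0)
  for (i in keep) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    raw <- fields[1]
    v <- NA_real_
    if (length(fields) >= 2 && valueKind != "none") {
      v <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(v))
        stop("line ", i, ": value '", fields[2], "' is not numeric")
      if (valueKind == "p_value" && (v <= 0 || v > 1))
        stop("line ", i, ": p-value ", v, " outside (0, 1]")
    }
    res <- resolveTerm(graph, raw)
    if (res$status == "alt")
      warning("line ", i, ": ", raw, " is an alternative id of ",
              res$accession)
    if (res$status == "replaced")
      warning("line ", i, ": obsolete term ", raw, " replaced by ",
              res$accession)
    if (is.na(res$accession)) {
      warning("line ", i, ": term ", raw, " dropped (", res$status, ")")
      next
    }
    accs <- c(accs, res$accession)
    vals <- c(vals, v)
  }
  if (!length(accs)) stop("no valid terms in input list")

  if (anyDuplicated(accs)) {
    dups <- unique(accs[duplicated(accs)])
    warning("duplicate term(s), keeping most significant value: ",
            paste(dups, collapse = ", "))
    better <- function(a, b) {
      if (is.na(a)) return(b)
      if (is.na(b)) return(a)
      if (valueKind == "p_value") min(a, b) else max(a, b)
    }
    keepVals <- tapply(vals, accs, function(x) Reduce(better, x))
    accs1 <- unique(accs)
    vals <- as.numeric(keepVals[accs1])
    accs <- accs1
  }

  hasValues <- valueKind != "none" && any(!is.na(vals))
  termRecords(accs,
              value = if (hasValues) vals else NULL,
              valueKind = if (hasValues) valueKind else "none")
}

#' Run the full reduction and visualization pipeline
#'
#' Loads the ontology and annotation source, parses the user list,
#' partitions it by namespace (similarity across namespaces is zero, so
#' namespaces are processed independently), and per namespace computes the
#' similarity matrix, the reduced clustering, the two-dimensional layout,
#' the thresholded similarity graph, the treemap hierarchy and the keyword
#' statistics.  Everything is deterministic given the configuration.  When
#' \code{outputDir} is given, per-namespace files are written:
#' \code{results_<ns>.tsv}, \code{graph_<ns>.xgmml},
#' \code{treemap_<ns>.json} and \code{keywords_<ns>.tsv}.
#'
#' @param oboPath path to the ontology OBO file.
#' @param termList path to the user's term list, or a character vector of
#'   its lines.
#' @param gafPath optional path to a GAF 2.x annotation file.
#' @param frequencyTablePath optional path to a pre-propagated frequency
#'   table (exactly one of \code{gafPath}/\code{frequencyTablePath} must
#'   be given).
#' @param taxonFilter optional taxon ids for GAF filtering.
#' @param excludeIEA skip electronically inferred GAF rows.
#' @param valueKind interpretation of the list's values.
#' @param measure similarity measure (default \code{"simrel"}).
#' @param config a \linkS4class{ReductionConfig}; default cutoff C = 0.7.
#' @param relations ontology relations to traverse.
#' @param edgeFraction fraction of strongest pairs kept as graph edges
#'   (default 0.03).
#' @param superCutoff treemap supercluster cutoff (default 0.10).
#' @param sizeMode treemap size semantics, \code{"value"} or
#'   \code{"frequency"}.
#' @param outputDir optional directory for the output files.
#' @param verbose log progress to stderr.
#' @return a list with elements \code{graph}, \code{ic}, \code{records} and
#'   \code{namespaces} — the latter a per-namespace list of
#'   \code{records}, \code{similarity}, \code{clusters}, \code{layout},
#'   \code{graphExport}, \code{treemap}, \code{keywords},
#'   \code{keywordCorrelation} and \code{table} (the results table as a
#'   data.frame).
#' @export
runPipeline <- function(oboPath, termList,
                        gafPath = NULL, frequencyTablePath = NULL,
                        taxonFilter = NULL, excludeIEA = FALSE,
                        valueKind = c("p_value", "enrichment", "none"),
                        measure = c("simrel", "lin", "resnik",
                                    "jiang_conrath"),
                        config = reductionConfig(),
                        relations = c("is_a", "part_of"),
                        edgeFraction = 0.03, superCutoff = 0.10,
                        sizeMode = c("value", "frequency"),
                        outputDir = NULL, verbose = FALSE) {
  valueKind <- match.arg(valueKind)
  measure <- match.arg(measure)
  sizeMode <- match.arg(sizeMode)
  if (is.null(gafPath) == is.null(frequencyTablePath))
    stop("exactly one annotation source (gafPath or frequencyTablePath) ",
         "must be given")
  note <- function(...) if (verbose) message(...)

  note("loading ontology from ", oboPath)
  graph <- loadOBO(oboPath, relations = relations)
  if (!is.null(gafPath)) {
    note("reading annotations from ", gafPath)
    counts <- readGAF(gafPath, taxonFilter = taxonFilter,
                      excludeIEA = excludeIEA)
    counts <- propagateCounts(graph, counts)
  } else {
    note("reading frequency table from ", frequencyTablePath)
    counts <- readFrequencyTable(frequencyTablePath, graph = graph)
  }
  ic <- informationContent(graph, counts)

  records <- parseTermList(termList, graph, valueKind = valueKind)
  note(nrow(records), " terms after resolution")

  byNs <- split(records$accession,
                graph@termNamespace[records$accession])
  results <- list()
  for (ns in sort(names(byNs))) {
    accs <- byNs[[ns]]
    rec <- records[match(accs, records$accession), , drop = FALSE]
    attr(rec, "valueKind") <- valueKind(records)
    rownames(rec) <- NULL
    note("namespace ", ns, ": ", nrow(rec), " terms")

    sm <- similarityMatrix(graph, ic, rec$accession, measure = measure)
    cl <- reduceTerms(sm, rec, config, graph = graph, ic = ic)
    note("namespace ", ns, ": ", length(cl@representatives),
         " clusters after ", nrow(cl@mergeLog), " merges")
    ly <- mdsLayout(sm)
    ge <- buildGraph(sm, clusters = cl, records = rec,
                     graph = graph, ic = ic, edgeFraction = edgeFraction)
    tm <- buildTreemap(sm, cl, records = rec, ic = ic, graph = graph,
                       superCutoff = superCutoff, sizeMode = sizeMode,
                       config = config)
    bgNames <- graph@termName[
      !graph@obsolete & graph@termNamespace == ns]
    kw <- keywordEnrichment(unname(termName(graph)[rec$accession]),
                            unname(bgNames))
    kwc <- if (valueKind(rec) != "none" && sum(!is.na(rec$value)) >= 3)
      keywordValueCorrelation(rec, unname(termName(graph)[rec$accession]))
    else NULL

    tab <- .resultsTable(rec, graph, ic, cl, ly)
    results[[ns]] <- list(records = rec, similarity = sm, clusters = cl,
                          layout = ly, graphExport = ge, treemap = tm,
                          keywords = kw, keywordCorrelation = kwc,
                          table = tab)
  }

  bundle <- list(graph = graph, ic = ic, records = records,
                 namespaces = results)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    for (ns in names(results)) {
      r <- results[[ns]]
      writeResultsTable(r$table,
                        file.path(outputDir, paste0("results_", ns, ".tsv")))
      writeGraph(r$graphExport,
                 file.path(outputDir, paste0("graph_", ns, ".xgmml")))
      writeTreemap(r$treemap,
                   file.path(outputDir, paste0("treemap_", ns, ".json")))
      kwAll <- rbind(r$keywords, r$keywordCorrelation)
      utils::write.table(kwAll,
                         file.path(outputDir,
                                   paste0("keywords_", ns, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  bundle
}

# assemble the per-namespace results table: representatives first within
# each cluster, clusters ordered by their representative's significance
.resultsTable <- function(rec, graph, ic, clusters, layout) {
  accs <- rec$accession
  kind <- valueKind(rec)
  sig <- if (kind == "none") rep(NA_real_, nrow(rec))
         else .sigScore(rec$value, kind)
  repOf <- clusters@memberOf[accs]
  repSig <- sig[match(repOf, accs)]
  isRep <- accs == repOf
  ord <- order(
    -ifelse(is.na(repSig), -Inf, repSig), repOf,  # cluster blocks
    -as.integer(isRep), accs)                     # representative first
  accs <- accs[ord]
  data.frame(
    term_id = accs,
    name = unname(termName(graph)[accs]),
    value = rec$value[ord],
    frequency_percent = 100 * vapply(
      accs, function(a) .lookupOrNA(termFrequency(ic), a), 0),
    uniqueness = unname(clusters@termUniqueness[accs]),
    dispensability = unname(clusters@dispensability[accs]),
    representative_id = unname(repOf[accs]),
    is_representative = unname(isRep[ord]),
    plot_x = unname(layout$coordinates[accs, "PC1"]),
    plot_y = unname(layout$coordinates[accs, "PC2"]),
    stringsAsFactors = FALSE)
}

#' Write the results table
#'
#' Tab-separated, fixed column order: term_id, name, value,
#' frequency_percent, uniqueness, dispensability, representative_id,
#' is_representative, plot_x, plot_y.  Within each cluster the
#' representative is listed before its members.
#'
#' @param table the \code{table} element of a pipeline namespace result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeResultsTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
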