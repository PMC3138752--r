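#' Thresholded similarity graph over cluster representatives
#'
#' Nodes are the cluster representatives (or all matrix terms when no
#' clustering is given); the strongest 3 percent of pairwise similarities
#' become edges, a fraction found empirically to balance over-connected
#' against fragmented graphs.  The edge count is round-half-up of
#' \code{edgeFraction} times the number of pairs, floored at one edge
#' whenever at least one pair exists; ties in similarity are broken by
#' lexicographic pair order, so the edge set is invariant under input
#' permutation.  No self-edges are produced.
#'
#' @param simMatrix a \linkS4class{SimilarityMatrix} covering the nodes.
#' @param clusters optional \linkS4class{TermClusters}; its representatives
#'   become the node set, and uniqueness/dispensability node attributes are
#'   taken from it.
#' @param records optional term-record data.frame supplying the
#'   user-value node attribute.
#' @param graph optional \linkS4class{OntologyGraph} supplying term names.
#' @param ic optional \linkS4class{ICTable} supplying term frequencies
#'   (bubble-size semantics).
#' @param edgeFraction fraction of strongest pairs kept as edges
#'   (default 0.03).
#' @return a list with \code{nodes} (data.frame: accession, name, value,
#'   frequency, uniqueness, dispensability), \code{edges} (data.frame:
#'   a, b, similarity, strongest first) and \code{edgeFraction}.
#' @export
buildGraph <- function(simMatrix, clusters = NULL, records = NULL,
                       graph = NULL, ic = NULL, edgeFraction = 0.03) {
  stopifnot(edgeFraction > 0, edgeFraction <= 1)
  nodesAcc <- if (!is.null(clusters)) clusters@representatives
              else simMatrix@terms
  missingAcc <- setdiff(nodesAcc, simMatrix@terms)
  if (length(missingAcc))
    stop("nodes not covered by the similarity matrix: ",
         paste(missingAcc, collapse = ", "))

  n <- length(nodesAcc)
  nodes <- data.frame(
    accession = nodesAcc,
    name = if (!is.null(graph))
      unname(termName(graph)[nodesAcc]) else nodesAcc,
    value = if (!is.null(records))
      records$value[match(nodesAcc, records$accession)] else NA_real_,
    frequency = if (!is.null(ic))
      vapply(nodesAcc, function(a) .lookupOrNA(termFrequency(ic), a), 0)
      else NA_real_,
    uniqueness = if (!is.null(clusters))
      unname(clusters@termUniqueness[nodesAcc])
      else unname(termUniqueness(simMatrix, nodesAcc)),
    dispensability = if (!is.null(clusters))
      unname(clusters@dispensability[nodesAcc]) else NA_real_,
    stringsAsFactors = FALSE)

  if (n < 2) {
    edges <- data.frame(a = character(0), b = character(0),
                        similarity = numeric(0))
    return(list(nodes = nodes, edges = edges,
                edgeFraction = edgeFraction))
  }

  idx <- utils::combn(sort(nodesAcc), 2)
  a <- idx[1, ]; b <- idx[2, ]
  sim <- simMatrix@values[cbind(a, b)]
  ord <- order(-sim, a, b)
  nPairs <- length(sim)
  nEdges <- min(nPairs, max(1L, as.integer(floor(edgeFraction * nPairs + 0.5))))
  keep <- ord[seq_len(nEdges)]
  edges <- data.frame(a = a[keep], b = b[keep],
                      similarity = unname(sim[keep]),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, edgeFraction = edgeFraction)
}

#' Write a similarity graph as XGMML or GraphML
#'
#' Emits well-formed XML consumable by Cytoscape (XGMML) and by generic
#' network tools (GraphML).  Node attributes carried: name, value,
#' frequency, uniqueness, dispensability; edge attribute: similarity.
#'
#' @param graphExport result of \code{\link{buildGraph}}.
#' @param path output file path.
#' @param dialect \code{"xgmml"} (default) or \code{"graphml"}.
#' @return the path, invisibly.
#' @export
writeGraph <- function(graphExport, path, dialect = c("xgmml", "graphml")) {
  dialect <- match.arg(dialect)
  nodes <- graphExport$nodes
  edges <- graphExport$edges
  fmtNum <- function(x) {
    ifelse(is.na(x), "", format(x, digits = 12, scientific = TRUE, trim = TRUE))
  }
  if (dialect == "xgmml") {
    doc <- xml2::xml_new_root(
      "graph", label = "GO term similarity graph",
      directed = "0", xmlns = "http://www.cs.rpi.edu/XGMML")
    numAttrs <- c("value", "frequency", "uniqueness", "dispensability")
    for (i in seq_len(nrow(nodes))) {
      nd <- xml2::xml_add_child(doc, "node",
                                id = as.character(i),
                                label = nodes$accession[i])
      xml2::xml_add_child(nd, "att", name = "name", type = "string",
                          value = nodes$name[i])
      for (at in numAttrs)
        xml2::xml_add_child(nd, "att", name = at, type = "real",
                            value = fmtNum(nodes[[at]][i]))
    }
    id <- seq_len(nrow(nodes)); names(id) <- nodes$accession
    for (i in seq_len(nrow(edges))) {
      ed <- xml2::xml_add_child(
        doc, "edge",
        label = paste(edges$a[i], edges$b[i], sep = "--"),
        source = as.character(id[[edges$a[i]]]),
        target = as.character(id[[edges$b[i]]]))
      xml2::xml_add_child(ed, "att", name = "similarity", type = "real",
                          value = fmtNum(edges$similarity[i]))
    }
    xml2::write_xml(doc, path)
  } else {
    doc <- xml2::xml_new_root(
      "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
    keyDefs <- rbind(
      data.frame(id = "name", to = "node", type = "string"),
      data.frame(id = "value", to = "node", type = "double"),
      data.frame(id = "frequency", to = "node", type = "double"),
      data.frame(id = "uniqueness", to = "node", type = "double"),
      data.frame(id = "dispensability", to = "node", type = "double"),
      data.frame(id = "similarity", to = "edge", type = "double"))
    for (i in seq_len(nrow(keyDefs)))
      xml2::xml_add_child(doc, "key", id = keyDefs$id[i],
                          `for` = keyDefs$to[i],
                          attr.name = keyDefs$id[i],
                          attr.type = keyDefs$type[i])
    g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
    for (i in seq_len(nrow(nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = nodes$accession[i])
      dat <- xml2::xml_add_child(nd, "data", key = "name")
      xml2::xml_set_text(dat, nodes$name[i])
      for (at in c("value", "frequency", "uniqueness", "dispensability")) {
        dat <- xml2::xml_add_child(nd, "data", key = at)
        xml2::xml_set_text(dat, fmtNum(nodes[[at]][i]))
      }
    }
    for (i in seq_len(nrow(edges))) {
      ed <- xml2::xml_add_child(g, "edge",
                                source = edges$a[i], target = edges$b[i])
      dat <- xml2::xml_add_child(ed, "data", key = "similarity")
      xml2::xml_set_text(dat, fmtNum(edges$similarity[i]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}
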