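#' Default stopword list for keyword statistics
#'
#' Standard English stopwords plus Gene Ontology boilerplate tokens
#' (process, regulation, activity, positive, negative, cell, cellular)
#' which occur in a large fraction of term names and carry no specific
#' meaning in a tag cloud.
#'
#' @return character vector of lowercase stopwords.
#' @export
defaultStopwords <- function() {
  c("the", "and", "for", "not", "are", "was", "were", "with", "via",
    "into", "from", "that", "this", "its", "any", "all", "but", "per",
    "has", "have", "had", "can", "may", "will", "upon", "during",
    "between", "within", "through", "other", "such", "involved",
    # GO boilerplate
    "process", "regulation", "activity", "positive", "negative",
    "cell", "cellular")
}

# lowercase alphanumeric tokens of length >= 3, stopwords removed
.tokenize <- function(name, stopwords) {
  tok <- strsplit(tolower(name), "[^a-z0-9]+")[[1]]
  tok <- tok[nchar(tok) >= 3]
  unique(setdiff(tok, stopwords))
}

#' Keywords overrepresented in the user's term names
#'
#' Term names are tokenized on non-alphanumeric characters and lowercased;
#' stopwords and tokens shorter than three characters are dropped.  Each
#' remaining token is scored by the smoothed log-odds
#' log2((f_list + pseudo) / (f_bg + pseudo)), where f_list and f_bg are the
#' fractions of user terms and of background (whole-namespace) term names
#' containing the token.  Only overrepresented keywords (score > 0) are
#' retained, sorted by decreasing score — underrepresented keywords never
#' appear in a tag cloud.
#'
#' @param userNames character vector of the user terms' names.
#' @param backgroundNames character vector of all term names in the
#'   namespace (the background vocabulary).
#' @param pseudo smoothing constant added to both fractions (default 0.5).
#' @param stopwords tokens to ignore; see \code{\link{defaultStopwords}}.
#' @return data.frame with columns \code{keyword}, \code{score},
#'   \code{direction} (\code{"overrepresented"}) and \code{support} (number
#'   of user terms containing the keyword).
#' @export
keywordEnrichment <- function(userNames, backgroundNames,
                              pseudo = 0.5,
                              stopwords = defaultStopwords()) {
  if (!length(userNames)) stop("at least one user term name is required")
  userTok <- lapply(userNames, .tokenize, stopwords = stopwords)
  bgTok <- lapply(backgroundNames, .tokenize, stopwords = stopwords)
  vocab <- sort(unique(unlist(userTok, use.names = FALSE)))
  if (!length(vocab))
    return(data.frame(keyword = character(0), score = numeric(0),
                      direction = character(0), support = integer(0)))
  support <- vapply(vocab, function(w)
    sum(vapply(userTok, function(t) w %in% t, TRUE)), 0L)
  fList <- support / length(userNames)
  fBg <- if (length(bgTok))
    vapply(vocab, function(w)
      mean(vapply(bgTok, function(t) w %in% t, TRUE)), 0)
  else rep(0, length(vocab))
  score <- log2((fList + pseudo) / (fBg + pseudo))
  keep <- score > 0
  out <- data.frame(keyword = vocab[keep], score = score[keep],
                    direction = rep("overrepresented", sum(keep)),
                    support = support[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$keyword), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keywords correlated with the user-supplied values
#'
#' For every retained token of the user terms' names, the score is the
#' point-biserial correlation (Pearson correlation with a binary presence
#' indicator) between the token's presence in a term's name and the term's
#' significance score (-log10 p, or log10 enrichment) across the user
#' list.  Tokens present in all or in none of the terms carry no signal and
#' are skipped; constant values yield all-zero scores.
#'
#' @param records a term-record data.frame (see \code{\link{termRecords}})
#'   with values for at least three terms.
#' @param names character vector of term names aligned with
#'   \code{records$accession}.
#' @param stopwords tokens to ignore.
#' @return data.frame with columns \code{keyword}, \code{score},
#'   \code{direction} (\code{"value_correlated"}) and \code{support},
#'   sorted by decreasing score.
#' @export
keywordValueCorrelation <- function(records, names,
                                    stopwords = defaultStopwords()) {
  kind <- valueKind(records)
  if (kind == "none")
    stop("keyword-value correlation requires user-supplied values")
  ok <- !is.na(records$value)
  if (sum(ok) < 3)
    stop("values are required for at least three terms")
  stopifnot(length(names) == nrow(records))
  vals <- .sigScore(records$value[ok], kind)
  toks <- lapply(names[ok], .tokenize, stopwords = stopwords)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  rows <- list()
  for (w in vocab) {
    present <- vapply(toks, function(t) w %in% t, TRUE)
    if (all(present) || !any(present)) next
    r <- if (stats::sd(vals) == 0) 0
         else stats::cor(as.numeric(present), vals)
    rows[[w]] <- data.frame(keyword = w, score = unname(r),
                            direction = "value_correlated",
                            support = sum(present),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(keyword = character(0), score = numeric(0),
                      direction = character(0), support = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$keyword), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treemap hierarchy: superclusters of loosely related representatives
#'
#' Builds the two-level hierarchy shown in treemap views: cluster
#' representatives are joined into "superclusters" of loosely related
#' terms by re-running the same greedy reduction on the representatives at
#' a much looser cutoff (default 0.10), so one clustering semantic governs
#' both levels.  Each surviving term labels a supercluster whose children
#' are the representatives it absorbed plus itself.  A non-positive
#' \code{superCutoff} degenerates to one supercluster per representative.
#' Rectangle sizes reflect either the user value (-log10 p, floored at
#' 0.01, or log10 enrichment floored likewise) or the term's relative
#' annotation frequency in percent.
#'
#' @param simMatrix a \linkS4class{SimilarityMatrix} covering the
#'   representatives.
#' @param clusters a \linkS4class{TermClusters} from
#'   \code{\link{reduceTerms}}.
#' @param records optional term-record data.frame (sizes from values).
#' @param ic optional \linkS4class{ICTable} (sizes from frequencies).
#' @param graph optional \linkS4class{OntologyGraph} for names.
#' @param superCutoff similarity cutoff for joining representatives
#'   (default 0.10).
#' @param sizeMode \code{"value"} (default) or \code{"frequency"}.
#' @param config optional \linkS4class{ReductionConfig} whose thresholds
#'   (other than the cutoff) are reused for the supercluster pass.
#' @return a nested list: \code{list(label = "root", children = ...)};
#'   each supercluster is \code{list(label, accession, children)}, each
#'   leaf \code{list(label, accession, size)}.
#' @export
buildTreemap <- function(simMatrix, clusters, records = NULL, ic = NULL,
                         graph = NULL, superCutoff = 0.10,
                         sizeMode = c("value", "frequency"),
                         config = NULL) {
  sizeMode <- match.arg(sizeMode)
  reps <- clusters@representatives
  if (!length(reps)) return(list(label = "root", children = list()))

  if (superCutoff <= 0) {
    superOf <- setNames(reps, reps)
  } else {
    subM <- asSimilarityMatrix(
      simMatrix@values[reps, reps, drop = FALSE], simMatrix@measure)
    subRec <- if (!is.null(records)) {
      r <- records[match(reps, records$accession), , drop = FALSE]
      attr(r, "valueKind") <- valueKind(records)
      r
    } else termRecords(reps, valueKind = "none")
    cfg <- if (is.null(config)) reductionConfig(cutoff = superCutoff)
           else reductionConfig(
             cutoff = superCutoff,
             generalFrequencyThreshold = config@generalFrequencyThreshold,
             parentAbsorptionRatio = config@parentAbsorptionRatio,
             valueClosenessLog10 = config@valueClosenessLog10)
    superRes <- reduceTerms(subM, subRec, cfg, graph = graph, ic = ic)
    superOf <- superRes@memberOf
  }

  nameOf <- function(a) {
    if (!is.null(graph) && a %in% graph@terms) unname(termName(graph, a))
    else a
  }
  sizeOf <- function(a) {
    if (sizeMode == "value" && !is.null(records)) {
      v <- records$value[match(a, records$accession)]
      if (!is.na(v)) {
        s <- .sigScore(v, valueKind(records))
        return(max(s, 0.01))
      }
    }
    if (!is.null(ic)) {
      f <- .lookupOrNA(termFrequency(ic), a)
      if (!is.na(f)) return(100 * f)
    }
    1
  }

  children <- lapply(sort(unique(superOf)), function(sc) {
    members <- sort(names(superOf)[superOf == sc])
    members <- c(sc, setdiff(members, sc))  # representative leaf first
    list(label = nameOf(sc), accession = sc,
         children = lapply(members, function(m)
           list(label = nameOf(m), accession = m, size = sizeOf(m))))
  })
  list(label = "root", children = children)
}

#' Write a treemap hierarchy as JSON or TSV
#'
#' JSON output nests root, superclusters and leaves; TSV output has three
#' columns (supercluster, representative, size), one row per leaf.
#'
#' @param tree result of \code{\link{buildTreemap}}.
#' @param path output file path.
#' @param format \code{"json"} (default) or \code{"tsv"}.
#' @return the path, invisibly.
#' @export
writeTreemap <- function(tree, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, path)
  } else {
    rows <- list()
    for (sc in tree$children)
      for (leaf in sc$children)
        rows[[length(rows) + 1L]] <- data.frame(
          supercluster = sc$accession,
          representative = leaf$accession,
          size = leaf$size, stringsAsFactors = FALSE)
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(supercluster = character(0),
                           representative = character(0),
                           size = numeric(0))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
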