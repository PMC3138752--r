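#' Build a term-record table for redundancy reduction
#'
#' @param accession character vector of term accessions (unique).
#' @param value optional numeric vector of user-supplied values (p-values
#'   or enrichments), recycled \code{NA} when absent.
#' @param valueKind interpretation of \code{value}: \code{"p_value"}
#'   (smaller is more significant, must lie in (0, 1]),
#'   \code{"enrichment"} (larger is better) or \code{"none"}.
#' @param pinned logical vector; pinned terms are never removed and always
#'   end up as cluster representatives.
#' @return a data.frame with columns \code{accession}, \code{value},
#'   \code{pinned} and attribute \code{valueKind}.
#' @export
termRecords <- function(accession, value = NULL,
                        valueKind = c("p_value", "enrichment", "none"),
                        pinned = FALSE) {
  valueKind <- match.arg(valueKind)
  if (anyDuplicated(accession))
    stop("duplicate accession in term records: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  n <- length(accession)
  if (is.null(value)) {
    value <- rep(NA_real_, n)
    if (valueKind != "none" && n > 0)
      valueKind <- "none"
  } else {
    stopifnot(length(value) == n)
    if (valueKind == "p_value" &&
        any(!is.na(value) & (value <= 0 | value > 1)))
      stop("p-values must lie in (0, 1]")
  }
  pinned <- rep_len(as.logical(pinned), n)
  out <- data.frame(accession = as.character(accession),
                    value = as.numeric(value),
                    pinned = pinned,
                    stringsAsFactors = FALSE)
  attr(out, "valueKind") <- valueKind
  out
}

#' @rdname termRecords
#' @param records a term-record data.frame.
#' @export
valueKind <- function(records) {
  vk <- attr(records, "valueKind")
  if (is.null(vk)) "none" else vk
}

# significance score: larger means "keep me"
.sigScore <- function(value, kind) {
  if (kind == "p_value") -log10(value)
  else if (kind == "enrichment") log10(value)
  else NA_real_
}

#' Decide which of two similar terms to remove
#'
#' The decision cascade applied to every merged pair, in order: (1) a
#' pinned term always survives (two pinned terms cannot be merged); (2) a
#' "very general" term (relative annotation frequency above the configured
#' threshold) is removed, the more frequent one when both are general; (3)
#' when user values are supplied and differ by more than the closeness
#' tolerance in log10, the less significant term is removed; without user
#' values the lower-uniqueness term is removed at this step instead; (4)
#' for close values, when one term is an ancestor of the other the child is
#' removed (the parent is kept as the more established description) —
#' unless the child accounts for more than the absorption ratio of the
#' parent's annotations, making the two de facto equivalent, in which case
#' the parent is rejected instead; (5) otherwise the lower-uniqueness term
#' is removed; (6) a final tie removes the lexicographically larger
#' accession.
#'
#' @param a,b accessions of the two terms under consideration.
#' @param records term-record data.frame (see \code{\link{termRecords}}).
#' @param config a \linkS4class{ReductionConfig}.
#' @param graph optional \linkS4class{OntologyGraph} enabling the ancestry
#'   step.
#' @param ic optional \linkS4class{ICTable} enabling the general-term and
#'   absorption steps.
#' @param uniqueness named numeric vector of uniqueness values (required
#'   for steps 3'(no values) and 5; computed by \code{\link{reduceTerms}}
#'   from the full input matrix).
#' @return the accession of the term to remove.
#' @export
chooseLoser <- function(a, b, records, config = reductionConfig(),
                        graph = NULL, ic = NULL, uniqueness = NULL) {
  stopifnot(a != b)
  rec <- records[match(c(a, b), records$accession), ]
  if (anyNA(rec$accession))
    stop("term(s) absent from records: ",
         paste(setdiff(c(a, b), records$accession), collapse = ", "))
  kind <- valueKind(records)

  # (1) pinning overrides everything
  if (rec$pinned[1] && rec$pinned[2])
    stop("cannot merge two pinned terms: ", a, ", ", b)
  if (rec$pinned[1]) return(b)
  if (rec$pinned[2]) return(a)

  # (2) very general terms are always avoided as representatives
  if (!is.null(ic)) {
    fr <- c(.lookupOrNA(termFrequency(ic), a), .lookupOrNA(termFrequency(ic), b))
    gen <- !is.na(fr) & fr > config@generalFrequencyThreshold
    if (gen[1] && !gen[2]) return(a)
    if (gen[2] && !gen[1]) return(b)
    if (gen[1] && gen[2] && fr[1] != fr[2])
      return(if (fr[1] > fr[2]) a else b)
  }

  # (3) decisive user values — or uniqueness when no values were supplied
  uq <- if (!is.null(uniqueness)) uniqueness[c(a, b)] else c(NA_real_, NA_real_)
  if (kind != "none" && !anyNA(rec$value)) {
    sc <- .sigScore(rec$value, kind)
    if (abs(sc[1] - sc[2]) > config@valueClosenessLog10)
      return(if (sc[1] < sc[2]) a else b)
  } else if (!anyNA(uq) && uq[1] != uq[2]) {
    return(if (uq[1] < uq[2]) a else b)
  }

  # (4) close values + ancestry: keep the parent unless the child makes up
  # most of it (> parentAbsorptionRatio), i.e. the two are near-equivalent
  if (!is.null(graph) &&
      all(c(a, b) %in% graph@terms[!graph@obsolete])) {
    ancA <- ancestors(graph, a)
    ancB <- ancestors(graph, b)
    parent <- child <- NULL
    if (a %in% ancB) { parent <- a; child <- b }
    else if (b %in% ancA) { parent <- b; child <- a }
    if (!is.null(parent)) {
      ratio <- NA_real_
      if (!is.null(ic)) {
        fp <- .lookupOrNA(termFrequency(ic), parent)
        fc <- .lookupOrNA(termFrequency(ic), child)
        if (!is.na(fp) && !is.na(fc) && fp > 0) ratio <- fc / fp
      }
      if (!is.na(ratio) && ratio > config@parentAbsorptionRatio)
        return(parent)
      return(child)
    }
  }

  # (5) uniqueness fallback
  if (!anyNA(uq) && uq[1] != uq[2])
    return(if (uq[1] < uq[2]) a else b)

  # (6) deterministic lexicographic tie-break
  if (a > b) a else b
}

.lookupOrNA <- function(v, key) {
  if (key %in% names(v)) unname(v[[key]]) else NA_real_
}

#' Greedy redundancy reduction of a GO term list
#'
#' Iteratively finds the most similar pair among the current cluster
#' representatives; while that similarity reaches the cutoff C, one of the
#' two (chosen by \code{\link{chooseLoser}}) is removed and merged into the
#' survivor's cluster, carrying along any terms it had already absorbed.
#' The removed term's dispensability is the similarity at which it was
#' merged away.  The procedure stops as soon as the highest remaining
#' similarity is below C, which guarantees that no two final
#' representatives are more similar than C.  Each input term belongs to
#' exactly one cluster.  Representatives are assigned the maximal
#' similarity to any other final representative as their dispensability
#' (0 for a lone representative), so representatives are exactly the terms
#' with dispensability below C.  Uniqueness (negative mean similarity to
#' all other input terms) is computed on the full input matrix for every
#' term.  Ties in the pair search are broken toward the lexicographically
#' smallest pair; the whole procedure is deterministic.
#'
#' @param simMatrix a \linkS4class{SimilarityMatrix} covering all records.
#' @param records a term-record data.frame (see \code{\link{termRecords}}).
#' @param config a \linkS4class{ReductionConfig}; its \code{cutoff} slot is
#'   the cutoff C.
#' @param graph optional \linkS4class{OntologyGraph} for the ancestry rule.
#' @param ic optional \linkS4class{ICTable} for the general-term and
#'   absorption rules.
#' @return a \linkS4class{TermClusters}.
#' @examples
#' fx <- workedExampleFixture()
#' reduceTerms(fx$matrix, fx$records, reductionConfig(cutoff = 0.5))
#' @export
reduceTerms <- function(simMatrix, records, config = reductionConfig(),
                        graph = NULL, ic = NULL) {
  accs <- records$accession
  missingAcc <- setdiff(accs, simMatrix@terms)
  if (length(missingAcc))
    stop("records not covered by the similarity matrix: ",
         paste(missingAcc, collapse = ", "))
  C <- config@cutoff
  if (!length(accs)) {
    return(new("TermClusters",
               representatives = character(0),
               memberOf = setNames(character(0), character(0)),
               dispensability = setNames(numeric(0), character(0)),
               termUniqueness = setNames(numeric(0), character(0)),
               mergeLog = data.frame(removed = character(0),
                                     absorber = character(0),
                                     similarity = numeric(0)),
               cutoff = C))
  }

  M <- simMatrix@values[accs, accs, drop = FALSE]
  uniq <- termUniqueness(simMatrix, accs)

  reps <- accs
  disp <- setNames(rep(NA_real_, length(accs)), accs)
  member <- setNames(accs, accs)
  logRemoved <- character(0); logAbsorber <- character(0)
  logSim <- numeric(0)

  while (length(reps) > 1) {
    sub <- M[reps, reps, drop = FALSE]
    diag(sub) <- -Inf
    top <- max(sub)
    if (top < C) break
    hits <- which(sub == top, arr.ind = TRUE)
    pairA <- pmin(reps[hits[, 1]], reps[hits[, 2]])
    pairB <- pmax(reps[hits[, 1]], reps[hits[, 2]])
    ord <- order(pairA, pairB)[1]
    a <- pairA[ord]; b <- pairB[ord]
    loser <- chooseLoser(a, b, records, config,
                         graph = graph, ic = ic, uniqueness = uniq)
    winner <- if (loser == a) b else a
    disp[[loser]] <- top
    member[member == loser] <- winner
    logRemoved <- c(logRemoved, loser)
    logAbsorber <- c(logAbsorber, winner)
    logSim <- c(logSim, top)
    reps <- setdiff(reps, loser)
  }

  for (r in reps) {
    others <- setdiff(reps, r)
    disp[[r]] <- if (length(others)) max(M[r, others]) else 0
  }

  new("TermClusters",
      representatives = reps,
      memberOf = member,
      dispensability = disp,
      termUniqueness = uniq,
      mergeLog = data.frame(removed = logRemoved,
                            absorber = logAbsorber,
                            similarity = logSim,
                            stringsAsFactors = FALSE),
      cutoff = C)
}

#' Uniqueness-based priority order for value-free term lists
#'
#' When the user supplies no p-values or enrichments, the reduction cascade
#' compares uniqueness (negative mean similarity to all other terms) in
#' place of significance: semantic outliers are kept as representatives.
#' This helper exposes that priority order explicitly.
#'
#' @param simMatrix a \linkS4class{SimilarityMatrix}.
#' @param records a term-record data.frame with \code{valueKind "none"}.
#' @return accessions ordered from highest priority (kept first) to
#'   lowest; ties broken lexicographically.
#' @export
uniquenessRanking <- function(simMatrix, records) {
  if (valueKind(records) != "none")
    stop("uniquenessRanking applies only when no user values are supplied")
  uq <- termUniqueness(simMatrix, records$accession)
  records$accession[order(-uq, records$accession)]
}
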