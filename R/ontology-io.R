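#' Load an ontology from an OBO file
#'
#' Parses the OBO 1.2/1.4 flat-file format used to distribute the Gene
#' Ontology.  Only \code{[Term]} stanzas are interpreted; the keys read are
#' \code{id}, \code{name}, \code{namespace}, \code{is_a},
#' \code{relationship}, \code{is_obsolete}, \code{replaced_by} and
#' \code{alt_id}.  Traversal edges are built from the requested relations
#' (default \code{is_a} and \code{part_of}, both of which carry containment
#' semantics: an annotation to the child implies the parent).  Obsolete
#' terms are retained for identifier resolution but excluded from
#' traversal.  Terms without parents within their namespace become that
#' namespace's roots.  A cycle among traversal edges is a fatal error
#' naming the offending accessions.
#'
#' @param path path to an OBO file.
#' @param relations character vector of relation names to traverse;
#'   must be drawn from the known OBO relation vocabulary.
#' @return a validated \linkS4class{OntologyGraph}.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root"), obo)
#' g <- loadOBO(obo)
#' ancestors(g, "GO:0000002")
#' @export
loadOBO <- function(path, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  known <- c("is_a", "part_of", "regulates", "positively_regulates",
             "negatively_regulates", "occurs_in", "has_part", "happens_during")
  bad <- setdiff(relations, known)
  if (length(bad))
    stop("unknown relation name(s): ", paste(bad, collapse = ", "))

  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  stanzaStarts <- grep("^\\[", lines)
  if (!length(stanzaStarts)) stop("no stanzas found in OBO file: ", path)

  ids <- character(0); nm <- character(0); ns <- character(0)
  obso <- logical(0); repl <- character(0)
  parentsRaw <- list(); altRaw <- list()

  bounds <- c(stanzaStarts, length(lines) + 1L)
  for (k in seq_along(stanzaStarts)) {
    header <- lines[stanzaStarts[k]]
    if (header != "[Term]") next
    body <- lines[seq(stanzaStarts[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", "")
    vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else "", "")
    # trailing "! comment" annotations are not part of the value
    vals <- sub("\\s*!.*$", "", vals)

    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) next
    ids <- c(ids, id)
    nm <- c(nm, if (any(keys == "name")) vals[keys == "name"][1] else id)
    if (any(keys == "namespace")) {
      ns <- c(ns, vals[keys == "namespace"][1])
    } else {
      warning("term ", id, " has no namespace; assigned 'unknown'")
      ns <- c(ns, "unknown")
    }
    isObs <- any(keys == "is_obsolete" &
                 tolower(vals) %in% c("true", "true!"))
    obso <- c(obso, isObs)
    repl <- c(repl,
              if (any(keys == "replaced_by")) vals[keys == "replaced_by"][1]
              else NA_character_)
    par <- character(0)
    if ("is_a" %in% relations)
      par <- c(par, vals[keys == "is_a"])
    relLines <- vals[keys == "relationship"]
    if (length(relLines)) {
      relParts <- strsplit(relLines, "\\s+")
      for (rp in relParts)
        if (length(rp) >= 2 && rp[1] %in% relations)
          par <- c(par, rp[2])
    }
    parentsRaw[[id]] <- unique(par)
    altRaw[[id]] <- vals[keys == "alt_id"]
  }

  if (anyDuplicated(ids))
    stop("duplicate term accessions in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(nm) <- ids; names(ns) <- ids; names(obso) <- ids; names(repl) <- ids

  # traversal parents: resolvable, same-namespace, never for obsolete terms
  parents <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    if (obso[[id]]) { parents[[id]] <- character(0); next }
    par <- parentsRaw[[id]]
    par <- par[par %in% ids]
    par <- par[!obso[par]]
    par <- par[ns[par] == ns[[id]]]
    parents[[id]] <- par
  }

  .assertAcyclic(parents, ids[!obso])

  altIds <- character(0)
  for (id in ids) {
    a <- altRaw[[id]]
    if (length(a)) altIds[a] <- id
  }

  live <- ids[!obso]
  roots <- lapply(split(live, ns[live]), function(members) {
    members[vapply(parents[members], length, 0L) == 0L]
  })

  new("OntologyGraph",
      terms = ids, termName = nm, termNamespace = ns,
      parents = parents, obsolete = obso, replacedBy = repl,
      altIds = altIds, roots = roots)
}

# Kahn's algorithm over child->parent edges; leftovers lie on a cycle.
.assertAcyclic <- function(parents, nodes) {
  outdeg <- vapply(parents[nodes], length, 0L)
  children <- list()
  for (id in nodes)
    for (p in parents[[id]])
      children[[p]] <- c(children[[p]], id)
  queue <- nodes[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[id]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) {
    cyc <- nodes[outdeg[nodes] > 0L]
    stop("cycle detected in ontology involving: ",
         paste(sort(cyc), collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname ancestors
setMethod("ancestors", "OntologyGraph", function(x, accession) {
  stopifnot(length(accession) == 1)
  .checkKnown(x, accession)
  if (x@obsolete[[accession]])
    stop("term is obsolete and excluded from traversal: ", accession)
  out <- character(0)
  frontier <- x@parents[[accession]]
  while (length(frontier)) {
    newOnes <- setdiff(frontier, out)
    out <- c(out, newOnes)
    frontier <- unique(unlist(x@parents[newOnes], use.names = FALSE))
  }
  sort(out)
})

# ancestor sets for many terms at once, memoized along a topological order
.ancestorSets <- function(graph, accessions) {
  cache <- new.env(parent = emptyenv())
  getAnc <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    par <- graph@parents[[id]]
    anc <- if (length(par))
      unique(c(par, unlist(lapply(par, getAnc), use.names = FALSE)))
    else character(0)
    cache[[id]] <- anc
    anc
  }
  setNames(lapply(accessions, getAnc), accessions)
}

#' Resolve a raw identifier to its primary accession
#'
#' Primary accessions resolve to themselves (status \code{"ok"});
#' alternative identifiers resolve to their primary term (\code{"alt"});
#' obsolete terms resolve to their \code{replaced_by} target
#' (\code{"replaced"}) or, lacking one, are \code{"dropped"}.  Identifiers
#' absent from the ontology get status \code{"missing"}.  A string that is
#' not syntactically a term identifier is a format error.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param raw a single identifier string, e.g. \code{"GO:0008150"}.
#' @return list with elements \code{accession} (primary accession or
#'   \code{NA}) and \code{status}.
#' @export
resolveTerm <- function(graph, raw) {
  stopifnot(is.character(raw), length(raw) == 1)
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*:[A-Za-z0-9_]+$", raw))
    stop("not a syntactically valid term identifier: '", raw, "'")
  if (raw %in% graph@terms) {
    if (graph@obsolete[[raw]]) {
      rep <- graph@replacedBy[[raw]]
      if (!is.na(rep) && rep %in% graph@terms)
        return(list(accession = rep, status = "replaced"))
      return(list(accession = NA_character_, status = "dropped"))
    }
    return(list(accession = raw, status = "ok"))
  }
  if (raw %in% names(graph@altIds))
    return(list(accession = unname(graph@altIds[[raw]]), status = "alt"))
  list(accession = NA_character_, status = "missing")
}
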