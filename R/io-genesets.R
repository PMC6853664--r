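# GMT gene-set reader and a minimal OBO 1.2 is_a parser; the ontology DAG is
# held as an igraph (child -> parent edges) for cycle checks and depths.

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a line are deduplicated; membership is otherwise
#' preserved exactly.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> member genes).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character(0)))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, ",
           "members required)")
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members))
      stop("GMT line ", i, " defines an empty gene set")
    nms[i] <- f[1]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  setNames(sets, nms)
}

#' Read an ontology from an OBO 1.2 file
#'
#' Parses \code{[Term]} stanzas (id, name, is_a); obsolete terms are
#' excluded.  \code{part_of} relationships are ignored unless
#' \code{usePartOf = TRUE}.  The resulting graph must be acyclic and every
#' non-root term reachable from a root.
#'
#' @param path OBO file path.
#' @param usePartOf also treat \code{relationship: part_of} as a parent edge.
#' @return an \linkS4class{OntologyDAG}.
#' @export
readOBO <- function(path, usePartOf = FALSE) {
  lines <- readLines(path)
  inTerm <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && nzchar(cur$id))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = "", name = "", parents = character(0), obsolete = FALSE)
      inTerm <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # some other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      inTerm <- FALSE
      next
    }
    if (!inTerm || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    } else if (usePartOf && startsWith(ln, "relationship:")) {
      rest <- trimws(sub("^relationship:", "", ln))
      if (startsWith(rest, "part_of"))
        cur$parents <- c(cur$parents, trimws(sub("^part_of", "", rest)))
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  edges <- do.call(rbind, lapply(terms, function(tm) {
    par <- intersect(tm$parents, ids) # parents outside the file are dropped
    if (length(par)) cbind(child = tm$id, parent = par) else NULL
  }))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(cbind(edges[, "child"], edges[, "parent"])))
  if (!igraph::is_dag(g)) {
    cyc <- findCycle(edges)
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  roots <- ids[igraph::degree(g, mode = "out") == 0]
  # reachability: every non-root must reach a root along is_a edges
  if (length(ids)) {
    reach <- igraph::distances(g, v = ids, to = roots, mode = "out")
    bad <- ids[!apply(is.finite(reach), 1, any)]
    if (length(bad))
      stop("term(s) unreachable from any root: ", paste(bad, collapse = ", "))
  }
  new("OntologyDAG", graph = g,
      terms = data.frame(id = ids,
                         name = vapply(terms, `[[`, "", "name"),
                         row.names = NULL),
      roots = roots)
}

# locate one directed cycle in an edge list (child -> parent), for error text
findCycle <- function(edges) {
  adj <- split(edges[, "parent"], edges[, "child"])
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = "new")[[1]]
    if (identical(st, "active")) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (identical(st, "done")) return()
    assign(v, "active", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, "done", envir = state)
  }
  for (v in unique(edges[, "child"])) {
    visit(v)
    if (!is.null(found)) break
  }
  found
}

#' Term depth in the ontology
#'
#' Depth is the shortest-path distance (in is_a edges) from the term to any
#' root, the usual proxy for term specificity: roots have depth 0.
#'
#' @param x an \linkS4class{OntologyDAG}.
#' @param terms term ids (default: all terms).
#' @return named integer vector of depths.
#' @export
setMethod("termDepth", "OntologyDAG", function(x, terms = NULL) {
  if (is.null(terms)) terms <- x@terms$id
  bad <- setdiff(terms, x@terms$id)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  d <- igraph::distances(x@graph, v = terms, to = x@roots, mode = "out")
  setNames(as.integer(apply(d, 1, min)), terms)
})

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", nrow(object@terms), "terms and",
      length(object@roots), "root(s)\n")
})
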