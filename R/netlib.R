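# Enumeration of labeled three-node regulatory structures (nodes G, x, y; no
# self-edges; signed edges; AND/OR gates on two-input nodes), kinetic
# parameter sampling, and genetic-condition variants (WT/KO/KI/INHIB).

NODES <- c("G", "x", "y")
# the 6 ordered node pairs, fixed enumeration order
EDGE_FROM <- c("G", "G", "x", "x", "y", "y")
EDGE_TO <- c("x", "y", "G", "y", "G", "x")
EDGE_NAMES <- paste0(EDGE_FROM, ">", EDGE_TO)

#' Enumerate unique three-node regulatory structures
#'
#' All 3^6 = 729 assignments of \{absent, activate, inhibit\} to the six
#' ordered node pairs (no self-edges), expanded with an AND/OR gate for every
#' node of in-degree 2 (13^3 = 2197 gated structures), then reduced by the
#' configured exclusion filters.  Nodes are labeled (G = perturbed gene,
#' x = rest-of-genome proxy, y = gene of interest), so uniqueness is exact
#' structural equality of the canonical key, not graph isomorphism.
#' Enumeration is pure combinatorics: output order and content are identical
#' across runs and platforms.
#'
#' Available filters:
#' \describe{
#'   \item{dropIsolatedNodes}{remove structures containing a node with
#'     in-degree 0 and out-degree 0 (the model degenerates to fewer than
#'     three interacting nodes).  This is the default and yields the 2172
#'     model library.}
#'   \item{dropUnregulatableY}{remove structures where y has no incoming
#'     edge at all (y cannot respond to anything).}
#'   \item{requirePathGToY}{keep only structures with a directed path from
#'     G to y.}
#'   \item{dropAllAbsent}{remove the empty structure.}
#' }
#'
#' @param gates expand AND/OR gates on in-degree-2 nodes (default TRUE).
#' @param filters character vector of filter names (possibly empty).
#' @return data.frame with canonical \code{key}, six edge columns (values
#'   -1/0/+1, named \code{G>x} etc.) and gate columns \code{gateG},
#'   \code{gateX}, \code{gateY} (\code{"AND"}, \code{"OR"} or \code{"."}).
#' @export
enumerateStructures <- function(gates = TRUE,
                                filters = "dropIsolatedNodes") {
  if (length(filters))
    filters <- match.arg(filters,
                         c("dropIsolatedNodes", "dropUnregulatableY",
                           "requirePathGToY", "dropAllAbsent"),
                         several.ok = TRUE)
  base <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 6L),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(base) <- EDGE_NAMES
  indeg <- vapply(NODES, function(n)
    rowSums(base[, EDGE_TO == n, drop = FALSE] != 0L), numeric(nrow(base)))
  if (gates) {
    rows <- list()
    gateChoices <- lapply(seq_len(nrow(base)), function(i) {
      opts <- lapply(NODES, function(n)
        if (indeg[i, n] == 2) c("AND", "OR") else ".")
      as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE))
    })
    reps <- vapply(gateChoices, nrow, integer(1))
    edges <- base[rep(seq_len(nrow(base)), reps), , drop = FALSE]
    gm <- do.call(rbind, gateChoices)
    colnames(gm) <- paste0("gate", c("G", "X", "Y"))
    out <- data.frame(edges, gm, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(base,
                      gateG = ".", gateX = ".", gateY = ".",
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  keep <- rep(TRUE, nrow(out))
  em <- as.matrix(out[, EDGE_NAMES])
  indegAll <- vapply(NODES, function(n)
    rowSums(em[, EDGE_TO == n, drop = FALSE] != 0L), numeric(nrow(out)))
  outdegAll <- vapply(NODES, function(n)
    rowSums(em[, EDGE_FROM == n, drop = FALSE] != 0L), numeric(nrow(out)))
  if ("dropIsolatedNodes" %in% filters)
    keep <- keep & !apply(indegAll == 0 & outdegAll == 0, 1, any)
  if ("dropUnregulatableY" %in% filters)
    keep <- keep & indegAll[, "y"] > 0
  if ("requirePathGToY" %in% filters) {
    gy <- em[, "G>y"] != 0L
    gxy <- em[, "G>x"] != 0L & em[, "x>y"] != 0L
    keep <- keep & (gy | gxy)
  }
  if ("dropAllAbsent" %in% filters)
    keep <- keep & rowSums(em != 0L) > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  key <- structureKey(out)
  if (anyDuplicated(key)) stop("internal error: duplicate structure keys")
  cbind(data.frame(key = key, stringsAsFactors = FALSE), out)
}

#' Canonical structure key
#'
#' Serializes the six signed edges and three gates into a unique string, e.g.
#' \code{"+0-00+|A.O"} (edge characters in the fixed pair order
#' G>x, G>y, x>G, x>y, y>G, y>x; gate characters for G, x, y).
#'
#' @param structures data.frame with the six edge columns and three gate
#'   columns as produced by \code{enumerateStructures}.
#' @return character vector of keys.
#' @export
structureKey <- function(structures) {
  em <- as.matrix(structures[, EDGE_NAMES, drop = FALSE])
  ec <- matrix(c("-", "0", "+")[em + 2L], nrow = nrow(em))
  gm <- as.matrix(structures[, paste0("gate", c("G", "X", "Y")), drop = FALSE])
  gc <- matrix(substr(gm, 1, 1), nrow = nrow(gm))
  paste0(apply(ec, 1, paste, collapse = ""), "|",
         apply(gc, 1, paste, collapse = ""))
}

#' Default kinetic parameter ranges
#'
#' Log-uniform sampling ranges chosen to give order-one steady states
#' compatible with 0-1 normalization of the simulated species: maximal
#' transcription v and translation k in [0.5, 2], degradation rates in
#' [0.1, 1] per minute, half-saturation K in [0.1, 1], Hill coefficient h
#' drawn from \{1, 2, 4\}; basal transcription alpha = 0.05 v.
#'
#' @return named list of ranges.
#' @export
defaultKineticRanges <- function() {
  list(v = c(0.5, 2), k = c(0.5, 2), gammam = c(0.1, 1), gammap = c(0.1, 1),
       K = c(0.1, 1), h = c(1, 2, 4), alphaFrac = 0.05)
}

logUnif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Sample kinetic parameters for one structure
#'
#' Draws per-node rates and per-edge Hill parameters from the configured
#' log-uniform ranges.  Sampling is fully determined by (seed, structure
#' key): the same inputs give byte-identical parameter sets.
#'
#' @param structure one row of \code{enumerateStructures} output (or any
#'   list with the edge/gate/key fields).
#' @param seed integer master seed.
#' @param ranges kinetic ranges, see \code{\link{defaultKineticRanges}}.
#' @param sigmaDyn intrinsic (chemical-Langevin) noise amplitude.
#' @return an object of class \code{SDEModel}: structure plus parameters.
#' @export
sampleParameters <- function(structure, seed = 1L,
                             ranges = defaultKineticRanges(),
                             sigmaDyn = 0.05) {
  key <- as.character(structure[["key"]])
  edges <- matrix(0L, 3, 3, dimnames = list(NODES, NODES))
  for (j in seq_along(EDGE_NAMES))
    edges[EDGE_FROM[j], EDGE_TO[j]] <- as.integer(structure[[EDGE_NAMES[j]]])
  gatesV <- setNames(unlist(structure[paste0("gate", c("G", "X", "Y"))],
                            use.names = FALSE), NODES)
  withSeed(substreamSeed(seed, key, "params"), {
    v <- logUnif(3, ranges$v)
    k <- logUnif(3, ranges$k)
    gammam <- logUnif(3, ranges$gammam)
    gammap <- logUnif(3, ranges$gammap)
    h <- matrix(sample(ranges$h, 9, replace = TRUE), 3, 3,
                dimnames = list(NODES, NODES))
    K <- matrix(logUnif(9, ranges$K), 3, 3, dimnames = list(NODES, NODES))
    names(v) <- names(k) <- names(gammam) <- names(gammap) <- NODES
    model <- list(key = key, edges = edges, gates = gatesV,
                  alpha = ranges$alphaFrac * v, v = v, k = k,
                  gammam = gammam, gammap = gammap, h = h, K = K,
                  sigmaDyn = sigmaDyn,
                  condition = conditionWT())
    class(model) <- "SDEModel"
    model
  })
}

#' Genetic / chemical condition descriptors
#'
#' \code{conditionWT} leaves the model untouched; \code{conditionKO} removes
#' G transcription entirely; \code{conditionKI} pins G mRNA production at
#' its constitutive maximum (alpha + v) irrespective of regulators and
#' stimulus; \code{conditionInhib} scales the regulatory activity of the G
#' protein on its targets by \code{strength} in [0, 1] (1 is equivalent to
#' wild type).
#'
#' @param strength inhibition multiplier in [0, 1].
#' @return a condition list with fields kind and strength.
#' @export
conditionWT <- function() list(kind = "WT", strength = 1)

#' @rdname conditionWT
#' @export
conditionKO <- function() list(kind = "KO", strength = 1)

#' @rdname conditionWT
#' @export
conditionKI <- function() list(kind = "KI", strength = 1)

#' @rdname conditionWT
#' @export
conditionInhib <- function(strength = 0.1) {
  stopifnot(strength >= 0, strength <= 1)
  list(kind = "INHIB", strength = strength)
}

conditionLabel <- function(condition) {
  if (condition$kind == "INHIB")
    paste0("INHIB", format(condition$strength)) else condition$kind
}

#' Apply a genetic condition to a model
#'
#' Returns the model tagged with the condition; the simulator interprets the
#' tag (KO: zero G transcription; KI: constitutive G mRNA production;
#' INHIB: scaled G-protein activity).  Idempotent for KO and KI; WT is the
#' identity.
#'
#' @param model an SDEModel.
#' @param condition a condition from \code{\link{conditionWT}} and friends.
#' @return the conditioned SDEModel.
#' @export
applyCondition <- function(model, condition) {
  if (!condition$kind %in% c("WT", "KO", "KI", "INHIB"))
    stop("unknown condition kind: ", condition$kind)
  model$condition <- condition
  model
}

#' Build the default SDE model library
#'
#' Enumerates the structures and samples one kinetic parameter set per
#' structure.  With the default filters the library contains 2172 uniquely
#' structured models.
#'
#' @inheritParams enumerateStructures
#' @inheritParams sampleParameters
#' @return a \linkS4class{ModelLibrary}.
#' @export
buildLibrary <- function(seed = 1L, gates = TRUE,
                         filters = "dropIsolatedNodes",
                         ranges = defaultKineticRanges(), sigmaDyn = 0.05) {
  st <- enumerateStructures(gates = gates, filters = filters)
  models <- lapply(seq_len(nrow(st)), function(i)
    sampleParameters(st[i, ], seed = seed, ranges = ranges,
                     sigmaDyn = sigmaDyn))
  names(models) <- st$key
  new("ModelLibrary", structures = st, models = models,
      filters = as.character(filters), seed = as.integer(seed),
      ranges = ranges)
}

#' @describeIn buildLibrary structure table of a library
#' @param x a ModelLibrary.
#' @export
setMethod("modelStructures", "ModelLibrary", function(x) x@structures)

#' @describeIn buildLibrary the parameterized models
#' @export
setMethod("libraryModels", "ModelLibrary", function(x) x@models)

#' @describeIn buildLibrary canonical structure keys
#' @export
setMethod("structureKeys", "ModelLibrary", function(x) x@structures$key)

#' @describeIn buildLibrary number of models
#' @export
setMethod("length", "ModelLibrary", function(x) nrow(x@structures))

setMethod("show", "ModelLibrary", function(object) {
  cat("ModelLibrary:", nrow(object@structures),
      "uniquely structured three-node SDE models\n")
  cat("filters:", if (length(object@filters))
    paste(object@filters, collapse = ", ") else "(none)",
    " seed:", object@seed, "\n")
})

#' Serialize / restore a model library as JSON lines
#'
#' One JSON record per model (structure key, edges, gates, parameters).
#'
#' @param library a \linkS4class{ModelLibrary}.
#' @param path output (input) file path.
#' @return \code{writeLibrary}: the path, invisibly; \code{readLibrary}: a
#'   ModelLibrary.
#' @export
writeLibrary <- function(library, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- list(type = "header", filters = library@filters,
               seed = library@seed, ranges = library@ranges)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  for (m in library@models) {
    rec <- list(type = "model", key = m$key, edges = m$edges,
                gates = as.list(m$gates), alpha = m$alpha, v = m$v, k = m$k,
                gammam = m$gammam, gammap = m$gammap, h = m$h, K = m$K,
                sigmaDyn = m$sigmaDyn)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  ranges <- hdr$ranges
  ranges$h <- as.numeric(ranges$h)
  models <- lapply(lines[-1], function(ln) {
    r <- jsonlite::fromJSON(ln)
    dimn <- list(NODES, NODES)
    edges <- matrix(as.integer(r$edges), 3, 3, dimnames = dimn)
    structure(list(key = r$key, edges = edges,
                   gates = setNames(unlist(r$gates), NODES),
                   alpha = setNames(as.numeric(r$alpha), NODES),
                   v = setNames(as.numeric(r$v), NODES),
                   k = setNames(as.numeric(r$k), NODES),
                   gammam = setNames(as.numeric(r$gammam), NODES),
                   gammap = setNames(as.numeric(r$gammap), NODES),
                   h = matrix(as.numeric(r$h), 3, 3, dimnames = dimn),
                   K = matrix(as.numeric(r$K), 3, 3, dimnames = dimn),
                   sigmaDyn = r$sigmaDyn,
                   condition = conditionWT()),
              class = "SDEModel")
  })
  keys <- vapply(models, `[[`, "", "key")
  names(models) <- keys
  st <- structuresFromModels(models)
  new("ModelLibrary", structures = st, models = models,
      filters = as.character(hdr$filters), seed = as.integer(hdr$seed),
      ranges = ranges)
}

structuresFromModels <- function(models) {
  rows <- lapply(models, function(m) {
    e <- vapply(seq_along(EDGE_NAMES), function(j)
      m$edges[EDGE_FROM[j], EDGE_TO[j]], integer(1))
    c(as.list(setNames(e, EDGE_NAMES)),
      list(gateG = unname(m$gates["G"]), gateX = unname(m$gates["x"]),
           gateY = unname(m$gates["y"])))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame, check.names = FALSE))
  rownames(df) <- NULL
  cbind(data.frame(key = vapply(models, `[[`, "", "key"),
                   stringsAsFactors = FALSE, row.names = NULL), df)
}

#' @export
print.SDEModel <- function(x, ...) {
  on <- which(x$edges != 0L, arr.ind = TRUE)
  desc <- if (nrow(on)) paste(NODES[on[, 1]],
                              ifelse(x$edges[on] > 0, "->", "-|"),
                              NODES[on[, 2]], collapse = ", ") else "(empty)"
  cat("SDEModel", x$key, ":", desc, "\n")
  cat("condition:", conditionLabel(x$condition), "\n")
  invisible(x)
}
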