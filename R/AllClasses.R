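# S4 classes for the timecourse container, moderated fits, contrast results,
# discrete profile sets, the SDE model library, and matched ensembles.

#' TimecourseExperiment: replicated multi-condition expression time course
#'
#' Extends \linkS4class{SummarizedExperiment}.  The single assay
#' (\code{"log2expr"}) holds log2-scale expression values (genes x samples);
#' \code{colData} carries the mandatory columns \code{condition},
#' \code{time} (minutes) and \code{replicate}.  Input is assumed already
#' normalized and log2-transformed; missing values are rejected, not imputed,
#' because the contrast machinery assumes complete replicate blocks.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
  cd <- colData(object)
  need <- c("condition", "time", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (length(assays(object)) < 1L) return("an assay is required")
  a <- assay(object)
  if (any(!is.finite(a))) return("expression values must be finite (no NAs)")
  if (anyDuplicated(rownames(object))) return("gene identifiers must be unique")
  if (anyDuplicated(colnames(object))) return("sample identifiers must be unique")
  if (any(cd$time < 0)) return("time must be non-negative (minutes)")
  if (any(cd$replicate < 1)) return("replicate indices must be positive")
  cell <- paste(cd$condition, cd$time, sep = "@")
  nrep <- table(cell)
  if (any(nrep < 2L))
    return(paste0("every (condition, time) cell needs >= 2 replicates; ",
                  "offending cell(s): ",
                  paste(names(nrep)[nrep < 2L], collapse = ", ")))
  TRUE
})

#' ModeratedFit: gene-wise cell-mean fit with empirical-Bayes moderation
#'
#' Holds per-gene cell means for every (condition, time) cell of a two
#' condition design, the pooled residual variance, and the posterior
#' (moderated) variance after squeezing towards the empirical prior.
#'
#' @slot coefficients genes x cells matrix of cell means (log2 units).
#' @slot cellCondition,cellTime condition label / time (minutes) per cell.
#' @slot cellN replicates per cell.
#' @slot sigma2 per-gene residual variance; \code{dfResidual} its df.
#' @slot dfPrior,s2Prior empirical-Bayes prior df and variance.
#' @slot s2Post per-gene posterior (moderated) variance.
#' @slot control,experimental the two condition labels of the design.
#' @slot times ordered time grid shared by both conditions.
#' @export
setClass("ModeratedFit", representation(
  coefficients = "matrix",
  cellCondition = "character",
  cellTime = "numeric",
  cellN = "integer",
  sigma2 = "numeric",
  dfResidual = "numeric",
  dfPrior = "numeric",
  s2Prior = "numeric",
  s2Post = "numeric",
  control = "character",
  experimental = "character",
  times = "numeric"
))

setValidity("ModeratedFit", function(object) {
  if (length(object@s2Post) != nrow(object@coefficients))
    return("s2Post length must match gene count")
  if (length(object@dfPrior) == 1 && is.finite(object@dfPrior) &&
      object@dfPrior < 0) return("dfPrior must be >= 0")
  lo <- pmin(object@sigma2, rep(object@s2Prior, length(object@sigma2)))
  hi <- pmax(object@sigma2, rep(object@s2Prior, length(object@sigma2)))
  if (length(object@s2Prior) == 1 && is.finite(object@s2Prior) &&
      (any(object@s2Post < lo - 1e-8) || any(object@s2Post > hi + 1e-8)))
    return("s2Post must lie between sigma2 and s2Prior (shrinkage)")
  TRUE
})

#' ContrastResult: moderated statistics for one contrast family
#'
#' @slot family one of PW, TS, AR, PW-TS, PW-AR.
#' @slot lfc genes x contrasts matrix of log2 fold changes.
#' @slot t moderated t statistics; \code{p}, \code{pAdj} the per-contrast
#'   two-sided p-values and their BH adjustment (across genes, per column).
#' @slot fStat,fP,fPAdj moderated family F statistic and (adjusted) p.
#' @slot df1,df2 F numerator / denominator degrees of freedom.
#' @export
setClass("ContrastResult", representation(
  family = "character",
  lfc = "matrix",
  t = "matrix",
  p = "matrix",
  pAdj = "matrix",
  fStat = "numeric",
  fP = "numeric",
  fPAdj = "numeric",
  df1 = "numeric",
  df2 = "numeric"
))

setValidity("ContrastResult", function(object) {
  if (!object@family %in% CONTRAST_FAMILIES)
    return(paste("unknown contrast family:", object@family))
  if (!all(dim(object@lfc) == dim(object@p)))
    return("lfc and p must have identical dimensions")
  if (any(object@pAdj < object@p - 1e-12))
    return("adjusted p-values cannot be smaller than raw p-values")
  TRUE
})

#' DiscreteProfileSet: ternary response profiles for one contrast family
#'
#' @slot family the contrast family the profiles were derived from.
#' @slot profiles genes x contrasts integer matrix with entries in
#'   \{-1, 0, +1\}.
#' @slot pCut the significance threshold used for discretization.
#' @export
setClass("DiscreteProfileSet", representation(
  family = "character",
  profiles = "matrix",
  pCut = "numeric"
))

setValidity("DiscreteProfileSet", function(object) {
  if (!all(object@profiles %in% c(-1L, 0L, 1L)))
    return("profiles must be ternary (-1, 0, +1)")
  TRUE
})

#' ModelLibrary: enumerated three-node SDE models with sampled kinetics
#'
#' @slot structures data.frame of unique signed structures (one row per
#'   model): canonical \code{key}, six edge columns, three gate columns.
#' @slot models named list of SDEModel parameter sets (one per structure).
#' @slot filters character vector of exclusion filters applied.
#' @slot seed master seed used for kinetic parameter sampling.
#' @slot ranges kinetic parameter sampling ranges.
#' @export
setClass("ModelLibrary", representation(
  structures = "data.frame",
  models = "list",
  filters = "character",
  seed = "integer",
  ranges = "list"
))

setValidity("ModelLibrary", function(object) {
  if (anyDuplicated(object@structures$key))
    return("structure keys must be unique")
  if (length(object@models) &&
      !identical(names(object@models), object@structures$key))
    return("models must be named by (and ordered as) the structure keys")
  TRUE
})

#' EnsembleSet: per-gene sets of library models matched by discrete profile
#'
#' @slot genes gene identifiers.
#' @slot profiles genes x contrasts ternary matrix (the matching keys).
#' @slot matched named list: for each gene, the character vector of matched
#'   model keys (possibly empty: an unmatched gene).
#' @slot family contrast family used for matching (default PW).
#' @export
setClass("EnsembleSet", representation(
  genes = "character",
  profiles = "matrix",
  matched = "list",
  family = "character"
))

setValidity("EnsembleSet", function(object) {
  if (length(object@matched) != length(object@genes))
    return("one matched set per gene required")
  TRUE
})

#' OntologyDAG: a parsed is_a ontology hierarchy
#'
#' @slot graph directed igraph, edges child -> parent.
#' @slot terms data.frame with columns id, name.
#' @slot roots term ids with no parents.
#' @export
setClass("OntologyDAG", representation(
  graph = "ANY",
  terms = "data.frame",
  roots = "character"
))

CONTRAST_FAMILIES <- c("PW", "TS", "AR", "PW-TS", "PW-AR")
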