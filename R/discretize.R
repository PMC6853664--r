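# Ternary discretization of contrast results, DEG/dDEG/DRG classification,
# profile clustering and pattern predicates over discrete entries.

#' Discretize a contrast result into ternary profiles
#'
#' Entrywise map: +1 if the LFC is positive and its adjusted p-value is
#' below \code{pCut}; -1 if negative and significant; 0 otherwise (including
#' an exactly-zero LFC, whose sign is 0).  An optional magnitude filter
#' zeroes entries with |LFC| below \code{lfcMin} (off by default).
#'
#' @param result a \linkS4class{ContrastResult}.
#' @param pCut significance threshold on the adjusted p-value, in (0, 1).
#' @param lfcMin minimum |LFC| for a non-zero call (0 disables).
#' @return a \linkS4class{DiscreteProfileSet}.
#' @export
discretizeContrasts <- function(result, pCut = 0.05, lfcMin = 0) {
  stopifnot(pCut > 0, pCut < 1, lfcMin >= 0)
  lfc <- result@lfc
  pAdj <- result@pAdj
  if (!all(dim(lfc) == dim(pAdj)))
    stop("lfc and adjusted p-value matrices differ in shape")
  d <- sign(lfc)
  d[pAdj >= pCut] <- 0
  if (lfcMin > 0) d[abs(lfc) < lfcMin] <- 0
  storage.mode(d) <- "integer"
  new("DiscreteProfileSet", family = result@family, profiles = d, pCut = pCut)
}

#' @describeIn discretizeContrasts the ternary genes x contrasts matrix
#' @param x a DiscreteProfileSet.
#' @export
setMethod("profileMatrix", "DiscreteProfileSet", function(x) x@profiles)

#' @describeIn discretizeContrasts contrast family of a profile set
#' @export
setMethod("contrastFamily", "DiscreteProfileSet", function(x) x@family)

setMethod("show", "DiscreteProfileSet", function(object) {
  nz <- mean(object@profiles != 0)
  cat("DiscreteProfileSet (", object@family, "): ", nrow(object@profiles),
      " genes x ", ncol(object@profiles), " contrasts; ",
      sprintf("%.1f%%", 100 * nz), " non-zero entries (pCut = ",
      object@pCut, ")\n", sep = "")
})

#' Classify genes as DEG / dDEG / DRG
#'
#' A DEG is differentially expressed between conditions at one or more time
#' points (adjusted PW-family F p below \code{pCut}).  A dDEG is a DEG whose
#' discrete PW profile is non-constant over time (it may be undetectable at
#' time 0 yet respond later).  A DRG is a DEG whose between-condition LFC
#' itself changes significantly over time: at least one non-zero entry in
#' the discrete PW-TS or PW-AR profile.  By definition every dDEG and DRG is
#' also a DEG.
#'
#' @param pwResult \linkS4class{ContrastResult} for the PW family (supplies
#'   the overall F test).
#' @param pwProfiles,pwtsProfiles,pwarProfiles
#'   \linkS4class{DiscreteProfileSet}s for the PW, PW-TS and PW-AR families.
#' @param pCut significance threshold for the F test.
#' @return data.frame with columns gene, isDEG, isDDEG, isDRG.
#' @export
classifyGenes <- function(pwResult, pwProfiles, pwtsProfiles, pwarProfiles,
                          pCut = 0.05) {
  if (contrastFamily(pwProfiles) != "PW" || contrastFamily(pwResult) != "PW")
    stop("PW family results are required")
  if (contrastFamily(pwtsProfiles) != "PW-TS")
    stop("PW-TS profiles are required")
  if (contrastFamily(pwarProfiles) != "PW-AR")
    stop("PW-AR profiles are required")
  pw <- profileMatrix(pwProfiles)
  isDEG <- overallFP(pwResult) < pCut
  nonConstant <- apply(pw, 1, function(r) length(unique(r)) > 1L)
  temporal <- rowSums(abs(profileMatrix(pwtsProfiles))) > 0 |
    rowSums(abs(profileMatrix(pwarProfiles))) > 0
  data.frame(gene = rownames(pw),
             isDEG = unname(isDEG),
             isDDEG = unname(isDEG & nonConstant),
             isDRG = unname(isDEG & temporal),
             row.names = NULL)
}

#' Cluster genes by identical discrete profile
#'
#' Exact grouping on the ternary vector.  For T time points the PW family
#' has 3^T possible keys; the other families have 3^(T-1) (one key per
#' ternary contrast vector), so the number of occupied clusters can never
#' exceed those bounds.
#'
#' @param profiles a \linkS4class{DiscreteProfileSet}.
#' @return data.frame with columns key, n and a list-column members;
#'   clusters partition the gene set.
#' @export
clusterByProfile <- function(profiles) {
  pm <- profileMatrix(profiles)
  keys <- apply(pm, 1, profileKey)
  grp <- split(rownames(pm), keys)
  data.frame(key = names(grp),
             n = lengths(grp),
             members = I(unname(grp)),
             row.names = NULL)
}

#' Pattern predicates over discrete profiles
#'
#' \code{patternRule} states that the discrete entry of \code{family} at
#' contrast position \code{index} equals \code{value}; \code{ruleAll} /
#' \code{ruleAny} combine rules with AND / OR.  \code{applyRule} evaluates a
#' rule against a named list of \linkS4class{DiscreteProfileSet}s and
#' returns the member genes, enabling derived clusters such as "lower LFC
#' at the final time than at time 0" (an AR-family entry of -1 at the last
#' position) or slope-sign groups over chosen steps.
#'
#' @param family contrast family name the rule applies to.
#' @param index contrast position (1-based) within the family.
#' @param value required ternary value (-1, 0 or +1).
#' @return for \code{patternRule}/\code{ruleAll}/\code{ruleAny}, a rule
#'   object; for \code{applyRule}, the character vector of genes satisfying
#'   the rule.
#' @export
patternRule <- function(family, index, value) {
  stopifnot(value %in% c(-1L, 0L, 1L), index >= 1L)
  structure(list(kind = "atom", family = family, index = as.integer(index),
                 value = as.integer(value)), class = "patternRule")
}

#' @rdname patternRule
#' @param ... rules to combine.
#' @export
ruleAll <- function(...) structure(list(kind = "all", rules = list(...)),
                                   class = "patternRule")

#' @rdname patternRule
#' @export
ruleAny <- function(...) structure(list(kind = "any", rules = list(...)),
                                   class = "patternRule")

#' @rdname patternRule
#' @param rule a rule built with \code{patternRule}/\code{ruleAll}/\code{ruleAny}.
#' @param profiles named list of DiscreteProfileSet, keyed by family.
#' @export
applyRule <- function(rule, profiles) {
  sel <- evalRule(rule, profiles)
  names(sel)[sel]
}

evalRule <- function(rule, profiles) {
  if (rule$kind == "atom") {
    ps <- profiles[[rule$family]]
    if (is.null(ps)) stop("no profiles provided for family ", rule$family)
    pm <- profileMatrix(ps)
    if (rule$index > ncol(pm))
      stop("rule references contrast index ", rule$index, " but family ",
           rule$family, " has only ", ncol(pm), " contrasts")
    setNames(pm[, rule$index] == rule$value, rownames(pm))
  } else {
    parts <- lapply(rule$rules, evalRule, profiles = profiles)
    out <- parts[[1]]
    for (p in parts[-1]) {
      p <- p[names(out)]
      out <- if (rule$kind == "all") out & p else out | p
    }
    out
  }
}
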