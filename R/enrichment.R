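# Hypergeometric over-representation of gene sets in discrete clusters,
# exclusive grouping of enriched terms across gene classes, and a
# permutation-based discrete two-sample KS comparison of term depths.

#' Hypergeometric enrichment of gene sets in a cluster
#'
#' One-sided (upper tail) hypergeometric test per gene set: the probability
#' of drawing at least the observed overlap when sampling the cluster from
#' the universe.  Sets are intersected with the universe before testing
#' (guarding against detection bias); BH adjustment is applied across all
#' sets tested for the cluster.
#'
#' @param cluster character vector of genes (must be a subset of
#'   \code{universe}).
#' @param sets named list of gene sets (e.g. from \code{\link{readGMT}}).
#' @param universe character vector of background genes (typically all genes
#'   present in the expression matrix after input filtering).
#' @return data.frame: set, k (overlap), n (cluster size), K (set size in
#'   universe), N (universe size), p, pAdj; ordered by p.
#' @export
hypergeomEnrich <- function(cluster, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  cluster <- unique(cluster)
  out <- setdiff(cluster, universe)
  if (length(out))
    stop("cluster gene(s) outside the universe: ",
         paste(head(out, 5), collapse = ", "))
  N <- length(universe)
  n <- length(cluster)
  rows <- lapply(names(sets), function(nm) {
    Kset <- intersect(sets[[nm]], universe)
    K <- length(Kset)
    k <- length(intersect(Kset, cluster))
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, p = p)
  })
  res <- do.call(rbind, rows)
  res$pAdj <- bhAdjust(res$p)
  res[order(res$p, res$set), , drop = FALSE]
}

#' Group enriched terms by exclusive class intersection
#'
#' Genes may carry several class labels (DEG, dDEG, DRG, ...), but each
#' enriched term is assigned to exactly one group: the exact combination of
#' classes in which it is enriched (e.g. a term enriched for both DEGs and
#' dDEGs goes to the "DEG&dDEG" group; one enriched only for dDEGs goes to
#' "dDEG").  The groups therefore partition the enriched terms.
#'
#' @param enriched named list: class name -> character vector of enriched
#'   term ids.
#' @return data.frame with columns term, group.
#' @export
groupTermsExclusively <- function(enriched) {
  classes <- names(enriched)
  if (is.null(classes)) stop("enriched must be a named list of term vectors")
  terms <- unique(unlist(enriched, use.names = FALSE))
  if (!length(terms))
    return(data.frame(term = character(0), group = character(0)))
  grp <- vapply(terms, function(tm) {
    inClass <- classes[vapply(enriched, function(v) tm %in% v, logical(1))]
    paste(inClass, collapse = "&")
  }, character(1))
  data.frame(term = terms, group = unname(grp), row.names = NULL)
}

#' Discrete two-sample KS comparison of term-depth distributions
#'
#' The statistic is the maximum absolute gap between the two empirical
#' distribution functions; because depths are small integers (heavily tied),
#' the p-value is computed by label permutation (default 10,000 shuffles,
#' seeded) rather than the asymptotic continuous-case formula.
#'
#' @param depthsA,depthsB integer depth samples (both non-empty).
#' @param nPerm number of label permutations.
#' @param seed permutation seed.
#' @return list with statistic and p.
#' @export
depthCompare <- function(depthsA, depthsB, nPerm = 10000, seed = 1L) {
  if (!length(depthsA) || !length(depthsB))
    stop("both depth samples must be non-empty")
  obs <- ksStatistic(depthsA, depthsB)
  pooled <- c(depthsA, depthsB)
  nA <- length(depthsA)
  count <- withSeed(substreamSeed(seed, "ks-perm", nA, length(pooled)), {
    hits <- 0L
    for (i in seq_len(nPerm)) {
      idx <- sample.int(length(pooled), nA)
      if (ksStatistic(pooled[idx], pooled[-idx]) >= obs - 1e-12)
        hits <- hits + 1L
    }
    hits
  })
  list(statistic = obs, p = (count + 1) / (nPerm + 1))
}

# max absolute ECDF gap over the pooled support (exact for ties)
ksStatistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}
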