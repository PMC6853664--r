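# Matching genes to library models by identical discrete profile, ensemble
# median prediction with a bootstrap band, MSE scoring against a
# random-model null, and ranking / evaluation (Spearman, AUROC, AUPR,
# elbow rule, Wilcoxon signed-rank).

#' Match genes to library models with identical discrete profiles
#'
#' A gene matches every library model whose simulated discrete profile
#' equals the gene's profile entrywise.  The matched set may be empty (an
#' unmatched gene, reported but never an error at this stage).
#'
#' @param geneProfiles \linkS4class{DiscreteProfileSet} of the genes.
#' @param libProfiles \linkS4class{DiscreteProfileSet} of the library models
#'   (same family, same number of contrasts).
#' @return an \linkS4class{EnsembleSet}.
#' @export
matchProfiles <- function(geneProfiles, libProfiles) {
  if (contrastFamily(geneProfiles) != contrastFamily(libProfiles))
    stop("gene and library profiles must be from the same contrast family")
  gp <- profileMatrix(geneProfiles)
  lp <- profileMatrix(libProfiles)
  if (ncol(gp) != ncol(lp))
    stop("profile length mismatch: genes have ", ncol(gp),
         " entries, library has ", ncol(lp))
  libKeys <- split(rownames(lp), apply(lp, 1, profileKey))
  geneKeys <- apply(gp, 1, profileKey)
  matched <- lapply(geneKeys, function(k) {
    hit <- libKeys[[k]]
    if (is.null(hit)) character(0) else hit
  })
  names(matched) <- rownames(gp)
  new("EnsembleSet", genes = rownames(gp), profiles = gp, matched = matched,
      family = contrastFamily(geneProfiles))
}

#' @describeIn matchProfiles matched model keys for one gene
#' @param x an EnsembleSet.
#' @param gene gene identifier.
#' @export
setMethod("matchedModels", "EnsembleSet", function(x, gene) {
  if (!gene %in% x@genes) stop("unknown gene: ", gene)
  x@matched[[gene]]
})

setMethod("show", "EnsembleSet", function(object) {
  nm <- sum(lengths(object@matched) > 0)
  sz <- lengths(object@matched)
  cat("EnsembleSet (", object@family, "): ", length(object@genes),
      " genes, ", nm, " matched to >= 1 model",
      if (nm) paste0(" (ensemble sizes ", min(sz[sz > 0]), "-", max(sz), ")"),
      "\n", sep = "")
})

#' Ensemble median prediction for one gene
#'
#' The predicted LFC at each time is the median over the matched models'
#' mean simulated LFC under the new condition (even-cardinality medians are
#' the midpoint of the two central values).  The uncertainty band is a
#' percentile bootstrap of the median (83\% by default).  If a control log2
#' expression series \code{b} is supplied, the predicted expression is
#' \code{b + lfcHat}.
#'
#' @param matched character vector of matched model keys (non-empty).
#' @param libLFC models x times matrix from \code{\link{libraryLFC}} for the
#'   prediction condition.
#' @param control optional control-condition log2 expression series
#'   (length T).
#' @param nBoot bootstrap resamples for the band (0 disables the band).
#' @param level band coverage (default 0.83).
#' @param seed seed for the bootstrap.
#' @return list with lfcHat, lower, upper, exprHat (each length T) and
#'   nModels.
#' @export
predictEnsemble <- function(matched, libLFC, control = NULL, nBoot = 1000,
                            level = 0.83, seed = 1L) {
  if (!length(matched))
    stop("empty ensemble: no library model shares this profile; ",
         "consider expanding the model library")
  bad <- setdiff(matched, rownames(libLFC))
  if (length(bad))
    stop("matched model(s) missing from the LFC table: ",
         paste(head(bad, 3), collapse = ", "))
  preds <- libLFC[matched, , drop = FALSE]
  lfcHat <- apply(preds, 2, median)
  lower <- upper <- rep(NA_real_, length(lfcHat))
  if (nBoot > 0 && nrow(preds) > 1) {
    qs <- withSeed(substreamSeed(seed, "band", paste(dim(preds), collapse = "x")), {
      idx <- matrix(sample.int(nrow(preds), nBoot * nrow(preds),
                               replace = TRUE), nrow = nBoot)
      boot <- vapply(seq_len(nBoot), function(b)
        apply(preds[idx[b, ], , drop = FALSE], 2, median),
        numeric(ncol(preds)))
      apply(boot, 1, quantile, probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    })
    lower <- pmin(qs[1, ], lfcHat)
    upper <- pmax(qs[2, ], lfcHat)
  } else if (nBoot > 0) {
    lower <- upper <- lfcHat
  }
  list(lfcHat = lfcHat, lower = lower, upper = upper,
       exprHat = if (!is.null(control)) control + lfcHat else NULL,
       nModels = nrow(preds))
}

#' Ensemble predictions for every matched gene
#'
#' @param ensembles an \linkS4class{EnsembleSet}.
#' @param libLFC models x times matrix for the prediction condition.
#' @param nBoot,level,seed see \code{\link{predictEnsemble}}.
#' @return list with \code{lfcHat} (matched genes x times matrix),
#'   \code{nModels}, and \code{unmatched} (gene ids with empty ensembles).
#' @export
ensemblePredictions <- function(ensembles, libLFC, nBoot = 0, level = 0.83,
                                seed = 1L) {
  ok <- lengths(ensembles@matched) > 0
  genes <- ensembles@genes[ok]
  preds <- lapply(genes, function(g)
    predictEnsemble(ensembles@matched[[g]], libLFC, nBoot = nBoot,
                    level = level, seed = substreamSeed(seed, g)))
  lfcHat <- do.call(rbind, lapply(preds, `[[`, "lfcHat"))
  rownames(lfcHat) <- genes
  list(lfcHat = lfcHat,
       nModels = setNames(vapply(preds, `[[`, numeric(1), "nModels"), genes),
       unmatched = ensembles@genes[!ok])
}

#' Score predictions against validation LFC and a random-model null
#'
#' Per gene: \code{mse} is the mean over time of the squared difference
#' between predicted and true LFC; \code{mseNull} is computed identically
#' for one uniformly drawn library model (seeded, paired per gene -- the
#' null of "pick a random model instead of training");
#' \code{deltaMse = mseNull - mse} (positive when training beats random) and
#' \code{pctMse = 100 * deltaMse / mseNull}.
#'
#' @param lfcHat genes x times matrix of predicted LFC.
#' @param truth genes x times matrix of validation LFC (same genes/order).
#' @param libLFC models x times matrix for the prediction condition (null
#'   models are drawn from its rows).
#' @param nullSeed seed for the random-model draw.
#' @return data.frame: gene, mse, mseNull, deltaMse, pctMse, nullModel.
#' @export
scorePredictions <- function(lfcHat, truth, libLFC, nullSeed = 1L) {
  if (!all(dim(lfcHat) == dim(truth)))
    stop("prediction and truth matrices differ in shape")
  nulls <- withSeed(substreamSeed(nullSeed, "null-models"),
                    sample.int(nrow(libLFC), nrow(lfcHat), replace = TRUE))
  mse <- rowMeans((lfcHat - truth)^2)
  mseNull <- rowMeans((libLFC[nulls, , drop = FALSE] - truth)^2)
  data.frame(gene = rownames(lfcHat),
             mse = unname(mse), mseNull = unname(mseNull),
             deltaMse = unname(mseNull - mse),
             pctMse = unname(100 * (mseNull - mse) / mseNull),
             nullModel = rownames(libLFC)[nulls],
             row.names = NULL)
}

#' Area under the ROC curve
#'
#' Computed with \pkg{pROC} from the rank ordering of scores against binary
#' labels; equals the concordant-pair fraction.
#'
#' @param score numeric ranking statistic (higher = ranked first).
#' @param label logical (TRUE = positive class).
#' @return AUROC in [0, 1], or NA if only one class is present.
#' @export
aurocScore <- function(score, label) {
  label <- as.logical(label)
  if (length(unique(label)) < 2L) return(NA_real_)
  r <- pROC::roc(response = label, predictor = score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(r$auc)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function integral of precision over recall: the mean of precision
#' evaluated at each positive, in decreasing score order.
#'
#' @inheritParams aurocScore
#' @return AUPR in (0, 1], or NA if there are no positives.
#' @export
auprScore <- function(score, label) {
  label <- as.logical(label)
  P <- sum(label)
  if (P == 0L || P == length(label)) {
    if (P == length(label) && P > 0L) return(1)
    return(NA_real_)
  }
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / P
}

#' Elbow index of a descending sorted curve
#'
#' The parameter-free knee rule: the index of the sorted (decreasing) value
#' curve with maximal perpendicular distance from the chord joining its
#' endpoints; used to select the high-confidence top of a ranking.
#'
#' @param values numeric vector, sorted decreasing (sorted internally
#'   otherwise).
#' @return integer index into the sorted curve.
#' @export
elbowIndex <- function(values) {
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  if (n < 3L) return(n)
  x <- seq_len(n)
  dx <- n - 1
  dy <- v[n] - v[1]
  # distance from (x, v) to the line through (1, v[1]) and (n, v[n])
  d <- abs(dy * (x - 1) - dx * (v - v[1])) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' Rank genes and evaluate prediction accuracy globally
#'
#' The ranking statistic is the per-gene mean |LFC| (training condition, and
#' separately the validation condition when available).  Reports: Spearman
#' correlation (with p-value) between the ranking statistic and deltaMse;
#' AUROC / AUPR of the ranking against the labels deltaMse > 0; the elbow
#' cutoff on the sorted ranking statistic; and Wilcoxon signed-rank tests of
#' the paired (mse, mseNull) overall and above the elbow.
#'
#' @param scores data.frame from \code{\link{scorePredictions}}.
#' @param rankStat per-gene ranking statistic, aligned with \code{scores}
#'   (e.g. \code{rowMeans(abs(trainLFC))}).
#' @return list with spearmanRho, spearmanP, auroc, aupr, elbowIndex,
#'   topGenes, wilcoxonP, wilcoxonTopP, medianDeltaMse, medianPctMse.
#' @export
rankAndEvaluate <- function(scores, rankStat) {
  if (nrow(scores) < 3L) stop("at least 3 genes are required")
  if (length(rankStat) != nrow(scores))
    stop("rankStat must align with the score table")
  labels <- scores$deltaMse > 0
  sp <- spearmanTest(rankStat, scores$deltaMse)
  ord <- order(rankStat, decreasing = TRUE)
  elbow <- elbowIndex(rankStat)
  topGenes <- scores$gene[ord[seq_len(elbow)]]
  top <- scores[ord[seq_len(elbow)], , drop = FALSE]
  wAll <- wilcox.test(scores$mse, scores$mseNull, paired = TRUE,
                      alternative = "less", exact = FALSE)
  wTop <- if (nrow(top) >= 3)
    wilcox.test(top$mse, top$mseNull, paired = TRUE,
                alternative = "less", exact = FALSE)$p.value
  else NA_real_
  list(spearmanRho = sp$rho, spearmanP = sp$p,
       auroc = aurocScore(rankStat, labels),
       aupr = auprScore(rankStat, labels),
       elbowIndex = elbow, topGenes = topGenes,
       wilcoxonP = wAll$p.value, wilcoxonTopP = wTop,
       medianDeltaMse = median(scores$deltaMse),
       medianPctMse = median(scores$pctMse))
}

# Spearman rho with t-approximation p; exact permutation for n < 10.
spearmanTest <- function(x, y) {
  n <- length(x)
  if (n < 10L) {
    rx <- rank(x)
    ry <- rank(y)
    obs <- suppressWarnings(stats::cor(rx, ry, method = "spearman"))
    perms <- permutationsAll(n)
    rhos <- as.vector(stats::cor(rx, matrix(ry[t(perms)], nrow = n)))
    p <- mean(abs(rhos) >= abs(obs) - 1e-12)
    list(rho = obs, p = p)
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
}

# all permutations of 1..n as a matrix (n <= 9)
permutationsAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsAll(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- as.matrix(block)
    row <- row + nrow(sub)
  }
  out
}
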