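# Profile matching, ensemble median prediction, MSE scoring and the
# ranking / evaluation statistics.

mkProfiles <- function(m, family = "PW") {
  storage.mode(m) <- "integer"
  new("DiscreteProfileSet", family = family, profiles = m, pCut = 0.05)
}

test_that("matching selects exactly the models with identical profiles", {
  libProf <- mkProfiles(matrix(c(0, 1, 1, 0, 0, 0,
                                 0, 1, 1, 0, 0, 0,
                                 0, 1, 1, 0, 0, 0,
                                 1, 1, 1, 1, 1, 1,
                                 0, 0, 0, 0, 0, 0), 5, byrow = TRUE,
                               dimnames = list(paste0("m", 1:5), NULL)))
  geneProf <- mkProfiles(matrix(c(0, 1, 1, 0, 0, 0,
                                  -1, -1, 0, 0, 0, 0,
                                  0, 0, 0, 0, 0, 0), 3, byrow = TRUE,
                                dimnames = list(c("gA", "gB", "gC"), NULL)))
  es <- matchProfiles(geneProf, libProf)
  expect_setequal(matchedModels(es, "gA"), c("m1", "m2", "m3"))
  expect_identical(matchedModels(es, "gB"), character(0)) # unmatched gene
  expect_identical(matchedModels(es, "gC"), "m5") # all-zero matches all-zero
  expect_error(matchProfiles(geneProf, mkProfiles(matrix(0L, 2, 5))),
               "length mismatch")
})

test_that("ensemble median follows the even/odd median contract", {
  libLFC <- rbind(mA = c(1, 2), mB = c(3, 4), mC = c(100, 0))
  pred <- predictEnsemble(c("mA", "mB", "mC"), libLFC, nBoot = 0)
  expect_equal(unname(pred$lfcHat), c(3, 2)) # per-time medians
  # permuting the ensemble changes nothing
  pred2 <- predictEnsemble(c("mC", "mA", "mB"), libLFC, nBoot = 0)
  expect_equal(pred2$lfcHat, pred$lfcHat)
  # single-model ensemble is that model's LFC
  expect_equal(unname(predictEnsemble("mB", libLFC, nBoot = 0)$lfcHat),
               c(3, 4))
  # even cardinality: midpoint of the two central values
  expect_equal(unname(predictEnsemble(c("mA", "mB"), libLFC, nBoot = 0)$lfcHat),
               c(2, 3))
  expect_error(predictEnsemble(character(0), libLFC), "expanding")
  # expression prediction adds the control baseline
  predB <- predictEnsemble(c("mA", "mB"), libLFC, control = c(8, 8),
                           nBoot = 0)
  expect_equal(unname(predB$exprHat), c(10, 11))
})

test_that("ensemble medians against brute force for sizes 1-9", {
  set.seed(99)
  T <- 6
  lib <- matrix(rnorm(40 * T), 40, T,
                dimnames = list(sprintf("m%02d", 1:40), NULL))
  bruteMedian <- function(v) { # independent of stats::median
    s <- sort(v)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (size in 1:9) {
    for (rep in 1:5) {
      keys <- sample(rownames(lib), size)
      got <- predictEnsemble(keys, lib, nBoot = 0)$lfcHat
      want <- apply(lib[keys, , drop = FALSE], 2, bruteMedian)
      expect_identical(unname(got), unname(want))
    }
  }
})

test_that("the median is robust to corrupting a minority of members", {
  set.seed(5)
  T <- 4
  clean <- matrix(rnorm(9 * T), 9, T,
                  dimnames = list(paste0("m", 1:9), NULL))
  for (rep in 1:20) {
    corrupt <- clean
    bad <- sample(9, 4) # < 50% of members
    corrupt[bad, ] <- rnorm(4 * T, sd = 1e4)
    got <- predictEnsemble(paste0("m", 1:9), corrupt, nBoot = 0)$lfcHat
    lo <- apply(clean[-bad, , drop = FALSE], 2, min)
    hi <- apply(clean[-bad, , drop = FALSE], 2, max)
    expect_true(all(got >= lo & got <= hi))
  }
})

test_that("the bootstrap band contains the point estimate and is seeded", {
  set.seed(1)
  lib <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("m", 1:10), NULL))
  a <- predictEnsemble(paste0("m", 1:10), lib, nBoot = 200, seed = 3)
  b <- predictEnsemble(paste0("m", 1:10), lib, nBoot = 200, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$lower <= a$lfcHat & a$lfcHat <= a$upper))
})

test_that("scoring: exact cases and seeded null draw", {
  lib <- rbind(mA = c(0, 0), mB = c(5, 5))
  truth <- rbind(g1 = c(1, 1), g2 = c(0, 0))
  lfcHat <- rbind(g1 = c(1, 1), g2 = c(0, 0))
  sc <- scorePredictions(lfcHat, truth, lib, nullSeed = 2)
  expect_equal(sc$mse, c(0, 0)) # perfect predictions
  sc2 <- scorePredictions(rbind(g1 = c(0, 0), g2 = c(0, 0)),
                          rbind(g1 = c(1, 1), g2 = c(2, 0)), lib,
                          nullSeed = 2)
  expect_equal(sc2$mse[1], 1)
  expect_equal(sc2$mse[2], 2)
  sc3 <- scorePredictions(lfcHat, truth, lib, nullSeed = 2)
  expect_identical(sc3$nullModel, sc$nullModel) # reproducible null
  expect_error(scorePredictions(lfcHat, truth[, 1, drop = FALSE], lib),
               "shape")
})

test_that("AUROC equals the brute-force concordant-pair count", {
  bruteAuroc <- function(score, label) {
    pos <- score[label]
    neg <- score[!label]
    pairs <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  set.seed(14)
  for (rep in 1:10) {
    score <- rnorm(10)
    label <- runif(10) > 0.5
    if (length(unique(label)) < 2) next
    expect_equal(aurocScore(score, label), bruteAuroc(score, label))
  }
  # perfect ordering
  expect_equal(aurocScore(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE,
                                              FALSE)), 1)
  expect_true(is.na(aurocScore(1:4, rep(TRUE, 4))))
})

test_that("AUROC of labels shuffled independently of rank is about 0.5", {
  set.seed(6)
  score <- rnorm(1000)
  label <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  expect_lt(abs(aurocScore(score, label) - 0.5), 0.05)
})

test_that("AUPR equals the brute-force precision-at-positives average", {
  bruteAupr <- function(score, label) {
    ord <- order(score, decreasing = TRUE)
    lab <- label[ord]
    ap <- 0
    tp <- 0
    for (i in seq_along(lab)) {
      if (lab[i]) {
        tp <- tp + 1
        ap <- ap + tp / i
      }
    }
    ap / sum(label)
  }
  set.seed(15)
  for (rep in 1:10) {
    score <- rnorm(12)
    label <- runif(12) > 0.4
    if (!any(label) || all(label)) next
    expect_equal(auprScore(score, label), bruteAupr(score, label))
  }
})

test_that("the elbow rule finds an obvious knee", {
  v <- c(10, 9.5, 9, 8.5, 1, 0.9, 0.8, 0.7, 0.6)
  expect_true(elbowIndex(v) %in% c(4, 5)) # the cliff edge
  expect_identical(elbowIndex(c(3, 1)), 2L)
})

test_that("rankAndEvaluate assembles the global report coherently", {
  set.seed(23)
  n <- 40
  rankStat <- sort(rexp(n), decreasing = TRUE)
  deltaMse <- rankStat * 0.5 + rnorm(n, sd = 0.3) - 0.2
  scores <- data.frame(gene = paste0("g", 1:n), mse = pmax(1 - deltaMse, 0),
                       mseNull = pmax(1 - deltaMse, 0) + deltaMse,
                       deltaMse = deltaMse,
                       pctMse = 100 * deltaMse / (1 + abs(deltaMse)))
  rep <- rankAndEvaluate(scores, rankStat)
  expect_gt(rep$spearmanRho, 0.3)
  expect_lt(rep$spearmanP, 0.05)
  expect_gt(rep$auroc, 0.5)
  expect_true(rep$elbowIndex >= 1 && rep$elbowIndex <= n)
  expect_identical(length(rep$topGenes), rep$elbowIndex)
  expect_error(rankAndEvaluate(scores[1:2, ], rankStat[1:2]), "3 genes")
  # all labels identical -> AUROC/AUPR reported as absent
  scores2 <- scores
  scores2$deltaMse <- abs(scores2$deltaMse) + 1
  rep2 <- rankAndEvaluate(scores2, rankStat)
  expect_true(is.na(rep2$auroc))
})

test_that("small-sample Spearman p uses the exact permutation distribution", {
  x <- c(1, 2, 3, 4, 5)
  res <- ternadex:::spearmanTest(x, x)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 2 / factorial(5)) # only the two perfect orders
})

test_that("unconnected-y library models predict about zero LFC on average", {
  lib <- e2eLibrary()
  sims <- e2eSims()
  em <- as.matrix(modelStructures(lib)[, ternadex:::EDGE_NAMES])
  unreg <- rowSums(em[, ternadex:::EDGE_TO == "y", drop = FALSE] != 0L) == 0
  lfcKO <- libraryLFC(sims, "KO", ref = "WT")
  expect_lt(abs(mean(lfcKO[unreg, ])), 0.05)
})
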