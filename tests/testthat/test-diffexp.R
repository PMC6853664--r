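# Cell-mean fits, empirical-Bayes moderation, the five contrast families,
# moderated t / F statistics and BH adjustment.

test_that("cell means, residual variance and shrinkage match direct computation", {
  tce <- tinyTce(nGenes = 50, times = c(0, 1, 2), nReps = 3, sigma = 0.3,
                 seed = 9)
  fit <- fitTimecourse(tce, "ctrl", "exp")
  vals <- exprValues(tce)
  cd <- colData(tce)
  # brute-force cell means / pooled variance for a few genes
  for (g in c(1, 25, 50)) {
    for (ci in seq_along(fit@cellCondition)) {
      sel <- cd$condition == fit@cellCondition[ci] & cd$time == fit@cellTime[ci]
      expect_equal(unname(fit@coefficients[g, ci]), mean(vals[g, sel]))
    }
    resid <- unlist(lapply(seq_along(fit@cellCondition), function(ci) {
      sel <- cd$condition == fit@cellCondition[ci] & cd$time == fit@cellTime[ci]
      vals[g, sel] - mean(vals[g, sel])
    }))
    expect_equal(unname(fit@sigma2[g]),
                 sum(resid^2) / (ncol(vals) - length(fit@cellN)))
  }
  # a gene with identical replicate values contributes nothing to s2
  v2 <- vals
  v2[1, ] <- 5
  fit2 <- fitTimecourse(TimecourseExperiment(v2, as.data.frame(cd)),
                        "ctrl", "exp")
  expect_equal(unname(fit2@coefficients[1, ]), rep(5, 6))
  expect_equal(unname(fit2@sigma2[1]), 0)
  # shrinkage property: s2Post between the gene's s2 and the prior
  expect_true(all(fit@s2Post >= pmin(fit@sigma2, fit@s2Prior) - 1e-12))
  expect_true(all(fit@s2Post <= pmax(fit@sigma2, fit@s2Prior) + 1e-12))
})

test_that("variance moderation agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(31)
  df <- 12
  s2 <- rchisq(200, df = df) / df * exp(rnorm(200, sd = 0.6))
  ours <- ternadex:::squeezeVariances(s2, df)
  ref <- limma::squeezeVar(s2, df = df)
  expect_equal(ours$dfPrior, ref$df.prior, tolerance = 1e-6)
  expect_equal(ours$s2Prior, ref$var.prior, tolerance = 1e-6)
  expect_equal(ours$s2Post, ref$var.post, tolerance = 1e-6)
  # degenerate case: identical variances -> no information to shrink with;
  # posterior is constant and equal across genes
  flat <- ternadex:::squeezeVariances(rep(0.25, 40), df)
  expect_equal(flat$s2Post, rep(0.25, 40)) # s2Post == s2 when all s2 equal
  refFlat <- limma::squeezeVar(rep(0.25, 40), df = df)
  expect_equal(flat$s2Post, refFlat$var.post, tolerance = 1e-6)
})

test_that("contrast families produce the LFC vectors their definitions force", {
  # exp means (3,5,5), ctrl means (3,3,3) over t = 0,1,2
  ctrl <- matrix(3, 1, 3)
  expm <- matrix(c(3, 5, 5), 1, 3)
  tce <- exactTce(ctrl, expm, times = c(0, 1, 2), nReps = 2)
  # add a second gene with noise so moderation is defined
  vals <- rbind(exprValues(tce), g2 = rnorm(ncol(tce), 8, 0.1))
  rownames(vals)[1] <- "g1"
  tce <- TimecourseExperiment(vals, as.data.frame(colData(tce)))
  fit <- fitTimecourse(tce, "ctrl", "exp")
  expect_equal(unname(contrastLFC(fit, "PW")["g1", ]), c(0, 2, 2))
  expect_equal(unname(contrastLFC(fit, "TS")["g1", ]), c(2, 0))
  expect_equal(unname(contrastLFC(fit, "AR")["g1", ]), c(2, 2))
  expect_equal(unname(contrastLFC(fit, "PW-TS")["g1", ]), c(2, 0))
  expect_equal(unname(contrastLFC(fit, "PW-AR")["g1", ]), c(2, 2))
  expect_error(contrastLFC(fit, "XX"))
})

test_that("identical conditions zero out every between-condition contrast", {
  set.seed(2)
  base <- matrix(rnorm(12, 8), 3, 4)
  tce <- exactTce(base, base, times = c(0, 5, 10, 20), nReps = 2)
  fit <- fitTimecourse(tce, "ctrl", "exp")
  # PW and the condition-differenced temporal families vanish identically;
  # TS/AR are within-condition contrasts and equal the shared temporal
  # differences of the (common) mean curve
  for (fam in c("PW", "PW-TS", "PW-AR"))
    expect_equal(max(abs(contrastLFC(fit, fam))), 0)
  expect_equal(unname(contrastLFC(fit, "TS")),
               unname(base[, 2:4] - base[, 1:3]))
  expect_equal(unname(contrastLFC(fit, "AR")),
               unname(base[, 2:4] - base[, 1]))
})

test_that("PW LFC equals brute-force mean differences and is antisymmetric", {
  tce <- tinyTce(nGenes = 20, times = c(0, 2, 4), nReps = 3, sigma = 0.5,
                 seed = 77)
  fit <- fitTimecourse(tce, "ctrl", "exp")
  pw <- contrastLFC(fit, "PW")
  vals <- exprValues(tce)
  cd <- colData(tce)
  for (ti in seq_along(fit@times)) {
    brute <- rowMeans(vals[, cd$condition == "exp" & cd$time == fit@times[ti]]) -
      rowMeans(vals[, cd$condition == "ctrl" & cd$time == fit@times[ti]])
    expect_equal(unname(pw[, ti]), unname(brute))
  }
  swapped <- contrastLFC(fitTimecourse(tce, "exp", "ctrl"), "PW")
  expect_equal(unname(swapped), unname(-pw))
})

test_that("moderated tests: zero-LFC gene, single-contrast F = t^2, p bounds", {
  tce <- tinyTce(nGenes = 30, times = c(0, 1), nReps = 3, sigma = 0.3,
                 seed = 12)
  # force gene 1 to exactly equal cell means in both conditions
  vals <- exprValues(tce)
  cd <- as.data.frame(colData(tce))
  for (ti in unique(cd$time)) {
    sel <- cd$time == ti
    vals[1, sel] <- 8
  }
  tce <- TimecourseExperiment(vals, cd)
  fit <- fitTimecourse(tce, "ctrl", "exp")
  pw <- contrastTests(fit, "PW")
  expect_equal(unname(pw@lfc[1, ]), c(0, 0))
  expect_equal(unname(pw@fStat[1]), 0)
  expect_equal(unname(pw@fP[1]), 1)
  # TS family of a 2-time design has a single contrast: F p == squared-t p
  ts <- contrastTests(fit, "TS")
  expect_equal(ncol(ts@lfc), 1L)
  expect_equal(unname(ts@fP), unname(ts@p[, 1]))
  expect_equal(unname(ts@fStat), unname(ts@t[, 1]^2))
  # adjusted p >= raw p always, and within [0, 1]
  expect_true(all(pw@pAdj >= pw@p - 1e-14))
  expect_true(all(pw@pAdj <= 1))
  expect_true(all(pw@fPAdj >= pw@fP - 1e-14))
})

test_that("temporal contrasts of a time-constant gene are exactly zero", {
  ctrl <- matrix(rep(c(7, 9, 6), 3), 3, 3)
  expm <- matrix(rep(c(8, 7.5, 10), 3), 3, 3) # constant in time, != ctrl
  tce <- exactTce(ctrl, expm, times = c(0, 1, 2), nReps = 3)
  fit <- fitTimecourse(tce, "ctrl", "exp")
  expect_equal(max(abs(contrastLFC(fit, "TS"))), 0)
  expect_equal(max(abs(contrastLFC(fit, "AR"))), 0)
})

test_that("null simulation: raw p approximately uniform, F calibrated", {
  tce <- tinyTce(nGenes = 1000, times = c(0, 1, 2), nReps = 3, sigma = 0.25,
                 seed = 2024)
  fit <- fitTimecourse(tce, "ctrl", "exp")
  pw <- contrastTests(fit, "PW")
  ks <- suppressWarnings(stats::ks.test(pw@p[, 2], "punif"))
  expect_gt(ks$p.value, 0.01)
  # type-I error of the unadjusted F at 5%
  expect_lt(mean(pw@fP < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("BH adjustment matches hand computation and is order-preserving", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("fit errors name offending cells and enforce the shared time grid", {
  tce <- tinyTce(nGenes = 5, times = c(0, 1), nReps = 2)
  cd <- as.data.frame(colData(tce))
  cd$time[cd$condition == "exp" & cd$time == 1] <- 2
  tce2 <- TimecourseExperiment(exprValues(tce), cd)
  expect_error(fitTimecourse(tce2, "ctrl", "exp"), "time grid")
  expect_error(fitTimecourse(tce, "ctrl", "ctrl"), "differ")
  expect_error(fitTimecourse(tce, "ctrl", "missing"), "missing")
})
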