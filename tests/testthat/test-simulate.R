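# Euler-Maruyama integration: analytic fixed points, determinism, the
# deterministic-limit ODE oracle, measurement noise and 0-1 normalization.

test_that("an unregulated node relaxes to its analytic steady state", {
  # isolated node: alpha = 1, v = 0, gamma_m = 1 => mRNA steady state 1.0
  m <- handModel(alpha = c(1, 1, 1), v = c(0, 0, 0), gammam = c(1, 1, 1))
  sim <- simulateModel(m, conditionWT(), times = c(0, 20, 50), nReps = 1,
                       seed = 1, sigmaDyn = 0)
  expect_true(all(abs(sim$values["mRNA_y", , 1] - 1) < 1e-3))
  expect_true(all(abs(sim$values["mRNA_x", , 1] - 1) < 1e-3))
})

test_that("simulation is deterministic under a fixed seed", {
  lib <- buildLibrary(seed = 2)
  m <- libraryModels(lib)[["+-+0-0|A.."]]
  tt <- c(0, 15, 40, 90)
  a <- simulateModel(m, conditionKO(), times = tt, nReps = 3, seed = 33)
  b <- simulateModel(m, conditionKO(), times = tt, nReps = 3, seed = 33)
  expect_identical(a$values, b$values)
  c1 <- simulateModel(m, conditionKO(), times = tt, nReps = 3, seed = 34)
  expect_false(identical(a$values, c1$values))
  expect_error(simulateModel(m, conditionKO(), times = c(5, 10), nReps = 1,
                             seed = 1), "start at 0")
})

test_that("knockout drives G mRNA to zero", {
  m <- handModel(alpha = c(0.5, 0.2, 0.2), v = c(1, 0, 0),
                 gammam = c(0.5, 0.5, 0.5))
  sim <- simulateModel(m, conditionKO(), times = c(0, 50, 100), nReps = 1,
                       seed = 1, sigmaDyn = 0)
  expect_lt(sim$values["mRNA_G", "t100", 1], 1e-6)
  # knockin pins production at alpha + v regardless of stimulus
  ki <- simulateModel(m, conditionKI(), times = c(0, 100), nReps = 1,
                      seed = 1, sigmaDyn = 0)
  expect_equal(unname(ki$values["mRNA_G", "t0", 1]),
               (0.5 + 1) / 0.5, tolerance = 1e-3)
})

test_that("zero-noise trajectories match an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  lib <- buildLibrary(seed = 4)
  tt <- c(0, 15, 40, 90, 180, 300)
  nodes <- c("G", "x", "y")
  rhs <- function(t, state, m) { # independent reimplementation of the model
    mm <- state[1:3]
    pp <- state[4:6]
    dm <- dp <- numeric(3)
    for (j in 1:3) {
      regs <- which(m$edges[, j] != 0L)
      contrib <- vapply(regs, function(i) {
        occ <- pp[i]^m$h[i, j] / (m$K[i, j]^m$h[i, j] + pp[i]^m$h[i, j])
        if (m$edges[i, j] > 0) occ else 1 - occ
      }, numeric(1))
      f <- if (length(contrib) == 0) 1
      else if (length(contrib) == 1) contrib
      else if (m$gates[j] == "OR") contrib[1] + contrib[2] -
        contrib[1] * contrib[2]
      else contrib[1] * contrib[2]
      prod <- if (j == 1) m$alpha[j] + 1 * m$v[j] * f # stimulus on
      else m$alpha[j] + m$v[j] * f
      dm[j] <- prod - m$gammam[j] * mm[j]
      dp[j] <- m$k[j] * mm[j] - m$gammap[j] * pp[j]
    }
    list(c(dm, dp))
  }
  # integration step chosen inside the integrator's convergent regime;
  # the pipeline default trades this accuracy for speed, which the
  # ternarized, noise-dominated profiles do not resolve
  for (key in c("++0000|...", "+-+0-0|A..", "-+++00|..A")) {
    m <- libraryModels(lib)[[key]]
    em <- simulateModel(m, conditionWT(), times = tt, nReps = 1, seed = 1,
                        sigmaDyn = 0, dt = 0.01)
    init <- c(em$values[1:3, "t0", 1], em$values[4:6, "t0", 1])
    ode <- deSolve::ode(y = unname(init), times = tt, func = rhs, parms = m)
    for (ti in seq_along(tt)) {
      expect_lt(max(abs(em$values[1:6, ti, 1] - ode[ti, 2:7])), 1e-2)
    }
  }
})

test_that("per-model simulation stays within the performance budget", {
  lib <- buildLibrary(seed = 2)
  m <- libraryModels(lib)[["+-+0-0|A.."]]
  tt <- c(0, 15, 40, 90, 180, 300)
  invisible(simulateModel(m, conditionWT(), times = tt, nReps = 3, seed = 1))
  elapsed <- system.time(for (i in 1:20)
    invisible(simulateModel(m, conditionWT(), times = tt, nReps = 3,
                            seed = i)))["elapsed"]
  expect_lt(elapsed / 20, 0.05) # < 50 ms per model (3 replicates)
})

test_that("measurement noise: identity at zero, half-normal at zero signal", {
  m <- handModel(alpha = c(1, 1, 1), v = c(0, 0, 0))
  sim <- simulateModel(m, conditionWT(), times = c(0, 10), nReps = 2,
                       seed = 2, sigmaDyn = 0)
  expect_identical(addMeasurementNoise(sim, 0, 0, seed = 1)$values,
                   sim$values)
  expect_error(addMeasurementNoise(sim, -0.1, 0.1), "non-negative")
  # zeros + additive noise: the retained positive part is half-normal
  zero <- sim
  zero$values[] <- 0
  draws <- unlist(lapply(1:2000, function(s)
    addMeasurementNoise(zero, sigmaAdd = 0.025, sigmaMult = 0.1,
                        seed = s)$values))
  pos <- draws[draws > 0]
  expect_equal(sd(pos), 0.025 * sqrt(1 - 2 / pi), tolerance = 0.1)
  # reproducible under a fixed seed
  expect_identical(addMeasurementNoise(sim, seed = 7)$values,
                   addMeasurementNoise(sim, seed = 7)$values)
})

test_that("normalize01 scales pooled across conditions and is idempotent", {
  m <- handModel()
  mk <- function(vals, label) {
    sim <- simulateModel(m, conditionWT(), times = c(0, 1, 2), nReps = 1,
                         seed = 1, sigmaDyn = 0)
    sim$values[] <- vals
    sim$condition <- conditionFromLabel(label)
    sim
  }
  a <- mk(2, "WT") # constant 2 everywhere
  b <- mk(6, "KO") # constant 6
  a$values["mRNA_y", , 1] <- c(2, 4, 6)
  b$values["mRNA_y", , 1] <- c(2, 2, 2)
  nn <- normalize01(list(WT = a, KO = b))
  expect_equal(unname(nn$WT$values["mRNA_y", , 1]), c(0, 0.5, 1))
  expect_equal(unname(nn$KO$values["mRNA_y", , 1]), c(0, 0, 0))
  # constant species map to 0
  expect_true(all(nn$WT$values["mRNA_G", , 1] == 0))
  # idempotent
  nn2 <- normalize01(nn)
  expect_equal(nn2$WT$values, nn$WT$values)
  expect_equal(nn2$KO$values, nn$KO$values)
})

test_that("simulated discrete profiles behave as the structure dictates", {
  lib <- e2eLibrary()
  prof <- profileMatrix(e2eLibProfiles()) # KO vs WT training profiles
  em <- as.matrix(modelStructures(lib)[, ternadex:::EDGE_NAMES])
  yIn <- rowSums(em[, ternadex:::EDGE_TO == "y", drop = FALSE] != 0L)
  # y with no incoming edge: no condition effect.  Under BH control across
  # a library rich in true signals the per-entry false-discovery chance is
  # a few percent, so a six-entry profile is entirely zero in most (not
  # quite 95%) of these models and almost never has more than one spurious
  # entry.
  unreg <- yIn == 0
  expect_gt(sum(unreg), 50)
  expect_gte(mean(rowSums(prof[unreg, , drop = FALSE] != 0L) == 0), 0.75)
  expect_gte(mean(rowSums(prof[unreg, , drop = FALSE] != 0L) <= 1), 0.95)
  # direct, sole activation of y by G: knocking G out represses y at
  # post-stimulus times in at least half the models
  act <- em[, "G>y"] == 1L & yIn == 1L
  expect_gt(sum(act), 50)
  lateNeg <- rowSums(prof[act, -1, drop = FALSE] == -1L) > 0
  expect_gte(mean(lateNeg), 0.5)
  # identical model and seed give identical simulations
  keys <- structureKeys(lib)
  keyAct <- keys[which(act)[1]]
  sub <- new("ModelLibrary",
             structures = modelStructures(lib)[match(keyAct, keys), ],
             models = libraryModels(lib)[keyAct], filters = lib@filters,
             seed = lib@seed, ranges = lib@ranges)
  simsA <- simulateLibrary(sub, list(WT = conditionWT(), KO = conditionKO()),
                           times = STUDY_TIMES, nReps = 3, seed = 55)
  simsB <- simulateLibrary(sub, list(WT = conditionWT(), KO = conditionKO()),
                           times = STUDY_TIMES, nReps = 3, seed = 55)
  expect_identical(simsA[[keyAct]], simsB[[keyAct]])
})
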