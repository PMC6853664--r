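# Shared fixtures: small deterministic experiments built in code, and a
# lazily computed cache of the full library simulation used by the
# end-to-end tests (computed once per test run).

STUDY_TIMES <- c(0, 15, 40, 90, 180, 300)

# small two-condition experiment with prescribed cell means and iid noise
tinyTce <- function(nGenes = 20, times = c(0, 1, 2), nReps = 3, sigma = 0.2,
                    seed = 42, meanFun = NULL) {
  set.seed(seed)
  conds <- c("ctrl", "exp")
  cols <- expand.grid(replicate = seq_len(nReps), time = times,
                      condition = conds, stringsAsFactors = FALSE)
  if (is.null(meanFun)) meanFun <- function(g, cond, t) 8
  mu <- matrix(0, nGenes, nrow(cols))
  for (g in seq_len(nGenes))
    mu[g, ] <- mapply(meanFun, g, cols$condition, cols$time)
  vals <- mu + matrix(rnorm(nGenes * nrow(cols), sd = sigma), nGenes)
  dimnames(vals) <- list(sprintf("g%03d", seq_len(nGenes)),
                         paste0(cols$condition, "_t", cols$time, "_r",
                                cols$replicate))
  meta <- data.frame(sample_id = colnames(vals), condition = cols$condition,
                     time = cols$time, replicate = cols$replicate)
  TimecourseExperiment(vals, meta)
}

# experiment with exact cell means and zero noise (for arithmetic checks)
exactTce <- function(ctrlMeans, expMeans, times, nReps = 2) {
  nGenes <- nrow(ctrlMeans)
  conds <- c("ctrl", "exp")
  cols <- expand.grid(replicate = seq_len(nReps), time = times,
                      condition = conds, stringsAsFactors = FALSE)
  vals <- matrix(0, nGenes, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    src <- if (cols$condition[j] == "ctrl") ctrlMeans else expMeans
    vals[, j] <- src[, match(cols$time[j], times)]
  }
  dimnames(vals) <- list(sprintf("g%03d", seq_len(nGenes)),
                         paste0(cols$condition, "_t", cols$time, "_r",
                                cols$replicate))
  meta <- data.frame(sample_id = colnames(vals), condition = cols$condition,
                     time = cols$time, replicate = cols$replicate)
  TimecourseExperiment(vals, meta)
}

# an SDEModel built by hand (bypasses sampling) for simulator unit tests
handModel <- function(edges = NULL, gates = c(G = ".", x = ".", y = "."),
                      alpha = c(1, 1, 1), v = c(0, 0, 0), k = c(1, 1, 1),
                      gammam = c(1, 1, 1), gammap = c(1, 1, 1),
                      h = 2, K = 0.5, sigmaDyn = 0, key = "hand") {
  nodes <- c("G", "x", "y")
  if (is.null(edges))
    edges <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  nm <- function(x) setNames(as.numeric(x), nodes)
  m <- list(key = key, edges = edges, gates = gates, alpha = nm(alpha),
            v = nm(v), k = nm(k), gammam = nm(gammam), gammap = nm(gammap),
            h = matrix(h, 3, 3, dimnames = list(nodes, nodes)),
            K = matrix(K, 3, 3, dimnames = list(nodes, nodes)),
            sigmaDyn = sigmaDyn, condition = conditionWT())
  class(m) <- "SDEModel"
  m
}

# lazily-computed heavy objects shared by the end-to-end tests
.e2eCache <- new.env(parent = emptyenv())

e2eLibrary <- function() {
  if (is.null(.e2eCache$lib)) .e2eCache$lib <- buildLibrary(seed = 7)
  .e2eCache$lib
}

e2eSims <- function() {
  if (is.null(.e2eCache$sims))
    .e2eCache$sims <- simulateLibrary(
      e2eLibrary(),
      list(WT = conditionWT(), KO = conditionKO(), KI = conditionKI()),
      times = STUDY_TIMES, nReps = 3, seed = 11)
  .e2eCache$sims
}

e2eLibProfiles <- function() {
  if (is.null(.e2eCache$prof))
    .e2eCache$prof <- libraryProfiles(e2eSims(), control = "WT",
                                      experimental = "KO")
  .e2eCache$prof
}
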