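# Fully synthetic experiments with known ground truth: expression matrices
# shaped like the replicated multi-condition study design, containing
# library-model-derived genes, null genes, and pattern-targeted genes.

#' Generate a synthetic timecourse experiment from library models
#'
#' Model genes are the y-mRNA trajectories of randomly chosen library
#' models, simulated independently per gene under every design condition,
#' given measurement noise, min-max normalized pooled across conditions, and
#' mapped to a log2 scale via \code{baseline + range * value}.  Null genes
#' are a constant baseline plus i.i.d. Gaussian noise, identical in
#' distribution across conditions.  Ground-truth labels (generating model
#' key or \code{"null"}) are returned in a sidecar table, never inside the
#' expression matrix.  Regeneration with the same seed reproduces the
#' experiment exactly.
#'
#' @param library a \linkS4class{ModelLibrary}.
#' @param nModelGenes number of genes generated from library models.
#' @param nNullGenes number of null (no-signal) genes.
#' @param conditions named list of conditions to simulate, e.g.
#'   \code{list(WT = conditionWT(), KO = conditionKO(), KI = conditionKI())}.
#' @param times sampling grid (minutes).
#' @param nReps replicates per condition.
#' @param seed integer master seed.
#' @param sigmaAdd,sigmaMult measurement noise on the simulated values.
#' @param nullSd SD of the null genes' log2 noise.
#' @param baseline,range affine map from normalized [0, 1] values to log2
#'   expression (defaults 8 and 4: typical log2 magnitudes, LFCs within
#'   +/- 4).
#' @param modelKeys optional explicit generating model keys (overrides the
#'   random draw; recycled errors if longer than the library).
#' @param dt,burnin integrator settings.
#' @return list with \code{experiment} (a
#'   \linkS4class{TimecourseExperiment}), \code{truth} (data.frame gene,
#'   label) and \code{seed}.
#' @export
makeSyntheticExperiment <- function(library, nModelGenes, nNullGenes = 0,
                                    conditions = list(WT = conditionWT(),
                                                      KO = conditionKO(),
                                                      KI = conditionKI()),
                                    times = c(0, 15, 40, 90, 180, 300),
                                    nReps = 3, seed = 1L,
                                    sigmaAdd = 0.025, sigmaMult = 0.1,
                                    nullSd = 0.25, baseline = 8, range = 4,
                                    modelKeys = NULL, dt = 0.5,
                                    burnin = 200) {
  if (length(conditions) < 2L) stop("the design needs >= 2 conditions")
  keys <- structureKeys(library)
  if (is.null(modelKeys)) {
    if (nModelGenes > length(keys))
      stop("nModelGenes exceeds the library size (sampling is without ",
           "replacement)")
    modelKeys <- withSeed(substreamSeed(seed, "pick-models"),
                          sample(keys, nModelGenes))
  } else {
    stopifnot(all(modelKeys %in% keys), length(modelKeys) == nModelGenes)
  }
  models <- libraryModels(library)
  nGenes <- nModelGenes + nNullGenes
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  condNames <- names(conditions)
  cols <- expand.grid(replicate = seq_len(nReps), time = times,
                      condition = condNames, stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nGenes, nrow(cols),
                 dimnames = list(geneIds,
                                 paste0(cols$condition, "_t", cols$time,
                                        "_r", cols$replicate)))
  for (i in seq_len(nModelGenes)) {
    m <- models[[modelKeys[i]]]
    gseed <- substreamSeed(seed, "synthgene", i)
    runs <- lapply(conditions, function(cc)
      addMeasurementNoise(
        simulateModel(m, condition = cc, times = times, nReps = nReps,
                      seed = gseed, dt = dt, burnin = burnin),
        sigmaAdd = sigmaAdd, sigmaMult = sigmaMult, seed = gseed))
    runs <- normalize01(runs)
    for (j in seq_len(nrow(cols))) {
      y <- ymRNA(runs[[cols$condition[j]]])
      vals[i, j] <- baseline + range *
        y[match(cols$time[j], times), cols$replicate[j]]
    }
  }
  if (nNullGenes > 0) {
    nullVals <- withSeed(substreamSeed(seed, "null-genes"),
                         matrix(baseline + rnorm(nNullGenes * nrow(cols),
                                                 sd = nullSd),
                                nNullGenes, nrow(cols)))
    vals[nModelGenes + seq_len(nNullGenes), ] <- nullVals
  }
  meta <- data.frame(sample_id = colnames(vals), condition = cols$condition,
                     time = cols$time, replicate = cols$replicate)
  truth <- data.frame(gene = geneIds,
                      label = c(modelKeys, rep("null", nNullGenes)),
                      row.names = NULL)
  list(experiment = TimecourseExperiment(vals, meta), truth = truth,
       seed = seed)
}

#' Generate genes with a prescribed discrete PW pattern
#'
#' Builds a two-condition block whose expected PW log fold change at each
#' time equals \code{effect * pattern[t]}, so the profile discretizes to the
#' requested ternary pattern with high probability at the default threshold.
#' When \code{effect} is not given it is auto-scaled to the noise level
#' (\code{max(1, 10 * sigma * sqrt(2 / nReps))}), giving per-entry recovery
#' probability of at least ~0.9.
#'
#' @param pattern ternary vector of length T (entries -1, 0, +1).
#' @param n number of genes to generate (0 gives an empty block).
#' @param sigma per-observation Gaussian noise SD (log2 units).
#' @param seed integer master seed.
#' @param times time grid (length must equal \code{length(pattern)}).
#' @param nReps replicates per cell.
#' @param baseline control-condition log2 expression level.
#' @param control,experimental condition labels of the block.
#' @param effect LFC magnitude of the non-zero pattern entries.
#' @return list with \code{experiment} (NULL when \code{n = 0}) and
#'   \code{truth} (data.frame gene, label = \code{"pattern:<key>"}).
#' @export
makePatternGenes <- function(pattern, n, sigma = 0.25, seed = 1L,
                             times = c(0, 15, 40, 90, 180, 300), nReps = 3,
                             baseline = 8, control = "ctrl",
                             experimental = "exp", effect = NULL) {
  stopifnot(all(pattern %in% c(-1, 0, 1)))
  if (length(pattern) != length(times))
    stop("pattern length must equal the number of time points")
  label <- paste0("pattern:", profileKey(pattern))
  if (n == 0L)
    return(list(experiment = NULL,
                truth = data.frame(gene = character(0), label = character(0))))
  if (is.null(effect)) effect <- max(1, 10 * sigma * sqrt(2 / nReps))
  condNames <- c(control, experimental)
  cols <- expand.grid(replicate = seq_len(nReps), time = times,
                      condition = condNames, stringsAsFactors = FALSE)
  mu <- ifelse(cols$condition == experimental,
               baseline + effect * pattern[match(cols$time, times)],
               baseline)
  geneIds <- sprintf("pgene%04d", seq_len(n))
  vals <- withSeed(substreamSeed(seed, "pattern", label),
                   matrix(rep(mu, each = n) + rnorm(n * nrow(cols), sd = sigma),
                          n, nrow(cols)))
  dimnames(vals) <- list(geneIds, paste0(cols$condition, "_t", cols$time,
                                         "_r", cols$replicate))
  meta <- data.frame(sample_id = colnames(vals), condition = cols$condition,
                     time = cols$time, replicate = cols$replicate)
  list(experiment = TimecourseExperiment(vals, meta),
       truth = data.frame(gene = geneIds, label = label, row.names = NULL))
}
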