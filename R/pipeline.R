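# High-level wrappers chaining the pipeline stages; used by the command-line
# entry point and convenient for interactive analyses.

#' Discrete-response analysis of a timecourse experiment
#'
#' Fits the two-condition cell-mean model, computes moderated contrasts for
#' the requested families, discretizes them, and classifies genes as
#' DEG / dDEG / DRG.
#'
#' @param tce a \linkS4class{TimecourseExperiment}.
#' @param control,experimental condition labels.
#' @param pCut significance threshold for discretization and the F test.
#' @param lfcMin optional minimum |LFC| for a non-zero discrete call.
#' @param families contrast families to compute (default: all five).
#' @return list with \code{fit}, \code{results} (ContrastResult per family),
#'   \code{profiles} (DiscreteProfileSet per family) and
#'   \code{classification} (data.frame; requires the PW, PW-TS and PW-AR
#'   families, otherwise NULL).
#' @export
discreteResponseAnalysis <- function(tce, control, experimental, pCut = 0.05,
                                     lfcMin = 0,
                                     families = CONTRAST_FAMILIES) {
  fit <- fitTimecourse(tce, control = control, experimental = experimental)
  results <- lapply(families, function(fam) contrastTests(fit, fam))
  names(results) <- families
  profiles <- lapply(results, discretizeContrasts, pCut = pCut,
                     lfcMin = lfcMin)
  classification <- NULL
  if (all(c("PW", "PW-TS", "PW-AR") %in% families))
    classification <- classifyGenes(results[["PW"]], profiles[["PW"]],
                                    profiles[["PW-TS"]], profiles[["PW-AR"]],
                                    pCut = pCut)
  list(fit = fit, results = results, profiles = profiles,
       classification = classification)
}

#' Train ensembles on one perturbation and score predictions on another
#'
#' Simulates the model library under the training pair and the validation
#' condition, matches each gene's discrete PW profile to the library,
#' predicts the validation LFC as the ensemble median, and scores it
#' against the observed validation LFC and a paired random-model null.
#'
#' @param tce experiment holding control, training and validation conditions.
#' @param library a \linkS4class{ModelLibrary}.
#' @param control,experimental training condition labels (condition kinds
#'   must be resolvable from the labels: WT / KO / KI / INHIB<strength>).
#' @param validation validation condition label.
#' @param pCut discretization threshold.
#' @param nReps stochastic replicates per library simulation.
#' @param seed master seed for library simulation and the null draw.
#' @param genes optional gene subset to match (e.g. the dDEGs); default all.
#' @param sims optional precomputed \code{LibrarySimulations} covering the
#'   three conditions (skips the expensive simulation step).
#' @param sigmaAdd,sigmaMult measurement noise for library simulations.
#' @return list with \code{ensembles}, \code{predictions}, \code{scores},
#'   \code{rankStat} (mean |training LFC| of the scored genes),
#'   \code{summary} (from \code{\link{rankAndEvaluate}}) and \code{sims}.
#' @export
trainPredictScore <- function(tce, library, control = "WT",
                              experimental = "KO", validation = "KI",
                              pCut = 0.05, nReps = 3, seed = 1L,
                              genes = NULL, sims = NULL,
                              sigmaAdd = 0.025, sigmaMult = 0.1) {
  times <- timePoints(tce)
  if (is.null(sims)) {
    conds <- setNames(lapply(c(control, experimental, validation),
                             conditionFromLabel),
                      c(control, experimental, validation))
    sims <- simulateLibrary(library, conds, times = times, nReps = nReps,
                            seed = seed, sigmaAdd = sigmaAdd,
                            sigmaMult = sigmaMult)
  }
  libProf <- libraryProfiles(sims, control = control,
                             experimental = experimental, pCut = pCut)
  fitTrain <- fitTimecourse(tce, control, experimental)
  geneProf <- discretizeContrasts(contrastTests(fitTrain, "PW"), pCut = pCut)
  if (!is.null(genes)) {
    keep <- rownames(profileMatrix(geneProf)) %in% genes
    geneProf <- new("DiscreteProfileSet", family = "PW",
                    profiles = profileMatrix(geneProf)[keep, , drop = FALSE],
                    pCut = pCut)
  }
  ensembles <- matchProfiles(geneProf, libProf)
  predLFC <- libraryLFC(sims, validation, ref = control)
  predictions <- ensemblePredictions(ensembles, predLFC, nBoot = 0,
                                     seed = seed)
  fitVal <- fitTimecourse(tce, control, validation)
  truth <- contrastLFC(fitVal, "PW")
  scored <- rownames(predictions$lfcHat)
  scores <- scorePredictions(predictions$lfcHat,
                             truth[scored, , drop = FALSE], predLFC,
                             nullSeed = seed)
  trainLFC <- contrastLFC(fitTrain, "PW")
  rankStat <- rowMeans(abs(trainLFC[scored, , drop = FALSE]))
  summary <- if (nrow(scores) >= 3) rankAndEvaluate(scores, rankStat)
             else NULL
  list(ensembles = ensembles, predictions = predictions, scores = scores,
       rankStat = rankStat, summary = summary, sims = sims)
}
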