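# Stochastic simulation of SDE models, measurement noise, 0-1 normalization,
# and the pipeline that turns library simulations into discrete profiles
# shaped exactly like the experimental analysis.

SPECIES <- c("mRNA_G", "mRNA_x", "mRNA_y",
             "protein_G", "protein_x", "protein_y")

#' Simulate an SDE model under a condition
#'
#' Euler-Maruyama integration (fixed internal step \code{dt}) of the
#' mRNA/protein system with chemical-Langevin multiplicative noise
#' (\code{sigmaDyn * sqrt(production + degradation) * dW} per species).  A
#' pre-stimulus burn-in of \code{burnin} minutes brings each replicate to a
#' stochastic steady state; the stimulus (a step multiplier on G's regulated
#' transcription, representing the growth-factor input) switches on at
#' t = 0, and the state is sampled on the experimental time grid.  Values
#' are clamped at 0.  Replicate r draws from an independent substream
#' derived from (seed, model key, condition, r), so identical calls give
#' identical trajectories.
#'
#' @param model an SDEModel (see \code{\link{sampleParameters}}).
#' @param condition optional condition overriding the model's tag.
#' @param times sampling times in minutes, ascending, starting at 0.
#' @param nReps number of independent stochastic replicates.
#' @param seed integer master seed.
#' @param dt internal integration step (minutes).
#' @param burnin pre-stimulus burn-in (minutes).
#' @param sigmaDyn noise amplitude; defaults to the model's own value.
#' @return a \code{SimulationResult}: list with the model key, condition,
#'   times and a 6 x T x nReps value array (species x time x replicate).
#' @export
simulateModel <- function(model, condition = NULL, times, nReps = 3,
                          seed = 1L, dt = 0.5, burnin = 200,
                          sigmaDyn = NULL) {
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly ascending and start at 0")
  if (nReps < 1) stop("nReps must be >= 1")
  cond <- if (is.null(condition)) model$condition else condition
  if (!cond$kind %in% c("WT", "KO", "KI", "INHIB"))
    stop("unknown condition kind: ", cond$kind)
  condKind <- match(cond$kind, c("WT", "KO", "KI", "INHIB")) - 1L
  seeds <- vapply(seq_len(nReps), function(r)
    substreamSeed(seed, model$key, conditionLabel(cond), r), integer(1))
  gatesI <- ifelse(model$gates == "OR", 1L, 0L)
  vals <- em_simulate_cpp(model$edges, model$h, model$K, gatesI,
                          model$alpha, model$v, model$gammam, model$k,
                          model$gammap, condKind, cond$strength,
                          as.numeric(times), dt, burnin,
                          if (is.null(sigmaDyn)) model$sigmaDyn else sigmaDyn,
                          as.integer(nReps), seeds, model$key)
  dimnames(vals) <- list(SPECIES, paste0("t", times), NULL)
  res <- list(key = model$key, condition = cond, times = as.numeric(times),
              values = vals)
  class(res) <- "SimulationResult"
  res
}

#' Add measurement noise to a simulation result
#'
#' Each observed value becomes
#' \code{value * exp(N(0, sigmaMult)) + N(0, sigmaAdd)}, i.e. a
#' multiplicative log-normal factor plus additive Gaussian noise, mimicking
#' microarray-like measurement error; negative results are clamped to 0.
#'
#' @param result a SimulationResult.
#' @param sigmaAdd additive noise SD (default 0.025).
#' @param sigmaMult multiplicative (log-scale) noise SD (default 0.1).
#' @param seed integer master seed (noise substream derived from it and the
#'   model key / condition).
#' @return the SimulationResult with noised values.
#' @export
addMeasurementNoise <- function(result, sigmaAdd = 0.025, sigmaMult = 0.1,
                                seed = 1L) {
  if (sigmaAdd < 0 || sigmaMult < 0) stop("noise SDs must be non-negative")
  if (sigmaAdd == 0 && sigmaMult == 0) return(result)
  v <- result$values
  n <- length(v)
  noised <- withSeed(
    substreamSeed(seed, result$key, conditionLabel(result$condition), "noise"),
    v * exp(rnorm(n, 0, sigmaMult)) + rnorm(n, 0, sigmaAdd))
  noised[noised < 0] <- 0
  result$values <- array(noised, dim = dim(v), dimnames = dimnames(v))
  result
}

#' Min-max normalize simulations of one model to [0, 1]
#'
#' Scaling is per species, pooled over all conditions, replicates and times
#' of the model (so cross-condition differences survive normalization);
#' constant series map to 0.  Idempotent.
#'
#' @param results list of SimulationResults of one model (one per condition).
#' @return the list with values scaled into [0, 1].
#' @export
normalize01 <- function(results) {
  if (!length(results)) stop("at least one simulation result is required")
  keys <- unique(vapply(results, `[[`, "", "key"))
  if (length(keys) > 1L)
    stop("normalize01 pools simulations of a single model; got keys: ",
         paste(keys, collapse = ", "))
  for (s in seq_along(SPECIES)) {
    pooled <- unlist(lapply(results, function(r) r$values[s, , ]))
    lo <- min(pooled)
    hi <- max(pooled)
    for (i in seq_along(results)) {
      if (hi > lo) {
        results[[i]]$values[s, , ] <-
          (results[[i]]$values[s, , ] - lo) / (hi - lo)
      } else {
        results[[i]]$values[s, , ] <- 0
      }
    }
  }
  results
}

#' Extract the y-node mRNA series
#'
#' The y mRNA is the species compared to measured gene expression (RNA-seq
#' measures mRNA); proteins are latent.
#'
#' @param result a SimulationResult.
#' @return T x nReps matrix.
#' @export
ymRNA <- function(result) {
  m <- result$values["mRNA_y", , , drop = TRUE]
  matrix(m, nrow = length(result$times),
         dimnames = list(paste0("t", result$times), NULL))
}

#' Simulate a whole model library under several conditions
#'
#' For every model: simulate under each condition, add measurement noise,
#' min-max normalize pooled across the conditions, and keep the normalized
#' y-mRNA series.  This produces simulated replicate data shaped exactly
#' like the experimental input.
#'
#' @param library a \linkS4class{ModelLibrary}.
#' @param conditions named list of conditions (names become condition
#'   labels), e.g. \code{list(WT = conditionWT(), KO = conditionKO())}.
#' @param times sampling grid (minutes).
#' @param nReps stochastic replicates per condition (default 3).
#' @param seed integer master seed.
#' @param sigmaAdd,sigmaMult measurement noise parameters.
#' @param dt,burnin integrator settings.
#' @return a \code{LibrarySimulations} object: per model, the named list of
#'   T x nReps normalized y-mRNA matrices.
#' @export
simulateLibrary <- function(library, conditions, times, nReps = 3, seed = 1L,
                            sigmaAdd = 0.025, sigmaMult = 0.1, dt = 0.5,
                            burnin = 200) {
  if (is.null(names(conditions)))
    names(conditions) <- vapply(conditions, conditionLabel, "")
  models <- libraryModels(library)
  sims <- lapply(models, function(m) {
    runs <- lapply(conditions, function(cc)
      addMeasurementNoise(
        simulateModel(m, condition = cc, times = times, nReps = nReps,
                      seed = seed, dt = dt, burnin = burnin),
        sigmaAdd = sigmaAdd, sigmaMult = sigmaMult, seed = seed))
    runs <- normalize01(runs)
    lapply(runs, ymRNA)
  })
  structure(sims, class = "LibrarySimulations", times = times,
            conditions = names(conditions), nReps = nReps, seed = seed)
}

#' Assemble library simulations into a TimecourseExperiment
#'
#' Models become rows (keyed by structure key), samples are
#' (condition, time, replicate) columns, exactly mirroring the layout of the
#' experimental expression matrix.
#'
#' @param sims a \code{LibrarySimulations} object.
#' @param conditions condition labels to include (default: all simulated).
#' @return a \linkS4class{TimecourseExperiment}.
#' @export
libraryExpression <- function(sims, conditions = attr(sims, "conditions")) {
  times <- attr(sims, "times")
  nReps <- attr(sims, "nReps")
  cols <- expand.grid(replicate = seq_len(nReps), time = times,
                      condition = conditions, stringsAsFactors = FALSE)
  vals <- vapply(seq_len(nrow(cols)), function(j) {
    ti <- match(cols$time[j], times)
    vapply(sims, function(s) s[[cols$condition[j]]][ti, cols$replicate[j]],
           numeric(1))
  }, numeric(length(sims)))
  if (length(sims) == 1L) vals <- matrix(vals, nrow = 1L)
  rownames(vals) <- names(sims)
  colnames(vals) <- paste0(cols$condition, "_t", cols$time, "_r",
                           cols$replicate)
  meta <- data.frame(sample_id = colnames(vals), condition = cols$condition,
                     time = cols$time, replicate = cols$replicate)
  TimecourseExperiment(vals, meta)
}

#' Discrete profiles of library models
#'
#' Feeds the simulated replicate series of every model through the same
#' fit / contrast / discretization pipeline as the experimental data
#' (identical settings, same \code{pCut}), returning the models' discrete
#' profiles for the requested families.
#'
#' @param sims a \code{LibrarySimulations} object.
#' @param control,experimental condition labels of the training pair.
#' @param pCut discretization threshold (same as the experimental analysis).
#' @param families contrast families to return (default PW, the matching
#'   family).
#' @return a single \linkS4class{DiscreteProfileSet} if one family is
#'   requested, otherwise a named list of them.
#' @export
libraryProfiles <- function(sims, control, experimental, pCut = 0.05,
                            families = "PW") {
  tce <- libraryExpression(sims, conditions = c(control, experimental))
  fit <- fitTimecourse(tce, control = control, experimental = experimental)
  out <- lapply(families, function(fam)
    discretizeContrasts(contrastTests(fit, fam), pCut = pCut))
  names(out) <- families
  if (length(out) == 1L) out[[1]] else out
}

#' Mean simulated LFC of every library model
#'
#' Per model and time point, the difference between the replicate-mean
#' normalized y-mRNA under \code{condition} and under \code{ref} (the
#' model's average LFC over its stochastic runs) -- the quantity used for
#' ensemble predictions.
#'
#' @param sims a \code{LibrarySimulations} object.
#' @param condition condition label of the perturbation.
#' @param ref reference condition label (default \code{"WT"}).
#' @return models x times matrix.
#' @export
libraryLFC <- function(sims, condition, ref = "WT") {
  out <- t(vapply(sims, function(s)
    rowMeans(s[[condition]]) - rowMeans(s[[ref]]),
    numeric(length(attr(sims, "times")))))
  rownames(out) <- names(sims)
  out
}

#' @export
print.SimulationResult <- function(x, ...) {
  cat("SimulationResult for model", x$key, "under",
      conditionLabel(x$condition), ":", dim(x$values)[3], "replicate(s) at",
      length(x$times), "time points\n")
  invisible(x)
}

#' @export
print.LibrarySimulations <- function(x, ...) {
  cat("LibrarySimulations:", length(x), "models x",
      length(attr(x, "conditions")), "conditions (",
      paste(attr(x, "conditions"), collapse = ", "), "),",
      attr(x, "nReps"), "replicates\n")
  invisible(x)
}
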