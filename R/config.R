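# YAML configuration: named sections with defaults, used by the command-line
# entry point and convenient for scripted analyses.

#' Default analysis configuration
#'
#' Sections mirror the pipeline stages: \code{design} (condition labels,
#' time grid, replicates), \code{contrasts} (families), \code{discretize}
#' (pCut, lfcMin), \code{library} (gates, filters, seed), \code{simulate}
#' (integrator step, burn-in, replicate count, noise), \code{predict}
#' (condition, bootstrap), \code{enrich} (permutations) and \code{synth}
#' (synthetic-experiment sizes).
#'
#' @return nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    design = list(control = "WT", experimental = "KO", validation = "KI",
                  times = c(0, 15, 40, 90, 180, 300), replicates = 3),
    contrasts = list(families = CONTRAST_FAMILIES),
    discretize = list(pCut = 0.05, lfcMin = 0),
    library = list(gates = TRUE, filters = "dropIsolatedNodes", seed = 1,
                   sigmaDyn = 0.05),
    simulate = list(dt = 0.5, burnin = 200, nReps = 3,
                    sigmaAdd = 0.025, sigmaMult = 0.1),
    predict = list(condition = "KI", nBoot = 1000, level = 0.83),
    enrich = list(nPerm = 10000),
    synth = list(nModelGenes = 20, nNullGenes = 100, nullSd = 0.25,
                 baseline = 8, range = 4)
  )
}

#' Read a YAML configuration file
#'
#' Values from the file override the defaults section by section; missing
#' sections or keys fall back to \code{\link{defaultConfig}}.
#'
#' @param path YAML file path (NULL gives the defaults).
#' @return nested named list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  mergeLists(cfg, user)
}

mergeLists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeLists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Resolve a condition label to a condition descriptor
#'
#' \code{"WT"}, \code{"KO"}, \code{"KI"} map to their constructors;
#' \code{"INHIB<strength>"} (e.g. \code{"INHIB0.1"}) to
#' \code{conditionInhib(strength)}.
#'
#' @param label condition label.
#' @return a condition list (kind, strength).
#' @export
conditionFromLabel <- function(label) {
  if (label %in% c("WT", "KO", "KI")) {
    switch(label, WT = conditionWT(), KO = conditionKO(), KI = conditionKI())
  } else if (grepl("^INHIB", label)) {
    s <- as.numeric(sub("^INHIB", "", label))
    conditionInhib(if (is.na(s)) 0.1 else s)
  } else stop("unknown condition label: ", label)
}
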