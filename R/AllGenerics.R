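# Generics for accessors shared across the package's S4 classes.

#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @export
setGeneric("sampleReplicates", function(x) standardGeneric("sampleReplicates"))
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setGeneric("lfcValues", function(x) standardGeneric("lfcValues"))
#' @export
setGeneric("adjustedP", function(x) standardGeneric("adjustedP"))
#' @export
setGeneric("overallFP", function(x, adjusted = TRUE) standardGeneric("overallFP"))
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @export
setGeneric("contrastFamily", function(x) standardGeneric("contrastFamily"))
#' @export
setGeneric("modelStructures", function(x) standardGeneric("modelStructures"))
#' @export
setGeneric("libraryModels", function(x) standardGeneric("libraryModels"))
#' @export
setGeneric("structureKeys", function(x) standardGeneric("structureKeys"))
#' @export
setGeneric("matchedModels", function(x, gene) standardGeneric("matchedModels"))
#' @export
setGeneric("termDepth", function(x, terms = NULL) standardGeneric("termDepth"))
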