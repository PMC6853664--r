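# Construction, accessors and TSV input/output for TimecourseExperiment.

#' Construct a TimecourseExperiment
#'
#' @param values numeric matrix of log2 expression, genes x samples, with
#'   unique row (gene) and column (sample) names.
#' @param sampleData data.frame with one row per sample and columns
#'   \code{sample_id}, \code{condition}, \code{time}, \code{replicate}
#'   (alternatively rownames instead of \code{sample_id}).
#'
#' Samples are canonically reordered by (condition, time, replicate) so
#' column order is deterministic for fixed metadata.
#'
#' @return a \linkS4class{TimecourseExperiment}.
#' @export
TimecourseExperiment <- function(values, sampleData) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData)) {
    rownames(sampleData) <- as.character(sampleData$sample_id)
  }
  if (is.null(colnames(values))) stop("expression matrix needs sample names")
  inMatrixOnly <- setdiff(colnames(values), rownames(sampleData))
  if (length(inMatrixOnly))
    stop("sample(s) present in the matrix but absent from metadata: ",
         paste(inMatrixOnly, collapse = ", "))
  inMetaOnly <- setdiff(rownames(sampleData), colnames(values))
  if (length(inMetaOnly))
    stop("sample(s) present in metadata but absent from the matrix: ",
         paste(inMetaOnly, collapse = ", "))
  sampleData <- sampleData[colnames(values), , drop = FALSE]
  ord <- order(sampleData$condition, sampleData$time, sampleData$replicate)
  values <- values[, ord, drop = FALSE]
  sampleData <- sampleData[ord, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(log2expr = values),
    colData = DataFrame(condition = as.character(sampleData$condition),
                        time = as.numeric(sampleData$time),
                        replicate = as.integer(sampleData$replicate),
                        row.names = rownames(sampleData)))
  new("TimecourseExperiment", se)
}

#' Read a timecourse experiment from TSV files
#'
#' @param matrixPath TSV: header row of sample ids, first column gene ids,
#'   numeric log2 expression values.
#' @param metaPath TSV with columns sample_id, condition, time, replicate.
#' @return a \linkS4class{TimecourseExperiment} with samples canonically
#'   ordered by (condition, time, replicate).
#' @export
readTimecourse <- function(matrixPath, metaPath) {
  mat <- read.delim(matrixPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(mat[[1]]))
    stop("duplicate gene identifier(s): ",
         paste(unique(mat[[1]][duplicated(mat[[1]])]), collapse = ", "))
  genes <- as.character(mat[[1]])
  vals <- mat[, -1, drop = FALSE]
  nonNum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonNum))
    stop("non-numeric expression column(s): ",
         paste(colnames(vals)[nonNum], collapse = ", "))
  vals <- as.matrix(vals)
  rownames(vals) <- genes
  meta <- read.delim(metaPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "time", "replicate")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  TimecourseExperiment(vals, meta)
}

#' Write a timecourse experiment to TSV files
#'
#' Values round-trip bit-identically through \code{readTimecourse} (full
#' double precision is retained).
#'
#' @param tce a TimecourseExperiment.
#' @param matrixPath,metaPath output file paths.
#' @return invisibly, the paths.
#' @export
writeTimecourse <- function(tce, matrixPath, metaPath) {
  a <- assay(tce)
  df <- data.frame(gene = rownames(a), check.names = FALSE)
  av <- as.data.frame(matrix(sprintf("%.17g", a), nrow = nrow(a),
                             dimnames = dimnames(a)),
                      check.names = FALSE, optional = TRUE)
  df <- cbind(df, av)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- colData(tce)
  meta <- data.frame(sample_id = rownames(cd), condition = cd$condition,
                     time = cd$time, replicate = cd$replicate)
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, metaPath))
}

#' @describeIn TimecourseExperiment condition label per sample
#' @export
setMethod("sampleConditions", "TimecourseExperiment",
          function(x) colData(x)$condition)

#' @describeIn TimecourseExperiment time (minutes) per sample
#' @export
setMethod("sampleTimes", "TimecourseExperiment", function(x) colData(x)$time)

#' @describeIn TimecourseExperiment replicate index per sample
#' @export
setMethod("sampleReplicates", "TimecourseExperiment",
          function(x) colData(x)$replicate)

#' @describeIn TimecourseExperiment sorted unique time grid
#' @export
setMethod("timePoints", "TimecourseExperiment",
          function(x) sort(unique(colData(x)$time)))

#' @describeIn TimecourseExperiment unique condition labels
#' @export
setMethod("conditionNames", "TimecourseExperiment",
          function(x) unique(colData(x)$condition))

#' @describeIn TimecourseExperiment the log2 expression matrix
#' @export
setMethod("exprValues", "TimecourseExperiment", function(x) assay(x))

setMethod("show", "TimecourseExperiment", function(object) {
  callNextMethod()
  cat("conditions:", paste(conditionNames(object), collapse = ", "), "\n")
  cat("time grid (min):", paste(timePoints(object), collapse = ", "), "\n")
})
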