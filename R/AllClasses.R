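#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats cor cov ks.test prcomp wilcox.test hclust cutree dist
#'   quantile rnorm rpois runif setNames sd var
#' @importFrom utils read.delim write.table head packageVersion
NULL

VALUE_KINDS <- c("abundance", "log2ratio")

#' Expression matrix with platform and value-kind metadata
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one
#' entities-by-samples expression matrix (miRNAs or array probes) in an
#' assay named \code{"exprs"}, together with the originating platform name
#' and the kind of values stored: \code{"abundance"} (higher = more
#' expressed, e.g. normalised log2 intensities or PCR-derived expression
#' estimates) or \code{"log2ratio"} (signed log2 ratios).
#' Missing measurements are \code{NA}; they are never zero-filled.
#'
#' @slot platform single platform name.
#' @slot valueKind \code{"abundance"} or \code{"log2ratio"}.
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()]
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(platform = "character", valueKind = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || is.na(object@platform))
    msg <- c(msg, "'platform' must be a single string")
  if (length(object@valueKind) != 1L || !object@valueKind %in% VALUE_KINDS)
    msg <- c(msg, sprintf("'valueKind' must be one of %s",
                          paste(sQuote(VALUE_KINDS), collapse = ", ")))
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (ncol(object) < 2L)
    msg <- c(msg, "at least 2 samples are required")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "entity ids must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, entities in rows, samples in columns; both
#'   dimensions must be named. \code{NA} marks missing measurements.
#' @param platform platform tag (e.g. an array platform name).
#' @param valueKind \code{"abundance"} or \code{"log2ratio"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, platform = "demo")
#' dim(em)
#' @export
ExpressionMatrix <- function(values, platform = "unspecified",
                             valueKind = c("abundance", "log2ratio")) {
  valueKind <- match.arg(valueKind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionMatrix", se, platform = platform, valueKind = valueKind)
}

#' @describeIn ExpressionMatrix-class display a short summary
#' @param object an \code{ExpressionMatrix}
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d entities x %d samples [%s, %s]\n",
              nrow(object), ncol(object), object@platform, object@valueKind))
  cat(sprintf("  missing values: %d\n", sum(is.na(exprValues(object)))))
})

#' One miRNA's expression profile with a detectability mask
#'
#' Per-sample expression values of a single miRNA (or aggregated miRNA
#' family) plus the mask of samples in which it is detectable. The mask
#' gates which miRNAs enter downstream correlation (the panel-level
#' "detectable in at least \code{minSamples} samples" rule); correlations
#' themselves use all non-missing values.
#'
#' @slot name miRNA (or family) identifier.
#' @slot values named per-sample numeric vector (\code{NA} = missing).
#' @slot detectable named per-sample logical mask.
#' @export
setClass("MiRNAProfile",
  representation(name = "character", values = "numeric",
                 detectable = "logical"))

setValidity("MiRNAProfile", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (length(object@values) != length(object@detectable))
    msg <- c(msg, "'values' and 'detectable' lengths differ")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "sample names must be present and unique")
  if (any(object@detectable & !is.finite(object@values)))
    msg <- c(msg, "values must be finite where detectable")
  if (length(msg)) msg else TRUE
})

#' Construct a MiRNAProfile
#' @param name miRNA identifier.
#' @param values named per-sample numeric vector.
#' @param detectable per-sample logical mask (default: finite values).
#' @return A \linkS4class{MiRNAProfile}.
#' @export
MiRNAProfile <- function(name, values, detectable = is.finite(values)) {
  if (is.null(names(detectable))) names(detectable) <- names(values)
  new("MiRNAProfile", name = name, values = values,
      detectable = detectable)
}

#' @describeIn MiRNAProfile-class display a short summary
#' @param object a \code{MiRNAProfile}
#' @export
setMethod("show", "MiRNAProfile", function(object) {
  cat(sprintf("MiRNAProfile %s: %d samples, detectable in %d\n",
              object@name, length(object@values), nDetectable(object)))
})

#' Named gene signature with direction labels
#'
#' A named list of genes, each labelled \code{"up"} or \code{"down"}.
#' For EMT signatures epithelial genes are \code{"up"} and mesenchymal
#' genes \code{"down"}; for regulator signatures induced genes are
#' \code{"up"} and repressed genes \code{"down"}. Direction-less lists
#' (e.g. ribosomal proteins) use \code{"up"} throughout.
#'
#' @slot name signature name.
#' @slot genes character vector of unique gene symbols.
#' @slot direction character vector, one of \code{"up"}/\code{"down"} per gene.
#' @export
setClass("GeneSignature",
  representation(name = "character", genes = "character",
                 direction = "character"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique within a signature")
  if (length(object@genes) != length(object@direction))
    msg <- c(msg, "'genes' and 'direction' lengths differ")
  if (!all(object@direction %in% c("up", "down")))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#' @param name signature name.
#' @param genes character vector of gene symbols.
#' @param direction \code{"up"}/\code{"down"} per gene; recycled if length 1.
#' @return A \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(name, genes, direction = "up") {
  direction <- rep_len(direction, length(genes))
  new("GeneSignature", name = name, genes = as.character(genes),
      direction = as.character(direction))
}

#' @describeIn GeneSignature-class display a short summary
#' @param object a \code{GeneSignature}
#' @export
setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature %s: %d genes (%d up, %d down)\n",
              object@name, length(object@genes),
              sum(object@direction == "up"),
              sum(object@direction == "down")))
})

#' Nested sample patterns for the titration statistic
#'
#' Samples ranked by miRNA expression (highest first; ties broken by sample
#' id for determinism, samples with missing miRNA values last). Pattern k
#' consists of the top \code{minSize + k - 1} samples, so the series runs
#' from the \code{minSize} highest-expression samples to the full panel and
#' each pattern extends the previous one by a single sample.
#'
#' @slot sampleOrder sample ids, descending miRNA expression.
#' @slot minSize size of the first (smallest) pattern.
#' @export
setClass("PatternSeries",
  representation(sampleOrder = "character", minSize = "integer"))

setValidity("PatternSeries", function(object) {
  msg <- character()
  if (anyDuplicated(object@sampleOrder))
    msg <- c(msg, "sample ids must be unique")
  if (object@minSize < 2L)
    msg <- c(msg, "'minSize' must be >= 2")
  if (length(object@sampleOrder) < object@minSize)
    msg <- c(msg, "fewer samples than 'minSize'")
  if (length(msg)) msg else TRUE
})

#' @describeIn PatternSeries-class number of patterns in the series
#' @param x a \code{PatternSeries}
#' @export
setMethod("length", "PatternSeries", function(x)
  length(x@sampleOrder) - x@minSize + 1L)

#' @describeIn PatternSeries-class display a short summary
#' @param object a \code{PatternSeries}
#' @export
setMethod("show", "PatternSeries", function(object) {
  cat(sprintf("PatternSeries: %d patterns (sizes %d..%d)\n",
              length(object), object@minSize, length(object@sampleOrder)))
})

#' Per-gene correlation results for one miRNA
#'
#' Gene-level correlation values between one miRNA (or family) profile and
#' all genes, collapsed over probes and platforms: the titration statistic
#' \code{sPCC} (sum of per-pattern Pearson correlations), the plain
#' correlation \code{dPCC}, and optionally the randomised control
#' \code{rsPCC}. \code{sPCC/nPatterns} is on the usual [-1, 1] scale.
#'
#' @slot mirna miRNA or family name.
#' @slot minSize minimum pattern size used.
#' @slot nPatterns number of patterns summed into each sPCC.
#' @slot table data.frame with columns \code{gene}, \code{sPCC} and/or
#'   \code{dPCC}, optionally \code{rsPCC}, plus \code{nProbes}.
#' @export
setClass("CorrelationTable",
  representation(mirna = "character", minSize = "integer",
                 nPatterns = "integer", table = "data.frame"))

setValidity("CorrelationTable", function(object) {
  msg <- character()
  tab <- object@table
  if (!"gene" %in% names(tab)) msg <- c(msg, "table must have a 'gene' column")
  else if (anyDuplicated(tab$gene)) msg <- c(msg, "duplicate gene symbols")
  if (!any(c("sPCC", "dPCC", "rsPCC") %in% names(tab)))
    msg <- c(msg, "at least one correlation column is required")
  if ("dPCC" %in% names(tab) &&
      any(abs(tab$dPCC) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "|dPCC| must not exceed 1")
  if ("sPCC" %in% names(tab) &&
      any(abs(tab$sPCC) > object@nPatterns + 1e-8, na.rm = TRUE))
    msg <- c(msg, "|sPCC| must not exceed the number of patterns")
  if (length(msg)) msg else TRUE
})

#' Construct a CorrelationTable
#' @param mirna miRNA or family name.
#' @param table gene-level data.frame (see the class description).
#' @param minSize,nPatterns pattern-series shape used to compute it.
#' @return A \linkS4class{CorrelationTable}.
#' @export
CorrelationTable <- function(mirna, table, minSize, nPatterns) {
  new("CorrelationTable", mirna = mirna, table = table,
      minSize = as.integer(minSize), nPatterns = as.integer(nPatterns))
}

#' @describeIn CorrelationTable-class display a short summary
#' @param object a \code{CorrelationTable}
#' @export
setMethod("show", "CorrelationTable", function(object) {
  cat(sprintf("CorrelationTable for %s: %d genes, %d patterns (min size %d)\n",
              object@mirna, nrow(object@table), object@nPatterns,
              object@minSize))
  cat("  columns:", paste(names(object@table), collapse = ", "), "\n")
})

#' @describeIn CorrelationTable-class extract the gene-level table
#' @param x a \code{CorrelationTable}
#' @param row.names,optional,... passed through (unused)
#' @export
setMethod("as.data.frame", "CorrelationTable",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' miRNA-by-miRNA percent overlap of top correlator gene lists
#'
#' Square symmetric matrix of the percent identity of the top-N correlator
#' gene lists of every miRNA pair: \code{100 * |A intersect B| / N}.
#' The diagonal is 100 by construction.
#'
#' @export
setClass("OverlapMatrix", contains = "matrix")

setValidity("OverlapMatrix", function(object) {
  m <- object@.Data
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else {
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "identical row/column names required")
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(m) - 100) > 1e-8))
      msg <- c(msg, "diagonal must equal 100")
    if (any(m < -1e-8 | m > 100 + 1e-8))
      msg <- c(msg, "entries must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn OverlapMatrix-class display a short summary
#' @param object an \code{OverlapMatrix}
#' @export
setMethod("show", "OverlapMatrix", function(object) {
  m <- object@.Data
  off <- m[row(m) != col(m)]
  cat(sprintf("OverlapMatrix: %d miRNAs, off-diagonal range %.1f..%.1f%%\n",
              nrow(m), min(off), max(off)))
})
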