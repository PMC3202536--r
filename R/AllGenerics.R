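#' Accessors for miRtitrate classes
#'
#' Small accessor generics: \code{exprValues} returns the expression matrix
#' of an \linkS4class{ExpressionMatrix}; \code{platformName} and
#' \code{valueKind} its metadata; \code{profileValues},
#' \code{detectableMask} and \code{nDetectable} the parts of a
#' \linkS4class{MiRNAProfile}; \code{mirnaName} and \code{nPatterns} the
#' metadata of a \linkS4class{CorrelationTable}; \code{patternSamples} the
#' sample ids of pattern \code{k} in a \linkS4class{PatternSeries}.
#'
#' @param x object to access.
#' @param k pattern index (1 = smallest pattern).
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("platformName", function(x) standardGeneric("platformName"))
#' @rdname accessors
#' @export
setMethod("platformName", "ExpressionMatrix", function(x) x@platform)

#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @rdname accessors
#' @export
setMethod("valueKind", "ExpressionMatrix", function(x) x@valueKind)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "MiRNAProfile", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("detectableMask", function(x) standardGeneric("detectableMask"))
#' @rdname accessors
#' @export
setMethod("detectableMask", "MiRNAProfile", function(x) x@detectable)

#' @rdname accessors
#' @export
setGeneric("nDetectable", function(x) standardGeneric("nDetectable"))
#' @rdname accessors
#' @export
setMethod("nDetectable", "MiRNAProfile", function(x) sum(x@detectable))

#' @rdname accessors
#' @export
setGeneric("mirnaName", function(x) standardGeneric("mirnaName"))
#' @rdname accessors
#' @export
setMethod("mirnaName", "MiRNAProfile", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("mirnaName", "CorrelationTable", function(x) x@mirna)

#' @rdname accessors
#' @export
setGeneric("nPatterns", function(x) standardGeneric("nPatterns"))
#' @rdname accessors
#' @export
setMethod("nPatterns", "CorrelationTable", function(x) x@nPatterns)
#' @rdname accessors
#' @export
setMethod("nPatterns", "PatternSeries", function(x) length(x))

#' @rdname accessors
#' @export
setGeneric("patternSamples", function(x, k) standardGeneric("patternSamples"))
#' @rdname accessors
#' @export
setMethod("patternSamples", "PatternSeries", function(x, k) {
  stopifnot(k >= 1L, k <= length(x))
  x@sampleOrder[seq_len(x@minSize + k - 1L)]
})

#' @rdname accessors
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))
#' @rdname accessors
#' @export
setMethod("signatureName", "GeneSignature", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setMethod("signatureGenes", "GeneSignature",
          function(x) setNames(x@direction, x@genes))
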