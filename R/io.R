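## Tabular readers/writers. All formats are plain TSV; "", "NA", "NaN" are
## read as missing and written back as "NA".

NA_STRINGS <- c("", "NA", "NaN")

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = NA_STRINGS, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "")
}

#' Read an expression matrix from TSV
#'
#' First row holds sample names, first column entity ids (miRNA names or
#' probe ids). Empty cells, \code{NA} and \code{NaN} denote missing values;
#' they are kept as \code{NA}, never zero-filled. For PCR-derived (ct-style)
#' data the caller must supply already-normalised abundance values in which
#' higher means more expressed; ct inversion is not performed here.
#'
#' @param path TSV file path.
#' @param platform platform tag stored with the matrix.
#' @param valueKind \code{"abundance"} or \code{"log2ratio"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, platform = "unspecified",
                                 valueKind = c("abundance", "log2ratio")) {
  valueKind <- match.arg(valueKind)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- first[-1]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample column name(s): ", paste(unique(dup), collapse = ", "))
  tab <- read_tsv_checked(path)
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate entity id(s): ", paste(unique(dup), collapse = ", "))
  body <- tab[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (is.character(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     col[bad[1]], ids[bad[1]], names(body)[j]))
      body[[j]] <- as.numeric(col)
    }
  }
  values <- as.matrix(body)
  dimnames(values) <- list(ids, names(body))
  ExpressionMatrix(values, platform = platform, valueKind = valueKind)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()]; missing values are written as
#' \code{NA} so that a read/write round trip is the identity.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path) {
  v <- exprValues(x)
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Gate miRNAs on panel-wide detectability
#'
#' Converts the rows of a miRNA expression matrix into
#' \linkS4class{MiRNAProfile} objects and keeps only miRNAs detectable
#' (non-missing value at or above \code{limit}) in at least
#' \code{minSamples} samples — the panel rule used to decide which miRNAs
#' are correlated at all. The default \code{limit = -Inf} treats any
#' non-missing measurement as detectable.
#'
#' @param x an \linkS4class{ExpressionMatrix} of miRNAs.
#' @param limit detection limit on the scale of the stored values.
#' @param minSamples minimum number of detectable samples (default 30,
#'   i.e. at least half of a 59-sample panel).
#' @return Named list of \linkS4class{MiRNAProfile}, in input row order.
#' @export
detectabilityFilter <- function(x, limit = -Inf, minSamples = 30L) {
  stopifnot(minSamples >= 2L)
  v <- exprValues(x)
  if (minSamples > ncol(v))
    stop(sprintf("minSamples (%d) exceeds the number of samples (%d)",
                 minSamples, ncol(v)))
  out <- list()
  for (i in seq_len(nrow(v))) {
    vals <- v[i, ]
    mask <- !is.na(vals) & vals >= limit
    if (sum(mask) >= minSamples)
      out[[rownames(v)[i]]] <- MiRNAProfile(rownames(v)[i], vals, mask)
  }
  out
}

#' Read a probe-to-gene mapping table
#'
#' Three-column TSV (\code{probe}, \code{gene}, \code{platform}). A probe
#' may map to at most one gene symbol within a platform; genes typically
#' have many probes across platforms.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{probe}, \code{gene}, \code{platform}.
#' @export
readProbeGeneMap <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("probe", "gene", "platform")
  if (!all(need %in% names(tab)))
    stop("probe map must have columns: ", paste(need, collapse = ", "))
  tab <- tab[need]
  key <- paste(tab$platform, tab$probe)
  dup <- tab$probe[duplicated(key)]
  if (length(dup))
    stop("probe(s) mapped more than once: ", paste(unique(dup), collapse = ", "))
  tab
}

#' Read a gene signature from TSV
#'
#' Two-column TSV (\code{gene}, \code{direction}) with direction
#' \code{"up"}/\code{"down"}.
#'
#' @param path TSV file path.
#' @param name signature name (default: file name without extension).
#' @return A \linkS4class{GeneSignature}.
#' @export
readGeneSignature <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- read_tsv_checked(path)
  if (!all(c("gene", "direction") %in% names(tab)))
    stop("signature file must have columns 'gene' and 'direction'")
  GeneSignature(name, tab$gene, tab$direction)
}

#' Read a miRNA/host-gene pair table
#'
#' Two-column TSV (\code{mirna}, \code{host_gene}); duplicated pairs are an
#' error.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{mirna}, \code{host_gene}.
#' @export
readHostPairs <- function(path) {
  tab <- read_tsv_checked(path)
  if (!all(c("mirna", "host_gene") %in% names(tab)))
    stop("host pair file must have columns 'mirna' and 'host_gene'")
  if (anyDuplicated(tab[c("mirna", "host_gene")]))
    stop("duplicated miRNA/host gene pair(s)")
  tab[c("mirna", "host_gene")]
}

#' Read a target-prediction table
#'
#' TSV with columns \code{mirna}, \code{gene} and either a site-level
#' \code{context_score} column (several rows per pair) or a pre-aggregated
#' \code{total_context_score} column (one row per pair); the variant is
#' auto-detected from the header.
#'
#' @param path TSV file path.
#' @return data.frame; attribute \code{"level"} is \code{"site"} or
#'   \code{"total"}.
#' @export
readPredictions <- function(path) {
  tab <- read_tsv_checked(path)
  if (!all(c("mirna", "gene") %in% names(tab)))
    stop("prediction file must have columns 'mirna' and 'gene'")
  if ("total_context_score" %in% names(tab)) {
    if (anyDuplicated(tab[c("mirna", "gene")]))
      stop("duplicated (mirna, gene) pair(s) in aggregated predictions")
    attr(tab, "level") <- "total"
  } else if ("context_score" %in% names(tab)) {
    attr(tab, "level") <- "site"
  } else stop("prediction file needs 'context_score' or 'total_context_score'")
  tab
}

#' Write / read a correlation table
#'
#' TSV export of a \linkS4class{CorrelationTable}: commented metadata lines
#' (miRNA name, pattern counts) followed by the gene-level columns. Columns
#' that were not computed (e.g. \code{rsPCC}) are omitted, not zero-filled.
#' \code{readCorrelationTable} restores an identical object.
#'
#' @param x a \linkS4class{CorrelationTable}.
#' @param path file path.
#' @return \code{writeCorrelationTable}: invisibly, \code{path};
#'   \code{readCorrelationTable}: a \linkS4class{CorrelationTable}.
#' @export
writeCorrelationTable <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mirna=%s", x@mirna),
               sprintf("# minSize=%d", x@minSize),
               sprintf("# nPatterns=%d", x@nPatterns)), con)
  utils::write.table(format_num_df(x@table), con, sep = "\t", quote = FALSE,
                     na = "NA", row.names = FALSE)
  invisible(path)
}

## full-precision, locale-independent numeric formatting for TSV export
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        formatC(df[[j]], digits = 17, format = "g"))
  df
}

#' @rdname writeCorrelationTable
#' @export
readCorrelationTable <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- sub("^# ", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  tab <- read_tsv_checked(path)
  tab$gene <- as.character(tab$gene)
  CorrelationTable(meta[["mirna"]], tab,
                   minSize = as.integer(meta[["minSize"]]),
                   nPatterns = as.integer(meta[["nPatterns"]]))
}
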