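## Signature scoring: count signature genes among a miRNA's positive and
## negative correlators, derive net scores and the epithelial/mesenchymal
## factor, rank miRNAs, and test per-cluster enrichment.

#' Count signature genes among a miRNA's correlators
#'
#' Two counting modes. \code{"threshold"}: a signature gene counts as a
#' positive correlator when its correlation value exceeds \code{cutoff}
#' and as a negative one when it falls below \code{-cutoff} (strictly;
#' values inside the band are uncounted, matching the ">1 or <-1"
#' convention for raw sPCC values). \code{"topn"}: a gene counts when it
#' is a member of the top-\code{n} positive or negative correlator list.
#' Genes absent from the table count as neither.
#'
#' @param signature a \linkS4class{GeneSignature}.
#' @param x a \linkS4class{CorrelationTable}.
#' @param mode \code{"threshold"} or \code{"topn"}.
#' @param cutoff threshold-mode cutoff (default 1, the raw-sPCC convention).
#' @param n topn-mode list size (default 2000).
#' @param method correlation column to use.
#' @return Named integer vector: \code{posUp}, \code{negUp}, \code{posDown},
#'   \code{negDown}.
#' @export
countSignatureCorrelators <- function(signature, x,
                                      mode = c("threshold", "topn"),
                                      cutoff = 1, n = 2000L,
                                      method = "sPCC") {
  mode <- match.arg(mode)
  dir <- signatureGenes(signature)
  tab <- x@table
  if (mode == "threshold") {
    v <- setNames(tab[[method]], tab$gene)[names(dir)]
    pos <- !is.na(v) & v > cutoff
    neg <- !is.na(v) & v < -cutoff
  } else {
    posList <- suppressWarnings(topCorrelators(x, n, "positive", method))
    negList <- suppressWarnings(topCorrelators(x, n, "negative", method))
    pos <- names(dir) %in% posList
    neg <- names(dir) %in% negList
  }
  c(posUp = sum(pos & dir == "up"), negUp = sum(neg & dir == "up"),
    posDown = sum(pos & dir == "down"), negDown = sum(neg & dir == "down"))
}

#' Net correlation score of a signature
#'
#' Number of signature genes positively correlating with the miRNA minus
#' the number negatively correlating, ignoring direction labels; used for
#' direction-less signatures such as ribosomal protein genes, where a
#' large positive score reads as growth-promoting and a large negative
#' one as growth-suppressing.
#'
#' @param counts output of [countSignatureCorrelators()].
#' @return Integer score.
#' @export
netScore <- function(counts) {
  as.integer((counts[["posUp"]] + counts[["posDown"]]) -
             (counts[["negUp"]] + counts[["negDown"]]))
}

#' Epithelial/mesenchymal factor
#'
#' \code{(negatively correlating M genes - positively correlating M genes)
#' + (positively correlating E genes - negatively correlating E genes)},
#' with epithelial genes labelled \code{"up"} and mesenchymal genes
#' \code{"down"}. Large positive values mark miRNAs of epithelial nature,
#' large negative values mesenchymal ones.
#'
#' @param counts output of [countSignatureCorrelators()].
#' @return Integer factor.
#' @export
emFactor <- function(counts) {
  as.integer((counts[["negDown"]] - counts[["posDown"]]) +
             (counts[["posUp"]] - counts[["negUp"]]))
}

#' Rank miRNAs by a score
#'
#' Descending sort with deterministic tie-break by name.
#'
#' @param factors named numeric vector (miRNA -> score).
#' @return Character vector of miRNA names, highest score first.
#' @export
rankByFactor <- function(factors) {
  names(factors)[order(-factors, names(factors))]
}

#' Wilcoxon rank-sum enrichment of scores per functional cluster
#'
#' For each cluster, compares the scores of its miRNAs against all other
#' miRNAs with a two-sided Wilcoxon rank-sum test (exact for small untied
#' samples, midrank normal approximation otherwise) and labels the
#' significance tier: \code{"0.0001"}, \code{"0.001"}, \code{"0.01"} or
#' \code{"ns"}.
#'
#' @param scores named numeric vector (miRNA -> score).
#' @param clusters data.frame from [functionalClusters()].
#' @param alternative passed to [stats::wilcox.test()].
#' @return data.frame with columns \code{cluster}, \code{n}, \code{p},
#'   \code{tier}.
#' @export
clusterEnrichment <- function(scores, clusters,
                              alternative = "two.sided") {
  stopifnot(length(unique(clusters$cluster)) >= 2L)
  out <- lapply(levels(droplevels(clusters$cluster)), function(cl) {
    inC <- clusters$mirna[clusters$cluster == cl]
    outC <- setdiff(clusters$mirna, inC)
    if (!length(outC))
      stop("a cluster containing every miRNA cannot be tested")
    p <- if (length(unique(c(scores[inC], scores[outC]))) == 1L) 1
    else suppressWarnings(
      wilcox.test(scores[inC], scores[outC],
                  alternative = alternative)$p.value)
    data.frame(cluster = cl, n = length(inC), p = p,
               tier = significanceTier(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

significanceTier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "0.0001" else if (p < 1e-3) "0.001" else
    if (p < 1e-2) "0.01" else "ns"
}

#' Correlations between miRNAs and their host genes
#'
#' miRNAs encoded within host genes are co-transcribed with them, so their
#' expression should correlate positively — a built-in biological positive
#' control. For each pair the table reports the raw sPCC, the normalised
#' sPCC (divided by the number of patterns, bringing it to the dPCC
#' scale so one cutoff serves both methods) and the dPCC. Pairs whose gene
#' is absent from the table are flagged and excluded from the summary
#' counts; counting at the cutoff is strict (\code{> cutoff} positive,
#' \code{< -cutoff} negative).
#'
#' @param pairs data.frame from [readHostPairs()].
#' @param tables named list of \linkS4class{CorrelationTable}.
#' @param cutoff summary-count cutoff on the normalised scale (default 0.2).
#' @return data.frame with one row per pair; attribute \code{"summary"}
#'   holds the positive/negative/uncounted totals.
#' @export
hostPairCorrelations <- function(pairs, tables, cutoff = 0.2) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- pairs$mirna[i]; g <- pairs$host_gene[i]
    ct <- tables[[m]]
    if (is.null(ct))
      return(data.frame(mirna = m, host_gene = g, sPCC = NA, sPCCnorm = NA,
                        dPCC = NA, status = "mirna_missing"))
    tab <- ct@table
    j <- match(g, tab$gene)
    if (is.na(j))
      return(data.frame(mirna = m, host_gene = g, sPCC = NA, sPCCnorm = NA,
                        dPCC = NA, status = "gene_missing"))
    s <- if ("sPCC" %in% names(tab)) tab$sPCC[j] else NA_real_
    d <- if ("dPCC" %in% names(tab)) tab$dPCC[j] else NA_real_
    data.frame(mirna = m, host_gene = g, sPCC = s,
               sPCCnorm = s / nPatterns(ct), dPCC = d, status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  v <- out$sPCCnorm[out$status == "ok"]
  attr(out, "summary") <- c(positive = sum(v > cutoff, na.rm = TRUE),
                            negative = sum(v < -cutoff, na.rm = TRUE),
                            uncounted = sum(abs(v) <= cutoff, na.rm = TRUE))
  attr(out, "cutoff") <- cutoff
  out
}

#' Cumulative correlation scores over gene blocks (HOX-style)
#'
#' For co-regulated genomic gene blocks (the four HOX clusters in the
#' canonical example), sums each miRNA's per-gene correlation value over all
#' members of each block and ranks the miRNAs per block; the miRNA encoded
#' within a block is expected to rank first for it. Absent genes
#' contribute 0 and are flagged.
#'
#' @param geneClusters named list of gene-symbol vectors.
#' @param tables named list of \linkS4class{CorrelationTable}.
#' @param method correlation column to cumulate (default \code{"sPCC"}).
#' @return data.frame with columns \code{mirna}, \code{cluster},
#'   \code{score}, \code{nFound}, \code{rank} (1 = highest score within
#'   the cluster).
#' @export
hoxCumulativeScores <- function(geneClusters, tables, method = "sPCC") {
  rows <- list()
  for (cl in names(geneClusters)) {
    genes <- geneClusters[[cl]]
    if (!length(genes)) warning("empty gene cluster: ", cl)
    for (m in names(tables)) {
      tab <- tables[[m]]@table
      v <- setNames(tab[[method]], tab$gene)[genes]
      rows[[length(rows) + 1L]] <-
        data.frame(mirna = m, cluster = cl,
                   score = sum(v, na.rm = TRUE),
                   nFound = sum(!is.na(v)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  for (cl in unique(out$cluster)) {
    idx <- which(out$cluster == cl)
    ord <- order(-out$score[idx], out$mirna[idx])
    out$rank[idx[ord]] <- seq_along(idx)
  }
  out
}
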