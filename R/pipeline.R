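## End-to-end orchestration and a flat-file query surface: TSV outputs, a
## manifest, and forward / reverse lookups over the exported correlation
## tables (no server or database needed).

#' Run the full correlation-and-clustering analysis
#'
#' Orchestrates the pipeline on in-memory inputs (typically a synthetic
#' panel or matrices loaded with the readers): detectability gating,
#' optional family aggregation, genome-wide correlation tables per miRNA,
#' top-correlator overlap clustering, and optional signature scoring and
#' host-pair validation. All outputs are written as TSV under
#' \code{outDir} together with a \code{manifest.json} recording the
#' parameters and seed; re-running with the same inputs and seed
#' reproduces identical files. On failure a \code{FAILED} marker file is
#' left in \code{outDir}.
#'
#' @param mirna \linkS4class{ExpressionMatrix} of miRNAs.
#' @param mrna list of probe-level \linkS4class{ExpressionMatrix}.
#' @param probeMap data.frame probe map.
#' @param outDir output directory (created if needed).
#' @param methods correlation methods, see [computeCorrelations()].
#' @param detectionLimit,minSamples detectability gate.
#' @param minSize,minPairs,nReps engine parameters.
#' @param seed integer seed (required with \code{"rspcc"}).
#' @param topN top-correlator list size for clustering.
#' @param clusterSign \code{"positive"} or \code{"negative"} lists.
#' @param shareThreshold cluster cut threshold (percent).
#' @param seedTable optional data.frame (\code{mirna}, \code{family}) for
#'   family profiles.
#' @param signature optional \linkS4class{GeneSignature} to score.
#' @param hostPairs optional host-pair data.frame.
#' @param signatureCutoff threshold-mode cutoff for signature counting.
#' @return Invisibly, a list with the in-memory results (\code{tables},
#'   \code{clusters}, \code{overlap}, \code{scores}, \code{hostPairs},
#'   \code{outDir}).
#' @export
runFullAnalysis <- function(mirna, mrna, probeMap, outDir,
                            methods = c("spcc", "dpcc"),
                            detectionLimit = -Inf, minSamples = 30L,
                            minSize = 30L, minPairs = 10L, nReps = 10L,
                            seed = NULL, topN = 100L,
                            clusterSign = "positive",
                            shareThreshold = 12.5,
                            seedTable = NULL, signature = NULL,
                            hostPairs = NULL, signatureCutoff = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(outDir, "FAILED")
  if (file.exists(failed)) file.remove(failed)
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline failed; partial outputs kept",
                              failed))
  ## validate inputs before any computation
  if (!all(c("probe", "gene", "platform") %in% names(probeMap)) ||
      nrow(probeMap) == 0L)
    stop("probe map is missing or empty; supply probe/gene/platform rows")
  mapKey <- paste(probeMap$platform, probeMap$probe)
  mapped <- vapply(mrna, function(em)
    any(paste(platformName(em), rownames(exprValues(em))) %in% mapKey),
    TRUE)
  if (!all(mapped))
    stop("probe map covers no probe of platform(s): ",
         paste(vapply(mrna[!mapped], platformName, ""), collapse = ", "))
  profiles <- detectabilityFilter(mirna, detectionLimit, minSamples)
  if (!length(profiles)) stop("no miRNA passed the detectability gate")
  if (!is.null(seedTable)) {
    fams <- familiesFromSeedTable(seedTable, names(profiles))
    for (fn in names(fams))
      profiles[[fn]] <- buildFamilyProfile(mirna, fams[[fn]], fn,
                                           limit = detectionLimit)
  }
  tables <- computeCorrelations(profiles, mrna, probeMap,
                                methods = methods, minSize = minSize,
                                minPairs = minPairs, nReps = nReps,
                                seed = seed)
  corrDir <- file.path(outDir, "correlations")
  dir.create(corrDir, showWarnings = FALSE)
  for (m in names(tables))
    writeCorrelationTable(tables[[m]],
                          file.path(corrDir, paste0(m, ".tsv")))
  rankCol <- if ("spcc" %in% methods) "sPCC" else "dPCC"
  lists <- lapply(tables, function(ct)
    suppressWarnings(topCorrelators(ct, topN, clusterSign, rankCol)))
  clusters <- NULL; ov <- NULL
  if (length(lists) >= 2L) {
    ov <- overlapMatrix(lists, denom = topN)
    clusters <- functionalClusters(ov, shareThreshold)
    utils::write.table(clusters, file.path(outDir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pc <- pcaScores(ov)
    utils::write.table(format_num_df(pc), file.path(outDir, "pca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  scores <- NULL
  if (!is.null(signature)) {
    counts <- t(vapply(tables, function(ct)
      countSignatureCorrelators(signature, ct, "threshold",
                                cutoff = signatureCutoff,
                                method = rankCol),
      integer(4)))
    scores <- data.frame(mirna = rownames(counts), counts,
                         net = apply(counts, 1, function(cc) netScore(as.list(cc))),
                         em = apply(counts, 1, function(cc) emFactor(as.list(cc))),
                         stringsAsFactors = FALSE)
    rownames(scores) <- NULL
    utils::write.table(scores, file.path(outDir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  hp <- NULL
  if (!is.null(hostPairs)) {
    hp <- hostPairCorrelations(hostPairs, tables)
    utils::write.table(format_num_df(hp),
                       file.path(outDir, "host_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(package = "miRtitrate",
                   version = as.character(utils::packageVersion("miRtitrate")),
                   methods = methods, minSize = minSize,
                   minPairs = minPairs, nReps = nReps,
                   seed = if (is.null(seed)) NA else seed,
                   topN = topN, clusterSign = clusterSign,
                   shareThreshold = shareThreshold,
                   nProfiles = length(profiles),
                   nPlatforms = length(mrna))
  writeLines(manifestJSON(manifest), file.path(outDir, "manifest.json"))
  ok <- TRUE
  invisible(list(tables = tables, clusters = clusters, overlap = ov,
                 scores = scores, hostPairs = hp, outDir = outDir))
}

## minimal JSON writer (scalars and flat vectors) to avoid a hard
## dependency for the manifest
manifestJSON <- function(x) {
  enc <- function(v) {
    if (length(v) == 1L && is.na(v)) return("null")
    if (is.numeric(v)) s <- formatC(v, format = "g", digits = 15)
    else s <- paste0('"', gsub('"', '\\\\"', as.character(v)), '"')
    if (length(s) > 1L) paste0("[", paste(s, collapse = ", "), "]") else s
  }
  paste0("{\n",
         paste(sprintf('  "%s": %s', names(x), vapply(x, enc, "")),
               collapse = ",\n"),
         "\n}")
}

#' Query exported correlation tables
#'
#' Forward and reverse lookups over a directory of correlation tables
#' written by [runFullAnalysis()] (or [writeCorrelationTable()]): given a
#' miRNA, list its correlated genes; given genes, list the miRNAs they
#' correlate with. Results are ordered by decreasing absolute value;
#' unknown identifiers yield an empty result with a warning.
#'
#' @param corrDir directory containing \code{<mirna>.tsv} tables.
#' @param mirna optional miRNA name (forward query).
#' @param genes optional character vector of gene symbols (reverse query).
#' @param sign \code{"positive"}, \code{"negative"} or \code{"both"}.
#' @param method correlation column to use.
#' @param limit maximum rows returned.
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{value}.
#' @export
queryCorrelations <- function(corrDir, mirna = NULL, genes = NULL,
                              sign = c("both", "positive", "negative"),
                              method = "sPCC", limit = Inf) {
  sign <- match.arg(sign)
  stopifnot(xor(is.null(mirna), is.null(genes)))
  files <- list.files(corrDir, pattern = "\\.tsv$", full.names = TRUE)
  empty <- data.frame(mirna = character(), gene = character(),
                      value = numeric())
  pick <- function(ct, gset = NULL) {
    tab <- ct@table
    v <- tab[[method]]
    keep <- !is.na(v)
    if (sign == "positive") keep <- keep & v > 0
    if (sign == "negative") keep <- keep & v < 0
    if (!is.null(gset)) keep <- keep & tab$gene %in% gset
    if (!any(keep)) return(NULL)
    data.frame(mirna = mirnaName(ct), gene = tab$gene[keep],
               value = v[keep], stringsAsFactors = FALSE)
  }
  if (!is.null(mirna)) {
    f <- file.path(corrDir, paste0(mirna, ".tsv"))
    if (!file.exists(f)) {
      warning("unknown miRNA: ", mirna)
      return(empty)
    }
    out <- pick(readCorrelationTable(f))
    if (is.null(out)) return(empty)
  } else {
    out <- do.call(rbind, lapply(files, function(f)
      pick(readCorrelationTable(f), gset = genes)))
    if (is.null(out) || !nrow(out)) {
      warning("no matching gene found")
      return(empty)
    }
  }
  out <- out[order(-abs(out$value), out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  head(out, limit)
}
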