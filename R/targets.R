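## Target-prediction processing (TargetScan-style context scores) and the
## method-comparison analyses: negative/positive correlation count ratios
## and their distributional comparison, and the prediction-strength ratio
## curve.

#' Total context score of a miRNA-gene pair
#'
#' Sum of the site-level context scores, keeping only non-positive site
#' scores (sites predicted to increase expression are excluded). A pair
#' with no non-positive site score is dropped (\code{NA}).
#'
#' @param siteScores numeric vector of site-level context scores.
#' @return Total context score (\eqn{\le 0}), or \code{NA}.
#' @export
totalContextScore <- function(siteScores) {
  s <- siteScores[!is.na(siteScores) & siteScores <= 0]
  if (!length(s)) return(NA_real_)
  sum(s)
}

#' Aggregate site-level predictions to pair totals
#'
#' @param predictions data.frame from [readPredictions()]; site-level
#'   tables are aggregated with [totalContextScore()] per (miRNA, gene)
#'   pair, pre-aggregated tables pass through.
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{total_context_score}, dropped pairs removed.
#' @export
aggregatePredictions <- function(predictions) {
  if (identical(attr(predictions, "level"), "total") ||
      "total_context_score" %in% names(predictions)) {
    out <- predictions[c("mirna", "gene", "total_context_score")]
    return(out[!is.na(out$total_context_score), , drop = FALSE])
  }
  key <- interaction(predictions$mirna, predictions$gene, drop = TRUE)
  tot <- tapply(predictions$context_score, key, totalContextScore)
  ids <- strsplit(names(tot), ".", fixed = TRUE)
  out <- data.frame(mirna = vapply(ids, `[`, "", 1L),
                    gene = vapply(ids, `[`, "", 2L),
                    total_context_score = as.numeric(tot),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$total_context_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family-level aggregate prediction
#'
#' The prediction for a miRNA family against a gene is the minimum (most
#' negative, i.e. strongest) total context score over its members.
#'
#' @param memberTotals numeric vector of member total context scores.
#' @return Minimum member total.
#' @export
familyAggregatePrediction <- function(memberTotals) {
  memberTotals <- memberTotals[!is.na(memberTotals)]
  if (!length(memberTotals)) stop("no member totals supplied")
  min(memberTotals)
}

#' Per-miRNA log2 ratio of negative to positive correlator counts
#'
#' Counts, per miRNA, the genes whose correlation value is below
#' \code{-cutoff} versus above \code{cutoff} (with \code{cutoff = 0}:
#' strictly negative vs strictly positive) and returns
#' \code{log2((neg + pseudocount) / (pos + pseudocount))}. Since miRNAs
#' predominantly repress their targets, methods that resolve genuine
#' miRNA-gene coupling shift this distribution to the right. sPCC-scale
#' values are normalised by the pattern count first so one cutoff serves
#' all methods.
#'
#' @param tables named list of \linkS4class{CorrelationTable}.
#' @param method correlation column to count.
#' @param cutoff magnitude cutoff on the normalised (per-pattern) scale.
#' @param pseudocount added to both counts (default 1).
#' @return data.frame with columns \code{mirna}, \code{neg}, \code{pos},
#'   \code{log2Ratio}.
#' @export
negPosLog2Ratio <- function(tables, method = "sPCC", cutoff = 0,
                            pseudocount = 1) {
  rows <- lapply(names(tables), function(m) {
    ct <- tables[[m]]
    v <- ct@table[[method]]
    if (method %in% c("sPCC", "rsPCC")) v <- v / nPatterns(ct)
    v <- v[!is.na(v)]
    neg <- sum(v < -cutoff); pos <- sum(v > cutoff)
    data.frame(mirna = m, neg = neg, pos = pos,
               log2Ratio = log2((neg + pseudocount) / (pos + pseudocount)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether sample \code{a} is stochastically larger than sample
#' \code{b} (its empirical CDF lies below/right of \code{b}'s), reporting
#' the one-sided statistic \eqn{D = \sup_t (F_b(t) - F_a(t))} and its
#' asymptotic p value.
#'
#' @param a,b numeric samples.
#' @return List with elements \code{D} and \code{p}.
#' @export
ksOneSided <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ## "less": the CDF of x lies below that of y => x stochastically larger
  res <- suppressWarnings(ks.test(a, b, alternative = "less"))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Flag predicted targets in a correlation table
#'
#' Adds a logical \code{predictedTarget} column (and the pair's
#' \code{total_context_score} where available) to a correlation table, so
#' that exported tables carry the prediction annotation alongside the
#' correlation values.
#'
#' @param x a \linkS4class{CorrelationTable}.
#' @param predictions data.frame with columns \code{mirna}, \code{gene},
#'   \code{total_context_score} (see [aggregatePredictions()]).
#' @return The annotated \linkS4class{CorrelationTable}.
#' @export
flagPredictedTargets <- function(x, predictions) {
  sub <- predictions[predictions$mirna == mirnaName(x), , drop = FALSE]
  tab <- x@table
  j <- match(tab$gene, sub$gene)
  tab$predictedTarget <- !is.na(j)
  tab$total_context_score <- sub$total_context_score[j]
  CorrelationTable(mirnaName(x), tab, minSize = x@minSize,
                   nPatterns = x@nPatterns)
}

#' Negative/positive correlation ratio along the prediction ranking
#'
#' Ranks predicted miRNA-gene pairs by prediction strength (most negative
#' total context score first by default; ties broken by miRNA then gene
#' for determinism) and, cumulatively at each list size k, counts the
#' pairs whose correlation value is negative versus positive. If true
#' targets concentrate among the strong predictions and the correlation
#' method resolves them, the ratio is highest at the top of the ranking
#' and decays along it. Pairs absent from the correlation tables are
#' skipped. A zero positive count at some k is handled with the
#' pseudocount and flagged.
#'
#' @param predictions data.frame with columns \code{mirna}, \code{gene},
#'   \code{total_context_score} (see [aggregatePredictions()]).
#' @param tables named list of \linkS4class{CorrelationTable}.
#' @param method correlation column to use.
#' @param kGrid cumulative list sizes (default \code{seq(50, 500, 50)}).
#' @param rankDirection \code{"ascending"} (most negative score =
#'   strongest, the default) or \code{"descending"}.
#' @param pseudocount used when a count is zero.
#' @return data.frame with columns \code{k}, \code{neg}, \code{pos},
#'   \code{ratio}, \code{flagged}.
#' @export
predictionRatioCurve <- function(predictions, tables, method = "sPCC",
                                 kGrid = seq(50L, 500L, 50L),
                                 rankDirection = c("ascending", "descending"),
                                 pseudocount = 1) {
  rankDirection <- match.arg(rankDirection)
  stopifnot(all(diff(kGrid) > 0))
  sc <- predictions$total_context_score
  ord <- if (rankDirection == "ascending")
    order(sc, predictions$mirna, predictions$gene)
  else order(-sc, predictions$mirna, predictions$gene)
  pred <- predictions[ord, , drop = FALSE]
  ## correlation value per pair (NA when miRNA table or gene is absent)
  val <- rep(NA_real_, nrow(pred))
  for (m in intersect(unique(pred$mirna), names(tables))) {
    ct <- tables[[m]]
    idx <- which(pred$mirna == m)
    v <- setNames(ct@table[[method]], ct@table$gene)
    val[idx] <- v[pred$gene[idx]]
  }
  keep <- !is.na(val)
  val <- val[keep]
  if (max(kGrid) > length(val))
    warning("fewer scored pairs than max(kGrid); curve truncated")
  kGrid <- kGrid[kGrid <= length(val)]
  cneg <- cumsum(val < 0); cpos <- cumsum(val > 0)
  neg <- cneg[kGrid]; pos <- cpos[kGrid]
  flagged <- neg == 0L | pos == 0L
  ratio <- ifelse(flagged,
                  (neg + pseudocount) / (pos + pseudocount),
                  neg / pos)
  data.frame(k = kGrid, neg = neg, pos = pos, ratio = ratio,
             flagged = flagged)
}
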