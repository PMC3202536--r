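## Functional clustering of miRNAs from the overlap of their top
## correlator gene lists, plus PCA of the overlap matrix.

#' Percent identity of two top-correlator gene lists
#'
#' \code{100 * |A intersect B| / denom}, where \code{denom} is the nominal
#' list size the lists were cut at.
#'
#' @param listA,listB character vectors of gene symbols.
#' @param denom nominal list size.
#' @return Percent overlap in \eqn{[0, 100]}.
#' @export
overlapPercent <- function(listA, listB, denom) {
  if (denom <= 0) stop("'denom' must be positive")
  100 * length(intersect(listA, listB)) / denom
}

#' Pairwise overlap matrix of top correlator lists
#'
#' @param topLists named list of gene lists (one per miRNA), all cut at
#'   the same nominal size.
#' @param denom nominal list size; defaults to the longest list.
#' @return An \linkS4class{OverlapMatrix}.
#' @export
overlapMatrix <- function(topLists, denom = max(lengths(topLists))) {
  ids <- names(topLists)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(topLists)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- overlapPercent(topLists[[i]], topLists[[j]], denom)
  }
  new("OverlapMatrix", m)
}

#' Functional clusters of miRNAs from the overlap matrix
#'
#' Embeds each miRNA as its row of overlap percentages, computes Euclidean
#' distances between rows and agglomerates with complete linkage. The tree
#' is cut at the largest height at which every within-cluster pair of
#' miRNAs directly shares more than \code{shareThreshold} percent of their
#' correlator genes (scanning merge heights from the top); this honours the
#' "more than x% shared genes" cluster definition deterministically, since
#' a percent threshold has no fixed Euclidean equivalent. A raw
#' \code{cutHeight} can be supplied instead. Cluster labels are Roman
#' numerals in dendrogram order.
#'
#' @param mat an \linkS4class{OverlapMatrix}.
#' @param shareThreshold minimum direct pairwise overlap (percent) within a
#'   cluster (default 12.5).
#' @param cutHeight optional explicit dendrogram cut height, overriding the
#'   threshold scan.
#' @return data.frame with columns \code{mirna}, \code{cluster} (ordered
#'   factor of Roman numerals); attributes \code{"cutHeight"},
#'   \code{"shareThreshold"} and \code{"tree"} (the \code{hclust} object).
#' @export
functionalClusters <- function(mat, shareThreshold = 12.5,
                               cutHeight = NULL) {
  m <- mat@.Data
  if (nrow(m) < 2L) stop("need at least 2 miRNAs to cluster")
  tree <- hclust(dist(m, method = "euclidean"), method = "complete")
  ids <- rownames(m)
  ok_cut <- function(labels) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) next
      sub <- m[idx, idx]
      if (min(sub[upper.tri(sub)]) <= shareThreshold) return(FALSE)
    }
    TRUE
  }
  if (is.null(cutHeight)) {
    labels <- seq_along(ids)            # all-singleton fallback
    cutHeight <- 0
    for (h in sort(unique(tree$height), decreasing = TRUE)) {
      cand <- cutree(tree, h = h)
      if (ok_cut(cand)) { labels <- cand; cutHeight <- h; break }
    }
  } else {
    labels <- cutree(tree, h = cutHeight)
  }
  ## relabel in dendrogram order with Roman numerals
  first <- vapply(unique(labels[tree$order]), function(cl)
    which(labels[tree$order] == cl)[1], 0L)
  dend_order <- unique(labels[tree$order])[order(first)]
  roman <- as.character(utils::as.roman(seq_along(dend_order)))
  lab <- roman[match(labels, dend_order)]
  out <- data.frame(mirna = ids,
                    cluster = factor(lab, levels = roman),
                    stringsAsFactors = FALSE)
  attr(out, "cutHeight") <- cutHeight
  attr(out, "shareThreshold") <- shareThreshold
  attr(out, "tree") <- tree
  out
}

#' Principal components of the overlap matrix
#'
#' Centered (unscaled — the matrix is already on a common percent scale)
#' PCA of the overlap-matrix rows; returns the scores on the two leading
#' components and their explained-variance fractions.
#'
#' @param mat an \linkS4class{OverlapMatrix}.
#' @return data.frame with columns \code{mirna}, \code{PC1}, \code{PC2};
#'   attribute \code{"varExplained"} gives the variance fractions. If the
#'   matrix has rank < 2 the available components are returned with a
#'   warning.
#' @export
pcaScores <- function(mat) {
  m <- mat@.Data
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  npc <- min(2L, ncol(p$x))
  tot <- sum(p$sdev^2)
  if (tot == 0 || (ncol(p$x) >= 2 && p$sdev[2]^2 / max(tot, 1e-300) < 1e-12)) {
    warning("overlap matrix has rank < 2; returning available components")
    npc <- max(1L, sum(p$sdev^2 / max(tot, 1e-300) > 1e-12))
    npc <- min(npc, 2L)
  }
  sc <- p$x[, seq_len(npc), drop = FALSE]
  out <- data.frame(mirna = rownames(m), sc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "varExplained") <-
    if (tot > 0) p$sdev[seq_len(npc)]^2 / tot else rep(0, npc)
  out
}
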