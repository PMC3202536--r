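## Correlation engine: plain Pearson on complete pairs, pattern series,
## the summed (titration) statistic, its randomised control, probe
## collapsing and top-correlator extraction.

#' Pearson correlation on complete pairs
#'
#' Product-moment correlation computed after dropping sample pairs in which
#' either value is missing. Returns \code{NA} (the undefined-result
#' sentinel excluded from all downstream averages) when fewer than
#' \code{minPairs} complete pairs remain or when either vector has zero
#' variance on the complete pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @param minPairs minimum number of complete pairs.
#' @return Correlation in \eqn{[-1, 1]}, or \code{NA}.
#' @examples
#' pearsonCC(c(1, 2, 3, 4), c(1, 3, 2, 4), minPairs = 3)  # 0.8
#' @export
pearsonCC <- function(x, y, minPairs = 10L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < minPairs) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

## descending expression, ties broken by sample id, missing values last
orderSamples <- function(values) {
  nm <- names(values)
  ord <- order(is.na(values), -rank(values, ties.method = "min",
                                    na.last = "keep"), nm)
  nm[ord]
}

#' Build the nested pattern series for a miRNA profile
#'
#' Ranks samples by miRNA expression (highest first; ties broken by sample
#' id, missing values last) and defines pattern k as the top
#' \code{minSize + k - 1} samples, from the \code{minSize}
#' highest-expression samples up to the whole panel. For a 59-sample panel
#' and the default \code{minSize = 30} this yields 30 patterns of sizes
#' 30..59.
#'
#' @param profile a \linkS4class{MiRNAProfile} or a named numeric vector.
#' @param minSize size of the smallest pattern (default 30).
#' @return A \linkS4class{PatternSeries}.
#' @export
buildPatterns <- function(profile, minSize = 30L) {
  values <- if (is(profile, "MiRNAProfile")) profileValues(profile) else profile
  if (length(values) < minSize)
    stop(sprintf("need at least %d samples, got %d", minSize, length(values)))
  new("PatternSeries", sampleOrder = orderSamples(values),
      minSize = as.integer(minSize))
}

#' Summed Pearson correlation (titration statistic)
#'
#' Sums the Pearson correlation between the miRNA profile and a gene over
#' every pattern of the series: the highest-expression samples appear in
#' all patterns and so carry the largest weight, mimicking a titration of
#' the miRNA. Patterns whose correlation is undefined (too few complete
#' pairs, zero variance) are skipped; if fewer than half the patterns are
#' defined the result is \code{NA}. The attribute
#' \code{"nPatternsEffective"} records how many patterns contributed.
#'
#' @param profile a \linkS4class{MiRNAProfile} or named numeric vector.
#' @param geneValues named numeric vector over the same samples.
#' @param patterns a \linkS4class{PatternSeries} built from \code{profile};
#'   built on the fly if \code{NULL}.
#' @param minSize pattern minimum size when \code{patterns} is \code{NULL}.
#' @param minPairs per-pattern minimum complete pairs (default 10).
#' @return The summed correlation (range \eqn{\pm} number of patterns).
#' @export
summedPCC <- function(profile, geneValues, patterns = NULL, minSize = 30L,
                      minPairs = 10L) {
  values <- if (is(profile, "MiRNAProfile")) profileValues(profile) else profile
  if (is.null(patterns)) patterns <- buildPatterns(values, minSize)
  pcc <- vapply(seq_len(length(patterns)), function(k) {
    s <- patternSamples(patterns, k)
    pearsonCC(values[s], geneValues[s], minPairs)
  }, numeric(1))
  nEff <- sum(!is.na(pcc))
  out <- if (nEff < ceiling(length(patterns) / 2)) NA_real_
         else sum(pcc, na.rm = TRUE)
  structure(out, nPatternsEffective = nEff)
}

#' Plain (direct) Pearson correlation over all samples
#'
#' @inheritParams summedPCC
#' @param minPairs minimum complete pairs.
#' @return Correlation in \eqn{[-1, 1]}, or \code{NA}.
#' @export
directPCC <- function(profile, geneValues, minPairs = 10L) {
  values <- if (is(profile, "MiRNAProfile")) profileValues(profile) else profile
  pearsonCC(values[names(geneValues)], geneValues, minPairs)
}

#' Randomised summed correlation (negative control)
#'
#' Recomputes the summed correlation with the sample ranking replaced by a
#' uniformly random ordering, repeated \code{nReps} times (default 10) and
#' averaged. Destroying the expression-based ranking removes exactly the
#' weighting that the titration statistic adds, so the result calibrates
#' how much of an sPCC is due to the ranking itself.
#'
#' @inheritParams summedPCC
#' @param nReps number of random orderings to average (default 10).
#' @param seed integer seed; required unless \code{orderings} is supplied.
#' @param orderings optional list of explicit sample-id orderings
#'   (overrides random draws; useful for controls and tests).
#' @return Mean summed correlation over the defined replicates, with
#'   attribute \code{"nRepsUsed"}; \code{NA} if all replicates are undefined.
#' @export
randomizedSPCC <- function(profile, geneValues, minSize = 30L, nReps = 10L,
                           seed = NULL, minPairs = 10L, orderings = NULL) {
  values <- if (is(profile, "MiRNAProfile")) profileValues(profile) else profile
  stopifnot(nReps >= 1L)
  if (is.null(orderings)) {
    if (is.null(seed)) stop("'seed' is required for random orderings")
    orderings <- withRNG(seed, replicate(nReps, sample(names(values)),
                                         simplify = FALSE))
  }
  reps <- vapply(orderings, function(ord) {
    ps <- new("PatternSeries", sampleOrder = ord,
              minSize = as.integer(minSize))
    as.numeric(summedPCC(values, geneValues, patterns = ps,
                         minPairs = minPairs))
  }, numeric(1))
  nUsed <- sum(!is.na(reps))
  out <- if (nUsed == 0L) NA_real_ else mean(reps, na.rm = TRUE)
  structure(out, nRepsUsed = nUsed)
}

## run code with a locally seeded RNG, restoring global RNG state after
withRNG <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Per-pattern Pearson correlations for a whole probe matrix
#'
#' Vectorised engine behind the pipeline: computes, for one miRNA profile
#' against every row of a probe/gene matrix, the Pearson correlation within
#' each nested pattern. Cumulative sums over the ranked sample order make
#' this O(entities x samples) per pattern series rather than a per-pattern
#' loop over \code{cor()} calls. Pairwise-complete handling matches
#' [pearsonCC()]: cells where either value is missing drop out of that
#' gene's sums, and entries with fewer than \code{minPairs} pairs or zero
#' variance are \code{NA}.
#'
#' @param x named numeric miRNA vector.
#' @param Y numeric matrix (entities x samples) with column names matching
#'   \code{names(x)}.
#' @param minSize smallest pattern size.
#' @param minPairs per-pattern minimum complete pairs.
#' @param sampleOrder optional explicit ordering (sample ids, "highest
#'   first"); defaults to the expression ranking of \code{x}.
#' @return Matrix entities x patterns of per-pattern correlations, with
#'   pattern sizes as column names.
#' @export
patternPCCMatrix <- function(x, Y, minSize = 30L, minPairs = 10L,
                             sampleOrder = NULL) {
  stopifnot(!is.null(names(x)), !is.null(colnames(Y)))
  if (!setequal(names(x), colnames(Y)))
    stop("sample ids of profile and matrix differ")
  if (is.null(sampleOrder)) sampleOrder <- orderSamples(x)
  n <- length(sampleOrder)
  if (n < minSize) stop("fewer samples than 'minSize'")
  xo <- as.numeric(x[sampleOrder])
  Yo <- Y[, sampleOrder, drop = FALSE]
  okx <- !is.na(xo)
  L <- upper.tri(diag(n), diag = TRUE) * 1        # cumulative-sum operator
  if (all(okx) && !anyNA(Yo)) {
    ## complete data: sample counts and x-sums are shared by all genes
    N   <- matrix(seq_len(n), nrow(Yo), n, byrow = TRUE)
    sx  <- cumsum(xo); sxx <- cumsum(xo^2)
    Sx  <- matrix(sx, nrow(Yo), n, byrow = TRUE)
    Sxx <- matrix(sxx, nrow(Yo), n, byrow = TRUE)
    Sy  <- Yo %*% L
    Syy <- (Yo * Yo) %*% L
    Sxy <- Yo %*% (xo * L)
  } else {
    OK <- (!is.na(Yo)) & rep(okx, each = nrow(Yo))
    xv <- ifelse(okx, xo, 0)
    Yz <- Yo; Yz[!OK] <- 0
    Lx <- xv * L; Lxx <- xv^2 * L
    N   <- OK %*% L
    Sx  <- OK %*% Lx
    Sxx <- OK %*% Lxx
    Sy  <- Yz %*% L
    Syy <- (Yz * Yz) %*% L
    Sxy <- Yz %*% Lx
  }
  dx <- N * Sxx - Sx^2
  dy <- N * Syy - Sy^2
  ## sums of squares are nonnegative, so N*Sxx / N*Syy bound the scale of
  ## dx / dy and serve as relative zero-variance thresholds
  bad <- (N < minPairs) | (dx <= 1e-10 * (N * Sxx) + 1e-300) |
         (dy <= 1e-10 * (N * Syy) + 1e-300)
  r <- (N * Sxy - Sx * Sy) / sqrt(pmax(dx, 0) * pmax(dy, 0))
  r[bad] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  cols <- minSize:n
  r <- r[, cols, drop = FALSE]
  dimnames(r) <- list(rownames(Y), cols)
  r
}

## summed statistic from a per-pattern correlation matrix
spccFromPatternMatrix <- function(r) {
  nPat <- ncol(r)
  nEff <- rowSums(!is.na(r))
  s <- rowSums(r, na.rm = TRUE)
  s[nEff < ceiling(nPat / 2)] <- NA_real_
  list(sPCC = unname(s), nEff = unname(nEff))
}

#' Collapse probe-level values to gene level
#'
#' Averages probe-level correlation values into one value per gene to
#' normalise detection variation among the probes of the different array
#' platforms. The default flat mode takes the unweighted mean over all
#' defined probe values across all platforms; \code{mode = "platform"}
#' averages within each platform first and then across platforms.
#' Undefined (\code{NA}) probe values never enter the mean; genes with no
#' defined probe value are absent from the output.
#'
#' @param probeValues data.frame with columns \code{probe},
#'   \code{platform}, \code{value}.
#' @param probeMap data.frame from [readProbeGeneMap()].
#' @param mode \code{"probe"} (flat) or \code{"platform"}.
#' @return data.frame with columns \code{gene}, \code{value},
#'   \code{nProbes} (defined probe values used).
#' @export
collapseAndAverage <- function(probeValues, probeMap,
                               mode = c("probe", "platform")) {
  mode <- match.arg(mode)
  key <- paste(probeValues$platform, probeValues$probe)
  mkey <- paste(probeMap$platform, probeMap$probe)
  gene <- probeMap$gene[match(key, mkey)]
  keep <- !is.na(gene) & !is.na(probeValues$value)
  pv <- probeValues[keep, , drop = FALSE]
  gene <- gene[keep]
  if (!nrow(pv))
    return(data.frame(gene = character(), value = numeric(),
                      nProbes = integer()))
  nProbes <- as.integer(table(gene)[unique(gene)])
  if (mode == "probe") {
    val <- tapply(pv$value, gene, mean)
  } else {
    per <- tapply(pv$value, list(gene, pv$platform), mean)
    val <- rowMeans(per, na.rm = TRUE)
  }
  out <- data.frame(gene = names(val), value = as.numeric(val),
                    nProbes = as.integer(table(gene)[names(val)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Top positively or negatively correlated genes
#'
#' Extracts the strongest correlator gene list of one sign from a
#' correlation table: the default 2000 genes per sign covers roughly 10\%
#' of a genome-wide table and drops the weak bulk of correlations.
#'
#' @param x a \linkS4class{CorrelationTable}.
#' @param n list size (default 2000).
#' @param sign \code{"positive"} or \code{"negative"}.
#' @param method which column to rank (\code{"sPCC"}, \code{"dPCC"},
#'   \code{"rsPCC"}).
#' @return Character vector of gene symbols, strongest first; shorter than
#'   \code{n} (with a warning) when fewer genes of that sign exist.
#' @export
topCorrelators <- function(x, n = 2000L, sign = c("positive", "negative"),
                           method = "sPCC") {
  sign <- match.arg(sign)
  tab <- x@table
  if (!method %in% names(tab))
    stop(sprintf("column '%s' not present in this table", method))
  v <- tab[[method]]
  keep <- !is.na(v) & if (sign == "positive") v > 0 else v < 0
  tab <- tab[keep, , drop = FALSE]
  v <- tab[[method]]
  ord <- if (sign == "positive") order(-v, tab$gene) else order(v, tab$gene)
  genes <- tab$gene[ord]
  if (length(genes) < n)
    warning(sprintf("only %d %s correlators available (requested %d)",
                    length(genes), sign, n))
  head(genes, n)
}

#' Genome-wide correlation tables for a set of miRNA profiles
#'
#' End-to-end engine: for each miRNA profile, computes per-probe
#' correlations against every mRNA platform matrix — the titration
#' statistic \code{sPCC} over nested patterns, the plain \code{dPCC}, and
#' optionally the randomised control \code{rsPCC} — then collapses probes
#' to genes and averages across platforms.
#'
#' Random orderings for \code{rsPCC} are drawn once per miRNA (shared by
#' all platforms and genes) from \code{seed}, so a run is fully
#' reproducible.
#'
#' @param profiles list of \linkS4class{MiRNAProfile} (e.g. from
#'   [detectabilityFilter()]).
#' @param mrna list of \linkS4class{ExpressionMatrix} probe matrices, one
#'   per platform; sample ids must match the profiles.
#' @param probeMap data.frame from [readProbeGeneMap()].
#' @param methods subset of \code{c("spcc", "dpcc", "rspcc")}.
#' @param minSize smallest pattern size (default 30).
#' @param minPairs per-pattern minimum complete pairs (default 10).
#' @param nReps rsPCC replicates (default 10).
#' @param seed integer seed, required when \code{"rspcc"} is requested.
#' @param collapse probe collapsing mode, see [collapseAndAverage()].
#' @return Named list of \linkS4class{CorrelationTable}, one per profile.
#' @export
computeCorrelations <- function(profiles, mrna, probeMap,
                                methods = c("spcc", "dpcc"),
                                minSize = 30L, minPairs = 10L, nReps = 10L,
                                seed = NULL,
                                collapse = c("probe", "platform")) {
  collapse <- match.arg(collapse)
  methods <- match.arg(methods, c("spcc", "dpcc", "rspcc"),
                       several.ok = TRUE)
  if ("rspcc" %in% methods && is.null(seed))
    stop("'seed' is required for rsPCC")
  if (is(profiles, "MiRNAProfile")) profiles <- list(profiles)
  samples <- names(profileValues(profiles[[1]]))
  nPat <- length(samples) - minSize + 1L
  orderings <- NULL
  if ("rspcc" %in% methods)
    orderings <- withRNG(seed, lapply(seq_along(profiles), function(i)
      replicate(nReps, sample(samples), simplify = FALSE)))
  platforms <- unname(vapply(mrna, platformName, ""))
  out <- vector("list", length(profiles))
  names(out) <- vapply(profiles, mirnaName, "")
  for (i in seq_along(profiles)) {
    x <- profileValues(profiles[[i]])
    probe_res <- list()
    for (p in seq_along(mrna)) {
      Y <- exprValues(mrna[[p]])
      res <- data.frame(probe = rownames(Y), platform = platforms[p],
                        stringsAsFactors = FALSE)
      rmat <- patternPCCMatrix(x, Y, minSize, minPairs)
      if ("spcc" %in% methods)
        res$sPCC <- spccFromPatternMatrix(rmat)$sPCC
      if ("dpcc" %in% methods)
        res$dPCC <- unname(rmat[, ncol(rmat)])
      if ("rspcc" %in% methods) {
        rs <- matrix(NA_real_, nrow(Y), nReps)
        for (rep in seq_len(nReps)) {
          rrep <- patternPCCMatrix(x, Y, minSize, minPairs,
                                   sampleOrder = orderings[[i]][[rep]])
          rs[, rep] <- spccFromPatternMatrix(rrep)$sPCC
        }
        res$rsPCC <- rowMeans(rs, na.rm = TRUE)
        res$rsPCC[rowSums(!is.na(rs)) == 0L] <- NA_real_
      }
      probe_res[[p]] <- res
    }
    probe_res <- do.call(rbind, probe_res)
    cols <- intersect(c("sPCC", "dPCC", "rsPCC"), names(probe_res))
    gene_tabs <- lapply(cols, function(cc) {
      g <- collapseAndAverage(
        data.frame(probe = probe_res$probe, platform = probe_res$platform,
                   value = probe_res[[cc]], stringsAsFactors = FALSE),
        probeMap, mode = collapse)
      names(g)[names(g) == "value"] <- cc
      g
    })
    tab <- Reduce(function(a, b) merge(a, b[setdiff(names(b), "nProbes")],
                                       by = "gene", all = TRUE),
                  gene_tabs)
    tab <- tab[order(tab$gene), c("gene", cols, "nProbes")]
    rownames(tab) <- NULL
    out[[i]] <- CorrelationTable(mirnaName(profiles[[i]]), tab,
                                 minSize = minSize, nPatterns = nPat)
  }
  out
}
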