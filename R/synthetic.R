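## Synthetic steady-state panel generator. Emulates the structure of a
## 59-cell-line, multi-platform expression compendium with planted,
## dose-dependent miRNA effects so that every pipeline stage can be
## benchmarked against a known truth without any external data.

#' Configuration for the synthetic panel generator
#'
#' Defaults describe the emulated study conditions: 59 samples, four mRNA
#' array platforms with redundant probes, a panel of miRNAs gated by a
#' detection limit, and four kinds of planted structure:
#' \itemize{
#' \item \emph{titration-suppressed effector sets} — every detectable miRNA
#'   represses its own disjoint set of genes, but only in the samples where
#'   the miRNA is above its \code{suppressionQuantile} (default 0.9, i.e.
#'   the top ~6 of 59 samples): a switch-like drop of
#'   \code{suppressionDepth} log2 units (default 2, a fourfold change),
#'   optionally plus a linear ramp \code{suppressionSlope * (z - z_q)}.
#'   Dose-restricted suppression is what a titration-weighted statistic is
#'   designed to detect;
#' \item \emph{host-gene pairs} — genes co-transcribed with a miRNA
#'   (coefficient \code{hostAlpha});
#' \item \emph{HOX-like gene blocks} — blocks of genes co-expressed with
#'   one anchor miRNA;
#' \item \emph{signature blocks} — a latent epithelial factor loading
#'   epithelial genes positively and mesenchymal genes negatively, tied to
#'   planted epithelial/mesenchymal miRNA families that load the same
#'   factor.
#' }
#' Gene-level biological noise is Gaussian (\code{noiseSd}); each platform
#' adds independent probe noise (\code{probeNoiseSd}) on 1+Poisson
#' replicate probes per gene. miRNA values are log2 abundances
#' \code{mu + z} with per-miRNA means drawn from \code{exprMeanRange}
#' (decoy miRNAs from \code{decoyMeanRange} sit below
#' \code{detectionLimit} in most samples and fail the 30-of-59 gate).
#'
#' @param seed integer seed (required; the whole panel is a deterministic
#'   function of it).
#' @param nSamples,nPlatforms,nGenes panel dimensions.
#' @param nSuppressorMirnas detectable miRNAs, each with a planted
#'   effector set.
#' @param suppressedPerMirna effector genes per miRNA.
#' @param suppressionDepth,suppressionSlope,suppressionQuantile planted
#'   suppression shape (log2 units; quantile in (0,1)).
#' @param suppressionCoexpression baseline co-expression coefficient of
#'   effector genes with their miRNA (default 0; see
#'   [titrationBenchmarkPanel()]).
#' @param nDecoyMirnas low-expression miRNAs that fail the gate.
#' @param nHostPairs,hostAlpha host-gene pairs and their coefficient.
#' @param nHoxClusters,hoxClusterSize,hoxAlpha HOX-like blocks.
#' @param nEpithelialMirnas,nMesenchymalMirnas planted family sizes.
#' @param familyLoading loading of family miRNAs on the latent factor.
#' @param nEpithelialGenes,nMesenchymalGenes signature block sizes.
#' @param signatureGamma gene loading on the latent factor.
#' @param noiseSd,probeNoiseSd,probesPerGeneMean noise model.
#' @param exprMeanRange,decoyMeanRange,detectionLimit miRNA abundance model
#'   (log2 scale).
#' @return A config list of class \code{"titrationSynthConfig"}.
#' @export
syntheticConfig <- function(seed,
                            nSamples = 59L, nPlatforms = 4L,
                            nGenes = 2000L,
                            nSuppressorMirnas = 24L,
                            suppressedPerMirna = 60L,
                            suppressionDepth = 2,
                            suppressionSlope = 0,
                            suppressionQuantile = 0.9,
                            suppressionCoexpression = 0,
                            nDecoyMirnas = 6L,
                            nHostPairs = 10L, hostAlpha = 0.8,
                            nHoxClusters = 4L, hoxClusterSize = 6L,
                            hoxAlpha = 0.8,
                            nEpithelialMirnas = 5L,
                            nMesenchymalMirnas = 3L,
                            familyLoading = 0.85,
                            nEpithelialGenes = 25L,
                            nMesenchymalGenes = 25L,
                            signatureGamma = 1,
                            noiseSd = 1, probeNoiseSd = 0.25,
                            probesPerGeneMean = 1.5,
                            exprMeanRange = c(6, 8),
                            decoyMeanRange = c(2, 4),
                            detectionLimit = 5) {
  if (missing(seed)) stop("'seed' is required")
  cfg <- as.list(environment())
  planted <- with(cfg, nSuppressorMirnas * suppressedPerMirna + nHostPairs +
                       nHoxClusters * hoxClusterSize +
                       nEpithelialGenes + nMesenchymalGenes)
  if (planted > cfg$nGenes)
    stop(sprintf("planted blocks need %d genes but nGenes = %d",
                 planted, cfg$nGenes))
  if (cfg$suppressionQuantile <= 0 || cfg$suppressionQuantile >= 1)
    stop("'suppressionQuantile' must lie in (0, 1)")
  if (cfg$nHostPairs + cfg$nHoxClusters + cfg$nEpithelialMirnas +
      cfg$nMesenchymalMirnas > cfg$nSuppressorMirnas)
    stop("more miRNA roles than detectable miRNAs")
  structure(cfg, class = "titrationSynthConfig")
}

#' Generate a synthetic panel with planted truth
#'
#' Deterministically generates the panel described by a
#' [syntheticConfig()]: the miRNA expression matrix, one probe-level mRNA
#' matrix per platform, the probe-to-gene map, side tables (seed-family
#' table for the planted families, host pairs, HOX-like blocks, an EMT
#' signature), and the planted truth used by [truthReport()].
#'
#' Within the detectable miRNAs, roles overlap deliberately (as they do in
#' real panels): the first miRNAs form the epithelial family, the next the
#' mesenchymal family, then HOX anchors and host-gene miRNAs; every
#' detectable miRNA additionally owns a suppressed effector set.
#'
#' @param config a [syntheticConfig()].
#' @return List with elements \code{mirna}
#'   (\linkS4class{ExpressionMatrix}), \code{mrna} (list of per-platform
#'   \linkS4class{ExpressionMatrix}), \code{probeMap}, \code{seedTable},
#'   \code{hostPairs}, \code{hoxClusters}, \code{signature}
#'   (\linkS4class{GeneSignature}), and \code{truth}.
#' @export
generateSyntheticPanel <- function(config) {
  stopifnot(inherits(config, "titrationSynthConfig"))
  cfg <- config
  withRNG(cfg$seed, {
    n <- cfg$nSamples
    samples <- sprintf("S%02d", seq_len(n))
    nDet <- cfg$nSuppressorMirnas
    nMir <- nDet + cfg$nDecoyMirnas
    mirnas <- sprintf("syn-miR-%02d", seq_len(nMir))
    genes <- sprintf("SYNG%04d", seq_len(cfg$nGenes))

    ## roles among the detectable miRNAs
    iE <- seq_len(cfg$nEpithelialMirnas)
    iM <- cfg$nEpithelialMirnas + seq_len(cfg$nMesenchymalMirnas)
    iHox <- max(c(iE, iM, 0L)) + seq_len(cfg$nHoxClusters)
    iHost <- max(c(iHox, 0L)) + seq_len(cfg$nHostPairs)

    f <- rnorm(n)                               # latent epithelial factor
    Z <- matrix(rnorm(nMir * n), nMir, n, dimnames = list(mirnas, samples))
    lam <- cfg$familyLoading
    for (i in iE) Z[i, ] <- lam * f + sqrt(1 - lam^2) * rnorm(n)
    for (i in iM) Z[i, ] <- -lam * f + sqrt(1 - lam^2) * rnorm(n)

    mu <- c(runif(nDet, cfg$exprMeanRange[1], cfg$exprMeanRange[2]),
            runif(cfg$nDecoyMirnas, cfg$decoyMeanRange[1],
                  cfg$decoyMeanRange[2]))
    X <- Z + mu                                  # log2 abundance

    ## gene blocks
    gi <- 0L
    takeGenes <- function(k) {
      out <- genes[gi + seq_len(k)]; gi <<- gi + k; out
    }
    suppressed <- list()
    eff <- matrix(0, cfg$nGenes, n, dimnames = list(genes, samples))
    for (i in seq_len(nDet)) {
      gset <- takeGenes(cfg$suppressedPerMirna)
      z <- Z[i, ]
      zq <- quantile(z, cfg$suppressionQuantile, names = FALSE)
      act <- z > zq
      e <- -cfg$suppressionDepth * act -
        cfg$suppressionSlope * pmax(z - zq, 0) +
        cfg$suppressionCoexpression * z
      eff[gset, ] <- eff[gset, , drop = FALSE] +
        matrix(e, length(gset), n, byrow = TRUE)
      suppressed[[mirnas[i]]] <- gset
    }
    hostPairs <- data.frame(mirna = character(), host_gene = character(),
                            stringsAsFactors = FALSE)
    for (i in iHost) {
      g <- takeGenes(1L)
      eff[g, ] <- eff[g, ] + cfg$hostAlpha * Z[i, ]
      hostPairs <- rbind(hostPairs,
                         data.frame(mirna = mirnas[i], host_gene = g,
                                    stringsAsFactors = FALSE))
    }
    hoxClusters <- list(); hoxAnchors <- character()
    for (j in seq_len(cfg$nHoxClusters)) {
      i <- iHox[j]
      gset <- takeGenes(cfg$hoxClusterSize)
      eff[gset, ] <- eff[gset, , drop = FALSE] +
        matrix(cfg$hoxAlpha * Z[i, ], length(gset), n, byrow = TRUE)
      nm <- sprintf("HOXBLK%d", j)
      hoxClusters[[nm]] <- gset
      hoxAnchors[nm] <- mirnas[i]
    }
    eGenes <- takeGenes(cfg$nEpithelialGenes)
    mGenes <- takeGenes(cfg$nMesenchymalGenes)
    eff[eGenes, ] <- eff[eGenes, , drop = FALSE] +
      matrix(cfg$signatureGamma * f, length(eGenes), n, byrow = TRUE)
    eff[mGenes, ] <- eff[mGenes, , drop = FALSE] -
      matrix(cfg$signatureGamma * f, length(mGenes), n, byrow = TRUE)

    base <- rnorm(cfg$nGenes, 8, 1)
    G <- base + eff + matrix(rnorm(cfg$nGenes * n, 0, cfg$noiseSd),
                             cfg$nGenes, n)
    dimnames(G) <- list(genes, samples)

    ## probe-level platform matrices
    platforms <- sprintf("platform_%s", LETTERS[seq_len(cfg$nPlatforms)])
    mrna <- list(); maps <- list()
    for (p in platforms) {
      nprobe <- 1L + rpois(cfg$nGenes, max(cfg$probesPerGeneMean - 1, 0))
      probeGene <- rep(genes, nprobe)
      probeIds <- sprintf("%s_%s_p%d", p, probeGene,
                          sequence(nprobe))
      P <- G[probeGene, , drop = FALSE] +
        matrix(rnorm(length(probeIds) * n, 0, cfg$probeNoiseSd),
               length(probeIds), n)
      dimnames(P) <- list(probeIds, samples)
      mrna[[p]] <- ExpressionMatrix(P, platform = p,
                                    valueKind = "abundance")
      maps[[p]] <- data.frame(probe = probeIds, gene = probeGene,
                              platform = p, stringsAsFactors = FALSE)
    }
    probeMap <- do.call(rbind, maps)
    rownames(probeMap) <- NULL

    mirnaEM <- ExpressionMatrix(X, platform = "synthetic_mirna",
                                valueKind = "abundance")
    seedTable <- data.frame(
      mirna = mirnas[c(iE, iM)],
      family = rep(c("synFam-epithelial", "synFam-mesenchymal"),
                   c(length(iE), length(iM))),
      stringsAsFactors = FALSE)
    signature <- GeneSignature("synthetic-EMT",
                               c(eGenes, mGenes),
                               rep(c("up", "down"),
                                   c(length(eGenes), length(mGenes))))
    fingerprint <- sprintf("%d:%d:%d:%.6f", cfg$seed, nMir, cfg$nGenes,
                           sum(X))
    truth <- list(
      suppressed = suppressed,
      hostPairs = hostPairs,
      hoxClusters = hoxClusters,
      hoxAnchors = hoxAnchors,
      families = split(mirnas[c(iE, iM)],
                       rep(c("epithelial", "mesenchymal"),
                           c(length(iE), length(iM)))),
      signatureGenes = list(epithelial = eGenes, mesenchymal = mGenes),
      latent = setNames(f, samples),
      mirnas = mirnas, detectable = mirnas[seq_len(nDet)],
      config = cfg, fingerprint = fingerprint)
    list(mirna = mirnaEM, mrna = mrna, probeMap = probeMap,
         seedTable = seedTable, hostPairs = hostPairs,
         hoxClusters = hoxClusters, signature = signature, truth = truth)
  })
}

#' Noise-matched benchmark panel for prediction-strength curves
#'
#' Builds a single-platform panel whose planted miRNA-gene pairs carry a
#' \emph{graded} titration signal and a baseline co-expression term
#' calibrated (per miRNA, via the in-sample regression of the suppression
#' indicator on the miRNA) so that each pair's overall sample covariance
#' with the miRNA is exactly zero: the plain correlation of a planted pair
#' is pure noise, while the dose-restricted suppression remains visible to
#' a titration-weighted statistic. Suppression depth is graded linearly
#' across the pair list and exported as a prediction strength
#' (\code{total_context_score = -depth}), emulating a prediction table in
#' which stronger predictions are more strongly repressed targets.
#'
#' @param seed integer seed.
#' @param nMirnas miRNAs (default 10).
#' @param pairsPerMirna planted pairs per miRNA (default 50).
#' @param depthRange suppression depth range, strongest first at the top
#'   of the prediction ranking (default 0.4..1.8 log2 units, i.e. weak to
#'   about 3.5-fold; the upper end is kept below full penetrance so that
#'   even the strongest pairs occasionally show positive correlations and
#'   cumulative count ratios stay finite).
#' @param q suppression quantile (default 0.9).
#' @param nNoiseGenes additional unplanted genes.
#' @param noiseSd,probeNoiseSd noise model.
#' @return List with \code{mirna}, \code{mrna}, \code{probeMap},
#'   \code{predictions}, \code{truth}.
#' @export
titrationBenchmarkPanel <- function(seed, nMirnas = 10L,
                                    pairsPerMirna = 50L,
                                    depthRange = c(0.4, 1.8), q = 0.9,
                                    nNoiseGenes = 100L, noiseSd = 1,
                                    probeNoiseSd = 0.25) {
  withRNG(seed, {
    n <- 59L
    samples <- sprintf("S%02d", seq_len(n))
    mirnas <- sprintf("bench-miR-%02d", seq_len(nMirnas))
    nPairs <- nMirnas * pairsPerMirna
    genes <- sprintf("BENCH%04d", seq_len(nPairs + nNoiseGenes))
    Z <- matrix(rnorm(nMirnas * n), nMirnas, n,
                dimnames = list(mirnas, samples))
    ## pair j in the global ranking gets depth graded strongest -> weakest
    depth <- seq(depthRange[2], depthRange[1], length.out = nPairs)
    mirOf <- rep(seq_len(nMirnas), pairsPerMirna)   # round-robin
    G <- matrix(rnorm(length(genes) * n, 0, noiseSd), length(genes), n,
                dimnames = list(genes, samples))
    G <- G + rnorm(length(genes), 8, 1)
    for (i in seq_len(nMirnas)) {
      z <- Z[i, ]
      zq <- quantile(z, q, names = FALSE)
      act <- as.numeric(z > zq)
      bhat <- cov(z, act) / var(z)      # cancels the overall covariance
      idx <- which(mirOf == i)
      e <- outer(depth[idx], act) * (-1) + outer(depth[idx] * bhat, z)
      G[idx, ] <- G[idx, ] + e
    }
    P <- G + matrix(rnorm(length(G), 0, probeNoiseSd), nrow(G), ncol(G))
    rownames(P) <- sprintf("probe_%s", genes)
    probeMap <- data.frame(probe = rownames(P), gene = genes,
                           platform = "bench", stringsAsFactors = FALSE)
    predictions <- data.frame(mirna = mirnas[mirOf],
                              gene = genes[seq_len(nPairs)],
                              total_context_score = -depth,
                              stringsAsFactors = FALSE)
    list(mirna = ExpressionMatrix(Z + 7, platform = "bench_mirna",
                                  valueKind = "abundance"),
         mrna = list(ExpressionMatrix(P, platform = "bench",
                                      valueKind = "abundance")),
         probeMap = probeMap, predictions = predictions,
         truth = list(pairs = predictions, mirnas = mirnas, seed = seed))
  })
}

#' Recovery metrics against the planted truth
#'
#' Compares pipeline outputs with the planted truth of a synthetic panel:
#' per-method precision/recall of the suppressed effector genes within the
#' top-N negative correlator lists, the fraction of planted host pairs
#' with positive normalised sPCC, and (when a cluster assignment is given)
#' the purity of the planted miRNA families — the largest fraction of a
#' family's members sharing one cluster label — plus whether the two
#' families land in different clusters.
#'
#' @param truth the \code{truth} element of [generateSyntheticPanel()].
#' @param tables named list of \linkS4class{CorrelationTable} computed on
#'   the matching panel.
#' @param topN negative-list size used for recall (default: planted set
#'   size).
#' @param clusters optional data.frame from [functionalClusters()].
#' @param hostCutoff cutoff for the host-pair positive fraction.
#' @return List of metric tables; empty planted blocks yield \code{NA}
#'   metrics flagged as undefined rather than zero.
#' @export
truthReport <- function(truth, tables, topN = NULL, clusters = NULL,
                        hostCutoff = 0.2) {
  unknown <- setdiff(names(tables), truth$mirnas)
  if (length(unknown))
    stop("results do not match this panel; unknown miRNA(s): ",
         paste(head(unknown, 3), collapse = ", "))
  methods <- intersect(c("sPCC", "dPCC", "rsPCC"),
                       names(tables[[1]]@table))
  recovery <- NULL
  if (length(truth$suppressed)) {
    rows <- list()
    for (m in intersect(names(truth$suppressed), names(tables))) {
      planted <- truth$suppressed[[m]]
      nn <- if (is.null(topN)) length(planted) else topN
      for (meth in methods) {
        hits <- suppressWarnings(
          topCorrelators(tables[[m]], nn, "negative", meth))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, method = meth,
          recall = length(intersect(hits, planted)) / length(planted),
          precision = if (length(hits))
            length(intersect(hits, planted)) / length(hits) else NA,
          stringsAsFactors = FALSE)
      }
    }
    recovery <- do.call(rbind, rows)
  }
  hostFraction <- NA_real_
  if (nrow(truth$hostPairs) && "sPCC" %in% methods) {
    hp <- hostPairCorrelations(truth$hostPairs, tables,
                               cutoff = hostCutoff)
    s <- attr(hp, "summary")
    hostFraction <- unname(s["positive"] / sum(s))
  }
  purity <- NULL
  if (!is.null(clusters) && length(truth$families)) {
    lab <- setNames(as.character(clusters$cluster), clusters$mirna)
    fam <- lapply(truth$families, function(mm) lab[mm])
    purity <- data.frame(
      family = names(fam),
      purity = vapply(fam, function(l)
        max(table(factor(l))) / length(l), 0),
      modal = vapply(fam, function(l)
        names(which.max(table(factor(l)))), ""),
      stringsAsFactors = FALSE)
    attr(purity, "separated") <-
      length(unique(purity$modal)) == nrow(purity)
  }
  list(recovery = recovery, hostPositiveFraction = hostFraction,
       familyPurity = purity)
}
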