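## Shared fixtures: everything is generated in code at test time.

## independent brute-force titration oracle: sort, slice, sum plain cor()
oracle_spcc <- function(x, y, minSize = 30, minPairs = 10) {
  nm <- names(x)
  ord <- nm[order(is.na(x), -rank(x, ties.method = "min", na.last = "keep"),
                  nm)]
  total <- 0; nEff <- 0
  for (k in minSize:length(x)) {
    s <- ord[1:k]
    xs <- x[s]; ys <- y[s]
    ok <- !is.na(xs) & !is.na(ys)
    if (sum(ok) < minPairs) next
    if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0) next
    total <- total + stats::cor(xs[ok], ys[ok])
    nEff <- nEff + 1
  }
  nPat <- length(x) - minSize + 1
  if (nEff < ceiling(nPat / 2)) NA_real_ else total
}

named_samples <- function(n) sprintf("S%02d", seq_len(n))

rand_profile <- function(n = 59, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(stats::rnorm(n), named_samples(n))
}

small_synth_config <- function(seed, ...) {
  args <- list(seed = seed, nGenes = 250L, nPlatforms = 2L,
               nSuppressorMirnas = 6L, suppressedPerMirna = 10L,
               nDecoyMirnas = 2L, nHostPairs = 2L, nHoxClusters = 1L,
               hoxClusterSize = 3L, nEpithelialMirnas = 2L,
               nMesenchymalMirnas = 1L, nEpithelialGenes = 8L,
               nMesenchymalGenes = 8L)
  do.call(syntheticConfig, utils::modifyList(args, list(...)))
}

## acceptance-scale panels are expensive; share them across test blocks
.panel_cache <- new.env(parent = emptyenv())

cached_panel_run <- function(seed, methods = c("spcc", "dpcc", "rspcc")) {
  key <- paste(seed, paste(sort(methods), collapse = "+"))
  if (!is.null(.panel_cache[[key]])) return(.panel_cache[[key]])
  panel <- generateSyntheticPanel(syntheticConfig(seed = seed))
  prof <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 30)
  tabs <- computeCorrelations(prof, panel$mrna, panel$probeMap,
                              methods = methods, seed = seed + 10000L)
  .panel_cache[[key]] <- list(panel = panel, profiles = prof,
                              tables = tabs)
  .panel_cache[[key]]
}

expression_fixture <- function(nGenes = 20, n = 12, seed = 42,
                               platform = "fix") {
  set.seed(seed)
  m <- matrix(stats::rnorm(nGenes * n), nGenes, n,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              named_samples(n)))
  ExpressionMatrix(m, platform = platform)
}
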