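test_that("the generator is a deterministic function of its seed", {
  p1 <- generateSyntheticPanel(small_synth_config(seed = 5))
  p2 <- generateSyntheticPanel(small_synth_config(seed = 5))
  p3 <- generateSyntheticPanel(small_synth_config(seed = 6))
  expect_identical(exprValues(p1$mirna), exprValues(p2$mirna))
  expect_identical(exprValues(p1$mrna[[1]]), exprValues(p2$mrna[[1]]))
  expect_false(identical(exprValues(p1$mirna), exprValues(p3$mirna)))
  expect_identical(p1$truth$fingerprint, p2$truth$fingerprint)
  ## generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generateSyntheticPanel(small_synth_config(seed = 9)))
  expect_identical(rnorm(1), before)
})

test_that("config validation rejects inconsistent block sizes", {
  expect_error(syntheticConfig(), "seed")
  expect_error(syntheticConfig(seed = 1, nGenes = 100L), "planted")
  expect_error(syntheticConfig(seed = 1, suppressionQuantile = 1),
               "Quantile")
  expect_error(small_synth_config(seed = 1, nHostPairs = 10L), "roles")
})

test_that("detectability masks respect the limit exactly", {
  panel <- generateSyntheticPanel(small_synth_config(seed = 11))
  prof <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 2)
  v <- exprValues(panel$mirna)
  for (m in names(prof))
    expect_identical(unname(detectableMask(prof[[m]])),
                     unname(!is.na(v[m, ]) & v[m, ] >= 5))
  ## decoy miRNAs sit below the limit and fail the 30-of-59 gate
  gated <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 30)
  expect_identical(names(gated), panel$truth$detectable)
})

test_that("noise-free planted effects reach their deterministic limits", {
  ## linear suppression over nearly the whole range + zero noise:
  ## the planted gene is an exact global anti-correlate of its miRNA
  cfg <- small_synth_config(seed = 21, noiseSd = 0, probeNoiseSd = 0,
                            suppressionDepth = 0,
                            suppressionSlope = 1,
                            suppressionQuantile = 1 / 59)
  panel <- generateSyntheticPanel(cfg)
  m <- panel$truth$detectable[6]      # outside the co-expressed families
  g <- panel$truth$suppressed[[m]][1]
  x <- exprValues(panel$mirna)[m, ]
  probe <- panel$probeMap$probe[panel$probeMap$gene == g][1]
  y <- exprValues(panel$mrna[[1]])[probe, ]
  ord <- names(sort(x, decreasing = TRUE))
  ## suppression is active above the empirical quantile; in the noise-free
  ## ramp every active sample is exactly linear in the miRNA
  act <- sum(x > stats::quantile(x, 1 / 59))
  expect_identical(act, 58L)
  expect_equal(stats::cor(x[ord[1:58]], y[ord[1:58]]), -1,
               tolerance = 1e-12)
  ## noise-free host gene is a perfect correlate
  hostm <- panel$truth$hostPairs$mirna[1]
  hostg <- panel$truth$hostPairs$host_gene[1]
  hp <- panel$probeMap$probe[panel$probeMap$gene == hostg][1]
  expect_equal(directPCC(exprValues(panel$mirna)[hostm, ],
                         exprValues(panel$mrna[[1]])[hp, ]), 1,
               tolerance = 1e-12)
})

test_that("with a near-zero suppression quantile the two methods agree (ramp limit)", {
  cfg <- small_synth_config(seed = 22, noiseSd = 0.05, probeNoiseSd = 0,
                            suppressionDepth = 0, suppressionSlope = 1,
                            suppressionQuantile = 1 / 59)
  panel <- generateSyntheticPanel(cfg)
  prof <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 30)
  m <- panel$truth$detectable[6]
  tabs <- computeCorrelations(prof[m], panel$mrna, panel$probeMap,
                              methods = c("spcc", "dpcc"))
  tab <- as.data.frame(tabs[[m]])
  planted <- panel$truth$suppressed[[m]]
  rank_s <- rank(tab$sPCC)[match(planted, tab$gene)]
  rank_d <- rank(tab$dPCC)[match(planted, tab$gene)]
  ## global linear suppression: both methods put the planted genes at the
  ## extreme negative end
  expect_true(all(rank_s <= length(planted)))
  expect_true(all(rank_d <= length(planted)))
})

test_that("truth report gives perfect recall in the noise-free limit and checks provenance", {
  cfg <- small_synth_config(seed = 23, noiseSd = 0, probeNoiseSd = 0)
  panel <- generateSyntheticPanel(cfg)
  prof <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 30)
  m <- panel$truth$detectable[6]
  tabs <- computeCorrelations(prof[m], panel$mrna, panel$probeMap,
                              methods = c("spcc", "dpcc"))
  rep <- truthReport(panel$truth, tabs)
  expect_equal(rep$recovery$recall[rep$recovery$method == "sPCC"], 1)
  ## results from a different panel are rejected
  bad <- tabs
  names(bad) <- "not-a-mirna"
  expect_error(truthReport(panel$truth, bad), "do not match")
  ## empty planted truth yields undefined metrics, not zeros
  empty <- panel$truth
  empty$suppressed <- list()
  empty$hostPairs <- empty$hostPairs[0, ]
  rep2 <- truthReport(empty, tabs)
  expect_null(rep2$recovery)
  expect_true(is.na(rep2$hostPositiveFraction))
})

test_that("benchmark panel pairs have vanishing overall covariance but graded depth", {
  bench <- titrationBenchmarkPanel(seed = 3, nMirnas = 4L,
                                   pairsPerMirna = 25L, nNoiseGenes = 10L,
                                   noiseSd = 0, probeNoiseSd = 0)
  Z <- exprValues(bench$mirna)
  P <- exprValues(bench$mrna[[1]])
  pred <- bench$predictions
  for (i in c(1, 50, 100)) {
    z <- Z[pred$mirna[i], ]
    y <- P[paste0("probe_", pred$gene[i]), ]
    expect_lt(abs(stats::cov(z, y)), 1e-10)
  }
  ## prediction scores are the (negated) planted depths, strongest first
  expect_true(all(diff(pred$total_context_score) >= 0))
})
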