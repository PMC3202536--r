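mk_table <- function(genes, values, nPatterns = 30L) {
  CorrelationTable("m", data.frame(gene = genes, sPCC = values,
                                   nProbes = 1L, stringsAsFactors = FALSE),
                   minSize = 30L, nPatterns = nPatterns)
}

test_that("threshold counting is strict and ignores absent genes", {
  sig <- GeneSignature("s", c("A", "B"), c("up", "down"))
  ct <- mk_table(c("A", "B", "C"), c(5, -5, 9))
  cnt <- countSignatureCorrelators(sig, ct, "threshold", cutoff = 1)
  expect_identical(cnt, c(posUp = 1L, negUp = 0L, posDown = 0L,
                          negDown = 1L))
  ## boundary: a value exactly at the cutoff is uncounted
  ct2 <- mk_table(c("A", "B"), c(1, -1))
  expect_identical(sum(countSignatureCorrelators(sig, ct2, cutoff = 1)), 0L)
  empty <- GeneSignature("none", character())
  expect_identical(sum(countSignatureCorrelators(empty, ct)), 0L)
})

test_that("counting agrees with a brute-force scan in both modes", {
  set.seed(41)
  genes <- sprintf("G%02d", 1:50)
  vals <- rnorm(50, sd = 3)
  ct <- mk_table(genes, vals)
  sgenes <- sample(genes, 10)
  sdir <- sample(c("up", "down"), 10, replace = TRUE)
  sig <- GeneSignature("s", sgenes, sdir)
  cnt <- countSignatureCorrelators(sig, ct, "threshold", cutoff = 1)
  v <- stats::setNames(vals, genes)[sgenes]
  expect_identical(cnt[["posUp"]], sum(v > 1 & sdir == "up"))
  expect_identical(cnt[["negUp"]], sum(v < -1 & sdir == "up"))
  expect_identical(cnt[["posDown"]], sum(v > 1 & sdir == "down"))
  expect_identical(cnt[["negDown"]], sum(v < -1 & sdir == "down"))
  cnt2 <- countSignatureCorrelators(sig, ct, "topn", n = 5)
  topPos <- genes[order(-vals)][1:5]; topNeg <- genes[order(vals)][1:5]
  expect_identical(cnt2[["posUp"]], sum(sgenes %in% topPos & sdir == "up"))
  expect_identical(cnt2[["negDown"]],
                   sum(sgenes %in% topNeg & sdir == "down"))
})

test_that("net score and E/M factor reproduce their defining arithmetic", {
  expect_identical(netScore(c(posUp = 40L, negUp = 10L, posDown = 0L,
                              negDown = 0L)), 30L)
  expect_identical(netScore(c(posUp = 7L, negUp = 7L, posDown = 2L,
                              negDown = 2L)), 0L)
  expect_identical(emFactor(c(posUp = 7L, negUp = 2L, posDown = 1L,
                              negDown = 5L)), 9L)
  expect_identical(emFactor(c(posUp = 0L, negUp = 0L, posDown = 0L,
                              negDown = 0L)), 0L)
  ## fully epithelial miRNA attains the |E|+|M| bound
  expect_identical(emFactor(c(posUp = 86L, negUp = 0L, posDown = 0L,
                              negDown = 59L)), 145L)
})

test_that("E/M factor flips sign when the E and M labels swap", {
  set.seed(43)
  for (i in 1:50) {
    cc <- sample(0:10, 4, replace = TRUE)
    counts <- c(posUp = cc[1], negUp = cc[2], posDown = cc[3],
                negDown = cc[4])
    labelSwap <- c(posUp = cc[3], negUp = cc[4], posDown = cc[1],
                   negDown = cc[2])
    expect_identical(emFactor(counts), -emFactor(labelSwap))
    ## swapping labels and correlation signs together is a no-op
    doubleSwap <- c(posUp = cc[4], negUp = cc[3], posDown = cc[2],
                    negDown = cc[1])
    expect_identical(emFactor(counts), emFactor(doubleSwap))
  }
})

test_that("ranking is descending with ties broken by name", {
  expect_identical(rankByFactor(c(a = 3, b = -1, c = 3)), c("a", "c", "b"))
  expect_identical(rankByFactor(c(solo = 1)), "solo")
})

test_that("cluster enrichment matches the exact rank-sum tail and tiers correctly", {
  clusters <- data.frame(
    mirna = sprintf("m%02d", 1:25),
    cluster = factor(rep(c("I", "II"), c(5, 20)), levels = c("I", "II")))
  scores <- stats::setNames(c(101:105, 1:20), clusters$mirna)
  enr <- clusterEnrichment(scores, clusters)
  ## complete separation of 5 vs 20: the most extreme two-sided p
  expect_equal(enr$p[enr$cluster == "I"], 2 / choose(25, 5),
               tolerance = 1e-12)
  ## identical scores everywhere: no enrichment signal at all
  flat <- stats::setNames(rep(1, 25), clusters$mirna)
  expect_equal(clusterEnrichment(flat, clusters)$p, c(1, 1))
  ## p values are invariant to monotone transforms of the scores
  enr2 <- clusterEnrichment(exp(scores / 50), clusters)
  expect_equal(enr$p, enr2$p)
  ## tier labelling
  expect_identical(miRtitrate:::significanceTier(0.005), "0.01")
  expect_identical(miRtitrate:::significanceTier(5e-5), "0.0001")
  expect_identical(miRtitrate:::significanceTier(5e-4), "0.001")
  expect_identical(miRtitrate:::significanceTier(0.5), "ns")
})

test_that("host-pair summary counts are strict at the cutoff and flag absences", {
  tabs <- list(
    m1 = mk_table(c("H1", "X"), c(6, 0)),        # 6/30 = 0.2 exactly
    m2 = mk_table(c("H2", "X"), c(12, 0)),       # 0.4
    m3 = mk_table(c("X"), c(0)))
  pairs <- data.frame(mirna = c("m1", "m2", "m3"),
                      host_gene = c("H1", "H2", "H3"))
  hp <- hostPairCorrelations(pairs, tabs, cutoff = 0.2)
  s <- attr(hp, "summary")
  expect_identical(unname(s["positive"]), 1L)     # only the 0.4 pair
  expect_identical(unname(s["uncounted"]), 1L)    # the boundary pair
  expect_identical(hp$status[3], "gene_missing")
  expect_equal(hp$sPCCnorm[1], 0.2)
})

test_that("cumulative block scores add member values and rank the anchor", {
  tabs <- list(
    mA = mk_table(c("h1", "h2", "h3"), c(2, 3, -1)),
    mB = mk_table(c("h1", "h2", "h3"), c(0.1, -0.2, 0.3)))
  hox <- hoxCumulativeScores(list(BLK = c("h1", "h2", "h3")), tabs)
  expect_equal(hox$score[hox$mirna == "mA"], 4)
  expect_identical(hox$rank[hox$mirna == "mA"], 1L)
  expect_warning(hoxCumulativeScores(list(EMPTY = character()), tabs),
                 "empty")
})
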