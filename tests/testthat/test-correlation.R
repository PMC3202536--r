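test_that("pearsonCC matches hand-computed values and sentinels", {
  expect_equal(pearsonCC(c(1, 2, 3), c(2, 4, 6), minPairs = 3), 1)
  expect_equal(pearsonCC(c(1, 2, 3), c(3, 2, 1), minPairs = 3), -1)
  expect_equal(pearsonCC(c(1, 2, 3, 4), c(1, 3, 2, 4), minPairs = 3), 0.8)
  ## missing pairs are dropped; too few pairs or flat vectors are NA
  expect_equal(pearsonCC(c(1, 2, 3, NA), c(1, 3, 2, 9), minPairs = 3), 0.5)
  expect_true(is.na(pearsonCC(c(1, 2, NA), c(1, 2, 3), minPairs = 3)))
  expect_true(is.na(pearsonCC(c(1, 1, 1), c(1, 2, 3), minPairs = 3)))
})

test_that("pattern series has the printed shape: 59 samples give 30 nested patterns", {
  x <- rand_profile(59, seed = 1)
  ps <- buildPatterns(x, 30)
  expect_identical(length(ps), 30L)
  sizes <- vapply(1:30, function(k) length(patternSamples(ps, k)), 0L)
  expect_identical(sizes, 30:59)
  ## nested, growing by exactly one sample, starting at the top 30
  for (k in 2:30)
    expect_identical(setdiff(patternSamples(ps, k - 1),
                             patternSamples(ps, k)), character(0))
  top <- names(sort(x, decreasing = TRUE))[1:30]
  expect_setequal(patternSamples(ps, 1), top)
  expect_identical(length(buildPatterns(rand_profile(31), 30)), 2L)
  expect_identical(length(buildPatterns(rand_profile(30), 30)), 1L)
  expect_error(buildPatterns(rand_profile(29), 30), "at least 30")
})

test_that("ties in miRNA expression are broken by sample id, deterministically", {
  x <- stats::setNames(c(5, 5, 1, 5, 0), c("b", "a", "z", "c", "d"))
  ps <- buildPatterns(x, 2)
  expect_identical(ps@sampleOrder, c("a", "b", "c", "z", "d"))
})

test_that("degenerate one-pattern series reduces the sum to the plain correlation", {
  x <- rand_profile(30, seed = 2)
  y <- rand_profile(30, seed = 3)
  s <- summedPCC(x, y, minSize = 30)
  expect_equal(as.numeric(s), pearsonCC(x, y), tolerance = 1e-12)
})

test_that("perfect correlates sum to the pattern count with either sign", {
  x <- rand_profile(59, seed = 4)
  expect_equal(as.numeric(summedPCC(x, x, minSize = 30)), 30)
  expect_equal(as.numeric(summedPCC(x, -2 * x + 7, minSize = 30)), -30)
})

test_that("summed statistic equals the brute-force sort-slice-sum oracle", {
  set.seed(11)
  for (i in 1:100) {
    x <- rand_profile(59)
    y <- rand_profile(59)
    if (i %% 4 == 0) y[sample(59, 8)] <- NA
    if (i %% 7 == 0) x[sample(59, 5)] <- NA
    s <- as.numeric(summedPCC(x, y, minSize = 30))
    o <- oracle_spcc(x, y, 30)
    expect_lt(abs(s - o), 1e-10)
  }
})

test_that("vectorised pattern engine agrees with the scalar path on missing data", {
  set.seed(21)
  x <- rand_profile(40)
  x[c(3, 9)] <- NA
  Y <- matrix(rnorm(40 * 30), 30, 40,
              dimnames = list(sprintf("g%02d", 1:30), names(x)))
  Y[sample(length(Y), 60)] <- NA
  Y[5, ] <- 1                       # flat gene -> all-sentinel row
  r <- patternPCCMatrix(x, Y, minSize = 20, minPairs = 10)
  expect_identical(dim(r), c(30L, 21L))
  fast <- rowSums(r, na.rm = TRUE)
  for (g in c(1:6, 30)) {
    slow <- summedPCC(x, Y[g, ], minSize = 20, minPairs = 10)
    if (is.na(slow)) expect_true(all(is.na(r[g, ])) ||
                                   sum(!is.na(r[g, ])) < ceiling(21 / 2))
    else expect_lt(abs(fast[g] - slow), 1e-9)
  }
  expect_true(all(is.na(r[5, ])))
})

test_that("summed statistic is affine-invariant and antisymmetric under negation", {
  set.seed(31)
  for (i in 1:20) {
    x <- rand_profile(45)
    y <- rand_profile(45)
    s <- as.numeric(summedPCC(x, y, minSize = 30))
    expect_equal(as.numeric(summedPCC(2.5 * x + 1, 0.1 * y - 4,
                                      minSize = 30)), s,
                 tolerance = 1e-9)
    expect_equal(as.numeric(summedPCC(x, -y, minSize = 30)), -s,
                 tolerance = 1e-9)
    expect_lte(abs(s), 45 - 30 + 1)
  }
})

test_that("randomised control defaults to 10 averaged replicates and is seeded", {
  x <- rand_profile(59, seed = 5)
  y <- rand_profile(59, seed = 6)
  r1 <- randomizedSPCC(x, y, seed = 99)
  r2 <- randomizedSPCC(x, y, seed = 99)
  expect_identical(attr(r1, "nRepsUsed"), 10L)
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_false(identical(as.numeric(r1),
                         as.numeric(randomizedSPCC(x, y, seed = 100))))
  ## the true-expression ordering reproduces the titration statistic exactly
  ident <- randomizedSPCC(x, y,
                          orderings = list(buildPatterns(x, 30)@sampleOrder))
  expect_equal(as.numeric(ident), as.numeric(summedPCC(x, y, minSize = 30)))
  ## zero-variance gene is the sentinel
  expect_true(is.na(randomizedSPCC(x, stats::setNames(rep(1, 59), names(x)),
                                   seed = 1)))
})

test_that("plain correlation honours the minimum-pair rule at the boundary", {
  set.seed(8)
  x <- rand_profile(59)
  y <- rand_profile(59)
  y[41:59] <- NA                     # 40 complete pairs
  expect_false(is.na(directPCC(x, y, minPairs = 30)))
  expect_true(is.na(directPCC(x, y, minPairs = 50)))
  expect_equal(directPCC(x, y, minPairs = 30),
               stats::cor(x[1:40], y[1:40]))
})

test_that("probe collapsing averages defined values and drops empty genes", {
  map <- data.frame(probe = c("p1", "p2", "p3", "q1"),
                    gene = c("A", "A", "A", "B"),
                    platform = c("x", "y", "y", "x"))
  pv <- data.frame(probe = c("p1", "p2", "p3", "q1"),
                   platform = c("x", "y", "y", "x"),
                   value = c(0.4, NA, 0.8, NA))
  out <- collapseAndAverage(pv, map)
  expect_identical(out$gene, "A")
  expect_equal(out$value, 0.6)
  expect_identical(out$nProbes, 2L)
  ## two probes on two platforms
  pv2 <- data.frame(probe = c("p1", "p2"), platform = c("x", "y"),
                    value = c(0.4, 0.6))
  expect_equal(collapseAndAverage(pv2, map)$value, 0.5)
  ## platform-first averaging weights platforms, not probes
  pv3 <- data.frame(probe = c("p1", "p2", "p3"),
                    platform = c("x", "y", "y"),
                    value = c(0.0, 0.4, 0.8))
  expect_equal(collapseAndAverage(pv3, map, mode = "probe")$value, 0.4)
  expect_equal(collapseAndAverage(pv3, map, mode = "platform")$value, 0.3)
})

test_that("identical tables replicated across platforms collapse to the single-platform result", {
  set.seed(13)
  map1 <- data.frame(probe = sprintf("p%d", 1:6),
                     gene = rep(c("A", "B", "C"), each = 2),
                     platform = "x")
  vals <- rnorm(6)
  pv1 <- data.frame(probe = map1$probe, platform = "x", value = vals)
  one <- collapseAndAverage(pv1, map1)
  map4 <- do.call(rbind, lapply(c("x", "y", "z", "w"), function(p)
    transform(map1, platform = p)))
  pv4 <- do.call(rbind, lapply(c("x", "y", "z", "w"), function(p)
    transform(pv1, platform = p)))
  four <- collapseAndAverage(pv4, map4)
  expect_equal(four$value, one$value)
})

test_that("top correlator lists are signed, ordered and warn when short", {
  tab <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    sPCC = c(3, 2, 1, -1, -2), nProbes = 1L)
  ct <- CorrelationTable("m", tab, minSize = 30, nPatterns = 30)
  expect_identical(topCorrelators(ct, 2, "positive"), c("a", "b"))
  expect_identical(topCorrelators(ct, 2, "negative"), c("e", "d"))
  expect_warning(all_pos <- topCorrelators(ct, 10, "positive"), "only 3")
  expect_identical(all_pos, c("a", "b", "c"))
})

test_that("engine output matches per-gene recomputation end to end", {
  cfg <- small_synth_config(seed = 77)
  panel <- generateSyntheticPanel(cfg)
  prof <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 30)
  tabs <- computeCorrelations(prof[1], panel$mrna, panel$probeMap,
                              methods = c("spcc", "dpcc"))
  ct <- as.data.frame(tabs[[1]])
  x <- profileValues(prof[[1]])
  for (g in sample(ct$gene, 4)) {
    vals_s <- c(); vals_d <- c()
    for (p in seq_along(panel$mrna)) {
      Y <- exprValues(panel$mrna[[p]])
      probes <- panel$probeMap$probe[panel$probeMap$gene == g &
        panel$probeMap$platform == platformName(panel$mrna[[p]])]
      for (pb in probes) {
        vals_s <- c(vals_s, as.numeric(summedPCC(x, Y[pb, ], minSize = 30)))
        vals_d <- c(vals_d, directPCC(x, Y[pb, ]))
      }
    }
    expect_equal(ct$sPCC[ct$gene == g], mean(vals_s, na.rm = TRUE),
                 tolerance = 1e-9)
    expect_equal(ct$dPCC[ct$gene == g], mean(vals_d, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})
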