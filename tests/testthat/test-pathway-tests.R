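test_that("gene t statistics match the textbook formula and handle degenerate genes", {
  ge <- randomExpression(p = 10, n1 = 5, n2 = 5, seed = 31)
  t <- geneTStatistics(ge)
  v <- exprValues(ge)
  for (i in c(1, 4, 10)) {
    expect_equal(unname(t[i]), directT(v[i, 1:5], v[i, 6:10]),
                 tolerance = 1e-12)
  }

  # identical group values: t = 0; zero pooled variance: 0 with warning
  vz <- rbind(rep(1, 6), c(0, 0, 0, 1, 1, 1))
  gz <- groupedExpression(vz, c("flat", "step"),
                          rep(c("control", "treatment"), each = 3))
  expect_warning(tz <- geneTStatistics(gz), "zero pooled variance")
  expect_equal(unname(tz), c(0, 0))
})

test_that("sum of t-square composes from the gene statistics", {
  ge <- randomExpression(p = 8, n1 = 4, n2 = 6, seed = 32)
  t <- geneTStatistics(ge)
  set <- rownames(ge)[c(2, 5, 7)]
  expect_equal(sumTSquare(ge, set), sum(t[set]^2))
  expect_error(sumTSquare(ge, character()), "non-empty")
  expect_error(sumTSquare(ge, "missing_gene"), "absent")
  # invariant under member reordering
  expect_equal(sumTSquare(ge, rev(set)), sumTSquare(ge, set))
})

test_that("pooled covariance weights the group covariances by their df", {
  ge <- randomExpression(p = 4, n1 = 5, n2 = 9, seed = 33)
  v <- exprValues(ge)
  s1 <- cov(t(v[, 1:5])); s2 <- cov(t(v[, 6:14]))
  expect_equal(pooledCovariance(ge, rownames(ge)),
               (4 * s1 + 8 * s2) / 12, tolerance = 1e-12)

  # equal group sizes: plain average; identical groups: that covariance
  ge2 <- randomExpression(p = 3, n1 = 6, n2 = 6, seed = 34)
  v2 <- exprValues(ge2)
  expect_equal(pooledCovariance(ge2, rownames(ge2)),
               (cov(t(v2[, 1:6])) + cov(t(v2[, 7:12]))) / 2)
  same <- groupedExpression(cbind(v2[, 1:6], v2[, 1:6]), rownames(ge2),
                            rep(c("control", "treatment"), each = 6))
  expect_equal(pooledCovariance(same, rownames(ge2)), cov(t(v2[, 1:6])))
})

test_that("shrinkage precision is sane in the univariate, null and large-n regimes", {
  # p = 1: precision is 1 / pooled variance
  ge <- randomExpression(p = 3, n1 = 10, n2 = 10, seed = 35)
  est <- shrinkagePrecision(ge, rownames(ge)[1])
  expect_equal(est$precision[1, 1],
               1 / pooledCovariance(ge, rownames(ge)[1])[1, 1])

  # exactly zero sample correlations: intensity defined as 1
  v <- rbind(c(1, -1, 1, -1, 2, -2, 2, -2),
             c(1, 1, -1, -1, 2, 2, -2, -2))   # orthogonal after centering
  gz <- groupedExpression(v, c("a", "b"),
                          rep(c("control", "treatment"), each = 4))
  estz <- shrinkagePrecision(gz, c("a", "b"))
  expect_equal(estz$shrinkageIntensity, 1)
  expect_equal(estz$precision[1, 2], 0)

  # diagonal truth at large n: estimate approaches the true inverse
  set.seed(36)
  big <- groupedExpression(matrix(rnorm(10 * 4000), 10, 4000),
                           sprintf("g%02d", 1:10),
                           rep(c("control", "treatment"), each = 2000))
  estb <- shrinkagePrecision(big, rownames(big))
  expect_lt(max(abs(estb$precision - diag(10))), 0.05)

  # constant genes are named in the error
  vc <- rbind(rep(3, 8), rnorm(8))
  gc <- groupedExpression(vc, c("const", "ok"),
                          rep(c("control", "treatment"), each = 4))
  expect_error(shrinkagePrecision(gc, c("const", "ok")), "const")
})

test_that("Hotelling T2 reduces to the squared t and is non-negative", {
  # equal group means exactly: statistic 0
  v <- matrix(rnorm(3 * 4), 3, 4)
  ge0 <- groupedExpression(cbind(v, v), paste0("g", 1:3),
                           rep(c("control", "treatment"), each = 4))
  expect_equal(hotellingT2(ge0, paste0("g", 1:3)), 0, tolerance = 1e-20)

  # p = 1 with shrinkage bypassed equals the squared pooled t
  for (seed in 1:20) {
    ge <- randomExpression(p = 1, n1 = 4, n2 = 7, seed = seed)
    t2 <- hotellingT2(ge, rownames(ge), shrinkageIntensity = 0)
    expect_equal(t2, unname(suppressWarnings(geneTStatistics(ge))^2),
                 tolerance = 1e-10)
  }

  # quadratic form in an SPD matrix: always >= 0
  for (seed in 21:30) {
    ge <- randomExpression(p = 6, n1 = 5, n2 = 5, seed = seed)
    expect_gte(hotellingT2(ge, rownames(ge)), 0)
  }
})

test_that("enrichment score equals the brute-force running sum on all membership patterns", {
  stats <- c(6, 5, 4, 3, 2, 1)
  for (code in 1:62) {                     # every pattern except none/all
    member <- as.logical(bitwAnd(code, 2^(0:5)))
    for (q in c(0, 1)) {
      expect_equal(gseaEnrichmentScore(stats, member, q),
                   bruteForceES(stats, member, q),
                   info = sprintf("pattern %d, q %d", code, q))
    }
  }
  # named cases: members at ranks {2,3,5} handled by the loop above;
  # full set climbs to exactly 1; single member ranked first with q = 0
  expect_equal(gseaEnrichmentScore(stats, rep(TRUE, 6), 1), 1)
  expect_equal(gseaEnrichmentScore(c(5, 4, 3, 2, 1),
                                   c(TRUE, FALSE, FALSE, FALSE, FALSE), 0), 1)
  expect_error(gseaEnrichmentScore(c(1, 0, 0), c(FALSE, TRUE, TRUE), 1),
               "zero")
  expect_error(gseaEnrichmentScore(c(1, 2, 3), c(TRUE, FALSE, TRUE), 1),
               "decreasing")
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(40)
  for (rep in 1:20) {
    stats <- sort(rnorm(50), decreasing = TRUE)
    pos <- sort(sample.int(50, 8))
    member <- seq_len(50) %in% pos
    ours <- gseaEnrichmentScore(stats, member, 1)
    theirs <- fgsea::calcGseaStat(stats, pos, gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("sample-label permutation p-values match exhaustive enumeration", {
  ge <- randomExpression(p = 5, n1 = 3, n2 = 3, seed = 41)
  set <- rownames(ge)

  exact <- sampleLabelPermutationP(ge, set, "sumTSquare", exact = TRUE)
  expect_equal(exact$nPermutations, 20L)

  # independent enumeration over the 20 distinct splits
  v <- exprValues(ge)
  splits <- combn(6, 3)
  stats <- apply(splits, 2, function(i1) {
    i2 <- setdiff(1:6, i1)
    sum(vapply(1:5, function(g) directT(v[g, i1], v[g, i2])^2, numeric(1)))
  })
  obs <- stats[1]                          # identity split is column 1
  expect_equal(exact$statistic, obs, tolerance = 1e-12)
  expect_equal(exact$pValue, (1 + sum(stats >= obs)) / 21)

  # heavily sampled estimate agrees with the exhaustive value
  approx <- sampleLabelPermutationP(ge, set, "sumTSquare", B = 4000,
                                    seed = 5)
  expect_equal(approx$pValue, sum(stats >= obs) / 20, tolerance = 0.05)
})

test_that("permutation p-value extremes behave as the add-one estimator dictates", {
  # statistic constant under all permutations -> p = 1
  ge <- randomExpression(p = 3, n1 = 3, n2 = 3, seed = 42)
  res <- sampleLabelPermutationP(ge, rownames(ge),
                                 statistic = function(v, i1, i2) 1,
                                 B = 50, seed = 1)
  expect_equal(res$pValue, 1)

  # observed beats every permutation -> p = 1/(B+1); group sizes large
  # enough that no random permutation reproduces the original labeling
  set.seed(43)
  v <- rbind(c(rnorm(10), rnorm(10) + 50))
  gbig <- groupedExpression(v, "g1",
                            rep(c("control", "treatment"), each = 10))
  res2 <- sampleLabelPermutationP(gbig, "g1", "sumTSquare", B = 50, seed = 1)
  expect_equal(res2$pValue, 1 / 51)
})

test_that("gene-label permutation p matches exhaustive subset enumeration", {
  stats <- c(2.5, 1.2, -0.3, -1.1, 0.4)
  names(stats) <- paste0("g", 1:5)
  ranked <- sort(stats, decreasing = TRUE)
  obs <- gseaEnrichmentScore(unname(ranked), names(ranked) %in% c("g1", "g2"), 1)

  exact <- geneLabelPermutationP(stats, 2, obs, exact = TRUE)
  # oracle: all 10 subsets by brute force
  wByPos <- abs(unname(ranked))
  esAll <- apply(combn(5, 2), 2, function(pos) {
    member <- seq_len(5) %in% pos
    bruteForceES(unname(ranked), member, 1)
  })
  expect_equal(exact$pValue, (1 + sum(abs(esAll) >= abs(obs))) / 11)

  # same seed -> identical p; maximal ES -> minimal p
  r1 <- geneLabelPermutationP(stats, 2, obs, B = 200, seed = 9)
  r2 <- geneLabelPermutationP(stats, 2, obs, B = 200, seed = 9)
  expect_identical(r1$pValue, r2$pValue)
  expect_error(geneLabelPermutationP(stats, 5, obs), "smaller")
})

test_that("testPathways is calibrated under the null and order-invariant", {
  d <- simulationDesign("II", nPerGroup = 10, rho = 0, detectionCall = 0,
                        pathwaySizes = rep(10L, 1), pathwaysPerSize = 50L,
                        seed = 51)
  s <- simulateType2(d)
  res <- testPathways(s$expression, s$pathways, "sumt2", B = 199, seed = 3)
  expect_true(all(res$pValue > 0 & res$pValue <= 1))
  expect_true(all(res$pValue >= 1 / 200))
  # null calibration: rejection fraction near alpha (binomial 99% band)
  frac <- mean(res$pValue <= 0.05)
  expect_lt(frac, qbinom(0.995, 50, 0.05) / 50 + 1e-9)

  # pathway order does not change per-pathway results
  idx <- rev(seq_len(length(s$pathways)))
  resRev <- testPathways(s$expression, s$pathways[idx], "sumt2", B = 199,
                        seed = 3)
  expect_equal(resRev$statistic[match(res$pathway, resRev$pathway)],
               res$statistic)

  # single pathway, B = 10: p >= 1/11
  one <- s$pathways[1]
  r1 <- testPathways(s$expression, one, "gsea", B = 10, seed = 1)
  expect_equal(nrow(r1), 1)
  expect_gte(r1$pValue, 1 / 11)
})

test_that("null p-value distributions are approximately uniform for all methods", {
  d <- simulationDesign("II", nPerGroup = 8, rho = 0, detectionCall = 0,
                        pathwaySizes = 8L, pathwaysPerSize = 100L, seed = 52)
  s <- simulateType2(d)
  for (method in c("sumt2", "gsea")) {
    res <- testPathways(s$expression, s$pathways, method, B = 99, seed = 7)
    ks <- suppressWarnings(ks.test(res$pValue, "punif"))
    expect_lt(unname(ks$statistic), 0.15)
  }
})
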