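## small labeled dataset with a strong signal in half of the pathways
makeSurrogateData <- function(nPerGroup = 20, seed = 71) {
  set.seed(seed)
  p <- 60
  v <- matrix(rnorm(p * 2 * nPerGroup), p, 2 * nPerGroup)
  rownames(v) <- sprintf("g%03d", seq_len(p))
  sets <- split(rownames(v), rep(1:6, each = 10))
  names(sets) <- sprintf("pw%02d", 1:6)
  # pathways 1-3 carry a shift in the treatment half
  treat <- (nPerGroup + 1):(2 * nPerGroup)
  v[unlist(sets[1:3]), treat] <- v[unlist(sets[1:3]), treat] + 1.5
  list(data = groupedExpression(v, rownames(v),
                                rep(c("control", "treatment"),
                                    each = nPerGroup)),
       pathways = pathwayCollection(sets))
}

test_that("reference lists flag exactly the sub-alpha pathways", {
  fx <- makeSurrogateData()
  ref <- buildReferenceList(fx$data, fx$pathways, "sumt2", B = 199,
                            alpha = 0.05, seed = 3)
  expect_equal(ref$significant, ref$pValue <= 0.05)
  expect_true(all(ref$significant[1:3]))      # strong signal found

  refAll <- buildReferenceList(fx$data, fx$pathways, "sumt2", B = 19,
                               alpha = 1, seed = 3)
  expect_true(all(refAll$significant))

  ref2 <- buildReferenceList(fx$data, fx$pathways, "sumt2", B = 199,
                             alpha = 0.05, seed = 3)
  expect_identical(ref, ref2)
})

test_that("bootstrap subsampling preserves the group design", {
  fx <- makeSurrogateData(nPerGroup = 12)
  bs <- bootstrapSubsample(fx$data, 5, seed = 4)
  expect_equal(ncol(bs), 10)
  expect_equal(nControl(bs), 5)
  expect_equal(nTreatment(bs), 5)
  expect_error(bootstrapSubsample(fx$data, 1), "at least 2")

  # every bootstrap column is one of the original columns of its group
  orig <- exprValues(fx$data)
  v <- exprValues(bs)
  for (j in 1:5)
    expect_true(any(colSums(abs(orig[, 1:12] - v[, j])) == 0))

  # expected fraction of distinct originals per draw: 1 - (1 - 1/n)^n
  n <- 12
  fracs <- vapply(1:400, function(b) {
    d <- bootstrapSubsample(fx$data, n, seed = b)
    cols <- exprValues(d)[1, 1:n]              # gene-1 values id the column
    length(unique(cols)) / n
  }, numeric(1))
  expect_equal(mean(fracs), 1 - (1 - 1 / n)^n, tolerance = 0.02)
})

test_that("confusion against the reference behaves like a confusion matrix", {
  ref <- data.frame(pathway = paste0("p", 1:10),
                    pValue = c(rep(0.01, 4), rep(0.5, 6)),
                    significant = c(rep(TRUE, 4), rep(FALSE, 6)))
  # identical calls: power 1, fpr 0
  res <- data.frame(pathway = paste0("p", 1:10),
                    pValue = ref$pValue)
  conf <- confusionVsReference(res, ref, 0.05)
  expect_equal(conf[c("power", "fpr")], list(power = 1, fpr = 0))
  expect_equal(conf$TP + conf$FP + conf$TN + conf$FN, 10)

  # complementary calls: power 0, fpr 1
  resC <- data.frame(pathway = paste0("p", 1:10),
                     pValue = ifelse(ref$significant, 0.5, 0.01))
  confC <- confusionVsReference(resC, ref, 0.05)
  expect_equal(confC[c("power", "fpr")], list(power = 0, fpr = 1))

  # random calls: E[TP] = k * r / m (hypergeometric)
  set.seed(72)
  tps <- vapply(1:2000, function(i) {
    resR <- data.frame(pathway = paste0("p", 1:10),
                       pValue = ifelse(seq_len(10) %in% sample.int(10, 3),
                                       0.01, 0.5))
    confusionVsReference(resR, ref, 0.05)$TP
  }, numeric(1))
  expect_equal(mean(tps), 3 * 4 / 10, tolerance = 0.05)

  expect_error(confusionVsReference(
    data.frame(pathway = "x", pValue = 1), ref), "different pathway sets")
})

test_that("bootstrap power curves rise with sample size on strong signal", {
  fx <- makeSurrogateData(nPerGroup = 25, seed = 73)
  pc <- powerCurve(fx$data, fx$pathways, "sumt2",
                   sampleSizes = c(4L, 10L, 25L), nBootstrap = 8, B = 99,
                   alpha = 0.05, seed = 6)
  expect_equal(nrow(pc), 3)
  expect_true(all(diff(pc$power) >= -2 * pmax(pc$sdPower[-1],
                                              pc$sdPower[-3])))
  expect_gte(pc$power[3], pc$power[1])
  expect_error(powerCurve(fx$data, fx$pathways, sampleSizes = 100L),
               "exceed")

  # deterministic under a fixed seed
  pc2 <- powerCurve(fx$data, fx$pathways, "sumt2",
                    sampleSizes = c(4L, 10L, 25L), nBootstrap = 8, B = 99,
                    alpha = 0.05, seed = 6)
  expect_identical(pc, pc2)
})

test_that("sample-size regression matches the closed-form solution", {
  # exact interpolation: (10, 0.4), (20, 0.2) hits zero at 30
  fit <- optimalSampleSizeRegression(
    data.frame(sampleSize = c(10, 20), distance = c(0.4, 0.2)))
  expect_equal(fit$predictedNAtZero, 30)
  expect_false(fit$undefined)

  # flat distances: slope 0, prediction undefined
  flat <- optimalSampleSizeRegression(
    data.frame(sampleSize = c(10, 20, 30), distance = c(0, 0, 0)))
  expect_true(flat$undefined)
  expect_true(is.na(flat$predictedNAtZero))

  # noisy line vs normal-equations oracle
  set.seed(74)
  n <- 50
  x <- runif(n, 5, 60)
  y <- 0.9 - 0.012 * x + rnorm(n, sd = 0.05)
  fit <- optimalSampleSizeRegression(data.frame(sampleSize = x, distance = y))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$predictedNAtZero, -beta[1] / beta[2], tolerance = 1e-8)
  expect_gt(fit$fStatistic, 10)
  expect_lt(fit$pValue, 0.01)

  expect_error(optimalSampleSizeRegression(
    data.frame(sampleSize = c(10, 10), distance = c(0.1, 0.2))), "distinct")
})

test_that("correlation profiles contrast within-pathway and global correlation", {
  # two identical genes: correlation exactly 1
  v <- matrix(rnorm(20), 2, 10, byrow = FALSE)
  v[2, ] <- v[1, ]
  twin <- groupedExpression(v, c("a", "b"),
                            rep(c("control", "treatment"), each = 5))
  prof <- pathwayCorrelationProfile(twin,
                                    pathwayCollection(list(P = c("a", "b"))))
  expect_equal(prof$profile$meanCorrelation, 1)

  # independent genes: mean correlation near zero
  set.seed(75)
  big <- groupedExpression(matrix(rnorm(20 * 10000), 20, 10000),
                           sprintf("g%02d", 1:20),
                           rep(c("control", "treatment"), each = 5000))
  profN <- pathwayCorrelationProfile(
    big, pathwayCollection(split(rownames(big), rep(1:2, each = 10))))
  expect_true(all(abs(profN$profile$meanCorrelation) < 0.05))
  expect_lt(abs(profN$overallMean), 0.05)

  # constant genes excluded with a warning
  vc <- rbind(v, const = rep(2, 10))
  gc <- groupedExpression(vc, c("a", "b", "const"),
                          rep(c("control", "treatment"), each = 5))
  expect_warning(pathwayCorrelationProfile(
    gc, pathwayCollection(list(P = c("a", "b")))), "constant")
})

test_that("detection-call estimation applies the BH step-up rule", {
  # hand-checked BH at q = 0.05: (0.001, 0.02, 0.8) -> 2 rejections
  padj <- p.adjust(c(0.001, 0.02, 0.8), method = "BH")
  expect_equal(sum(padj <= 0.05), 2)

  # null data: mean DC near 0
  set.seed(76)
  null <- groupedExpression(matrix(rnorm(50 * 40), 50, 40),
                            sprintf("g%02d", 1:50),
                            rep(c("control", "treatment"), each = 20))
  pw <- pathwayCollection(split(rownames(null), rep(1:5, each = 10)))
  est <- estimateDcDistribution(null, pw, q = 0.05)
  expect_lt(est$meanDc, 0.05)

  # overwhelming shift: DC ~ 1, and the BH rejection set grows with q
  v <- exprValues(null)
  v[1:10, 21:40] <- v[1:10, 21:40] + 3
  strong <- groupedExpression(v, rownames(null),
                              rep(c("control", "treatment"), each = 20))
  estS <- estimateDcDistribution(strong, pw, q = 0.05)
  expect_equal(unname(estS$perPathway[1]), 1)
  estLoose <- estimateDcDistribution(strong, pw, q = 0.5)
  expect_true(all(estLoose$perPathway >= estS$perPathway))
})
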