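#' Reference list of significant pathways at full sample size
#'
#' First step of the surrogate-data assessment: test every pathway on the
#' complete dataset and record which are significant at level alpha. The
#' significant pathways are subsequently treated as (operational) true
#' positives — the list may of course contain false declarations, so the
#' downstream power and FPR measure robustness relative to the full-sample
#' result, not biological truth.
#'
#' @inheritParams testPathways
#' @return data.frame with `pathway`, `pValue`, `significant`, plus an
#'   `alpha` attribute.
#' @export
buildReferenceList <- function(data, pathways, method = "sumt2", B = 1000L,
                               alpha = 0.05, seed = 1L) {
  res <- testPathways(data, pathways, method, B = B, alpha = alpha,
                     seed = seed)
  out <- data.frame(pathway = res$pathway, pValue = res$pValue,
                    significant = res$pValue <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  out
}

#' Stratified bootstrap subsample of a two-group dataset
#'
#' Draws `mPerGroup` samples with replacement within each condition,
#' preserving the two-group design at the reduced size.
#'
#' @param data a [GroupedExpression-class]
#' @param mPerGroup samples per condition in the subsample (>= 2).
#' @param seed integer seed.
#' @return a [GroupedExpression-class] with `2 * mPerGroup` columns.
#' @export
bootstrapSubsample <- function(data, mPerGroup, seed = 1L) {
  if (mPerGroup < 2)
    stop("mPerGroup must be at least 2")
  gi <- .groupIdx(data)
  set.seed(as.integer(seed))
  pick1 <- gi$i1[sample.int(length(gi$i1), mPerGroup, replace = TRUE)]
  pick2 <- gi$i2[sample.int(length(gi$i2), mPerGroup, replace = TRUE)]
  v <- exprValues(data)[, c(pick1, pick2), drop = FALSE]
  colnames(v) <- paste0("b", seq_len(ncol(v)))
  groupedExpression(v, rownames(data),
                    rep(c("control", "treatment"), each = mPerGroup))
}

#' Confusion of test results against a reference list
#'
#' Scores each pathway's call (significant at alpha or not) against the
#' reference list: significant & reference-significant is a true positive,
#' and so on. Power = TP / (TP + FN), FPR = FP / (FP + TN); the four counts
#' partition the pathway set.
#'
#' @param results data.frame from [testPathways()].
#' @param reference data.frame from [buildReferenceList()].
#' @param alpha significance level applied to `results`.
#' @return list with `TP`, `FP`, `TN`, `FN`, `power`, `fpr`.
#' @export
confusionVsReference <- function(results, reference, alpha = 0.05) {
  if (!setequal(results$pathway, reference$pathway))
    stop("results and reference cover different pathway sets")
  ref <- reference$significant[match(results$pathway, reference$pathway)]
  call <- results$pValue <= alpha
  tp <- sum(call & ref); fp <- sum(call & !ref)
  fn <- sum(!call & ref); tn <- sum(!call & !ref)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       power = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

#' Bootstrap power curve over reduced sample sizes
#'
#' For each probed per-group sample size, draws `nBootstrap` stratified
#' bootstrap datasets, tests every pathway on each, scores the calls against
#' the full-sample reference list, and averages power, FPR and the number of
#' significant pathways over the bootstrap replicates.
#'
#' @inheritParams buildReferenceList
#' @param reference optional precomputed [buildReferenceList()] output
#'   (computed from `data` if missing).
#' @param sampleSizes integer vector of per-group sizes to probe (each must
#'   not exceed the available per-group size).
#' @param nBootstrap bootstrap datasets per size.
#' @return data.frame with one row per size: `sampleSize`, `method`,
#'   `power`, `fpr`, `nSignificant`, `sdPower`, `sdFpr`, `nBootstrap`.
#' @export
powerCurve <- function(data, pathways, method = "sumt2", sampleSizes,
                       nBootstrap = 20L, B = 500L, alpha = 0.05, seed = 1L,
                       reference = NULL) {
  gi <- .groupIdx(data)
  if (any(sampleSizes > min(length(gi$i1), length(gi$i2))))
    stop("sampleSizes exceed the available per-group sample size")
  if (is.null(reference))
    reference <- buildReferenceList(data, pathways, method, B, alpha,
                                    seed = .deriveSeed(seed, 0L))
  rows <- lapply(seq_along(sampleSizes), function(si) {
    m <- sampleSizes[si]
    pw <- numeric(nBootstrap); fp <- numeric(nBootstrap)
    ns <- numeric(nBootstrap)
    for (b in seq_len(nBootstrap)) {
      bs <- bootstrapSubsample(data, m, seed = .deriveSeed(seed, si * 1000L + b))
      res <- testPathways(bs, pathways, method, B = B, alpha = alpha,
                         seed = .deriveSeed(seed, si * 1000L + 500L + b))
      conf <- confusionVsReference(res, reference, alpha)
      pw[b] <- conf$power; fp[b] <- conf$fpr
      ns[b] <- countSignificant(res, alpha)
    }
    data.frame(sampleSize = m, method = method,
               power = mean(pw, na.rm = TRUE), fpr = mean(fp, na.rm = TRUE),
               nSignificant = mean(ns),
               sdPower = sd(pw), sdFpr = sd(fp),
               nBootstrap = as.integer(nBootstrap),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Optimal sample size from a distance-to-convergence regression
#'
#' Ordinary least squares of the distance to convergence (the shortfall of
#' the power curve from its plateau, here 1 - power) on the probed sample
#' size; the predicted optimal size is where the fitted line meets zero
#' distance, \eqn{-intercept / slope}. The regression F statistic and its
#' p-value quantify the fit.
#'
#' @param points data.frame with columns `sampleSize` and `distance` (or a
#'   two-column matrix in that order).
#' @return list with `slope`, `intercept`, `predictedNAtZero`,
#'   `fStatistic`, `pValue`, and logical `undefined` (TRUE when the slope is
#'   zero and no prediction exists).
#' @export
optimalSampleSizeRegression <- function(points) {
  points <- as.data.frame(points)
  if (ncol(points) >= 2 && !all(c("sampleSize", "distance") %in% names(points)))
    names(points)[1:2] <- c("sampleSize", "distance")
  if (length(unique(points$sampleSize)) < 2)
    stop("need at least 2 distinct sample sizes")
  fit <- lm(distance ~ sampleSize, data = points)
  b <- coef(fit)
  slope <- unname(b["sampleSize"]); intercept <- unname(b["(Intercept)"])
  fstat <- tryCatch({
    s <- summary(fit)$fstatistic
    if (is.null(s)) c(NA_real_, NA_real_)
    else c(unname(s["value"]),
           pf(s["value"], s["numdf"], s["dendf"], lower.tail = FALSE))
  }, error = function(e) c(NA_real_, NA_real_))
  undefined <- slope == 0 || is.na(slope)
  list(slope = slope, intercept = intercept,
       predictedNAtZero = if (undefined) NA_real_ else -intercept / slope,
       fStatistic = fstat[1], pValue = unname(fstat[2]),
       undefined = undefined)
}

#' Within-pathway correlation profile
#'
#' For each pathway, the mean of all pairwise Pearson correlations among its
#' member genes over all samples, returned sorted in decreasing order,
#' together with the overall mean correlation over all gene pairs in the
#' data. Beyond 2000 genes the overall mean switches to seeded subsampling
#' of 1e5 gene pairs; below that it is exact. Constant genes are excluded
#' with a warning.
#'
#' @param data a [GroupedExpression-class]
#' @param pathways a [PathwayCollection-class] (sizes >= 2).
#' @param seed seed for the pair subsampling of the overall mean.
#' @return list with `profile` (data.frame `pathway`, `meanCorrelation`,
#'   sorted decreasing) and `overallMean`.
#' @export
pathwayCorrelationProfile <- function(data, pathways, seed = 1L) {
  v <- exprValues(data)
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s) excluded from correlations",
                    sum(sds == 0)))
    v <- v[sds > 0, , drop = FALSE]
  }
  meanCor <- vapply(pathways@sets, function(s) {
    s <- intersect(s, rownames(v))
    if (length(s) < 2) return(NA_real_)
    cm <- cor(t(v[s, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  prof <- data.frame(pathway = names(pathways@sets),
                     meanCorrelation = unname(meanCor),
                     stringsAsFactors = FALSE)
  prof <- prof[order(-prof$meanCorrelation), , drop = FALSE]
  rownames(prof) <- NULL
  p <- nrow(v)
  if (p <= 2000) {
    cm <- cor(t(v))
    overall <- mean(cm[upper.tri(cm)])
  } else {
    set.seed(as.integer(seed))
    nPairs <- 100000L
    i <- sample.int(p, nPairs, replace = TRUE)
    j <- sample.int(p, nPairs, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    vs <- t(scale(t(v)))
    overall <- mean(rowSums(vs[i, , drop = FALSE] * vs[j, , drop = FALSE]) /
                      (ncol(v) - 1))
  }
  list(profile = prof, overallMean = overall)
}

#' Detection-call distribution over pathways
#'
#' Identifies differentially expressed genes with a pooled-variance
#' two-sample t test followed by Benjamini–Hochberg correction at level `q`,
#' then reports each pathway's detection call — the fraction of its member
#' genes rejected — and the mean DC over pathways.
#'
#' @param data a [GroupedExpression-class]
#' @param pathways a [PathwayCollection-class]
#' @param q FDR level for the BH step.
#' @return list with `perPathway` (named numeric DC values) and `meanDc`.
#' @export
estimateDcDistribution <- function(data, pathways, q = 0.05) {
  gi <- .groupIdx(data)
  t <- .tstats(exprValues(data), gi$i1, gi$i2)
  df <- length(gi$i1) + length(gi$i2) - 2
  pvals <- 2 * pt(-abs(t), df)
  padj <- p.adjust(pvals, method = "BH")
  rejected <- rownames(data)[padj <= q]
  dc <- vapply(pathways@sets, function(s) mean(s %in% rejected), numeric(1))
  list(perPathway = dc, meanDc = mean(dc))
}
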