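## Fast pooled-variance two-sample t statistics for all genes at once.
## values: genes x samples; i1/i2: control/treatment column indices.
## Zero-pooled-variance genes get t = 0 (warning handled by callers that
## expose this path to users).
.tstats <- function(values, i1, i2, warnZero = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  x1 <- values[, i1, drop = FALSE]
  x2 <- values[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums(x1 * x1) - n1 * m1 * m1
  ss2 <- rowSums(x2 * x2) - n2 * m2 * m2
  sp2 <- pmax(ss1 + ss2, 0) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  zero <- se == 0
  if (any(zero)) {
    t[zero] <- 0
    if (warnZero)
      warning(sprintf("%d gene(s) with zero pooled variance; t set to 0",
                      sum(zero)))
  }
  t
}

.groupIdx <- function(data) {
  g <- groupLabels(data)
  list(i1 = which(g == "control"), i2 = which(g == "treatment"))
}

.setIdx <- function(data, geneSet) {
  idx <- match(geneSet, rownames(data))
  if (anyNA(idx))
    stop(sprintf("genes absent from the data: %s",
                 paste(head(geneSet[is.na(idx)], 5), collapse = ", ")))
  idx
}

#' Gene-wise two-sample t statistics
#'
#' Pooled-variance two-sample t per gene,
#' \eqn{t_i = (\bar{y}_i - \bar{x}_i) / (s_{p,i} \sqrt{1/n_1 + 1/n_2})},
#' treatment minus control. Genes with zero pooled variance get a statistic
#' of 0 with a warning (conservative; keeps downstream sums finite).
#'
#' @param data a [GroupedExpression-class] with at least two samples per
#'   group.
#' @return named numeric vector, one t per gene.
#' @export
geneTStatistics <- function(data) {
  stopifnot(is(data, "GroupedExpression"))
  gi <- .groupIdx(data)
  if (length(gi$i1) < 2 || length(gi$i2) < 2)
    stop("each group needs at least 2 samples")
  t <- .tstats(exprValues(data), gi$i1, gi$i2, warnZero = TRUE)
  names(t) <- rownames(data)
  t
}

#' Sum-of-t-square pathway statistic
#'
#' The self-contained univariate pathway statistic
#' \eqn{\sum_{i \in S} t_i^2} over the member genes' two-sample t
#' statistics.
#'
#' @param data a [GroupedExpression-class]
#' @param geneSet character vector of member gene ids.
#' @return the statistic (non-negative scalar).
#' @export
sumTSquare <- function(data, geneSet) {
  if (length(geneSet) == 0)
    stop("geneSet must be non-empty")
  idx <- .setIdx(data, geneSet)
  gi <- .groupIdx(data)
  t <- .tstats(exprValues(data)[idx, , drop = FALSE], gi$i1, gi$i2)
  sum(t * t)
}

## Shrinkage precision on a raw sub-matrix (genes x samples).
## Pooled covariance S = ((n1-1)S1 + (n2-1)S2)/(n1+n2-2); its correlation
## off-diagonals are shrunk toward zero with the analytic intensity
## lambda = sum var-hat(r_ij) / sum r_ij^2 (diagonal unequal-variance
## target), clipped to [0, 1]; the precision is the inverse of the shrunk
## covariance.
.shrinkagePrecisionRaw <- function(x, i1, i2, shrinkageIntensity = NULL) {
  p <- nrow(x)
  n1 <- length(i1); n2 <- length(i2)
  d <- n1 + n2 - 2
  xc <- x
  xc[, i1] <- x[, i1, drop = FALSE] - rowMeans(x[, i1, drop = FALSE])
  xc[, i2] <- x[, i2, drop = FALSE] - rowMeans(x[, i2, drop = FALSE])
  v <- rowSums(xc * xc) / d                 # pooled variances
  if (any(v == 0))
    stop(sprintf("constant gene(s) within both groups: %s",
                 paste(head(rownames(x)[v == 0], 5), collapse = ", ")))
  if (p == 1) {
    return(list(precision = matrix(1 / v, 1, 1,
                                   dimnames = list(rownames(x), rownames(x))),
                shrinkageIntensity = 0))
  }
  xs <- xc / sqrt(v)                        # sum_k xs_ki^2 = d per gene
  R <- tcrossprod(xs) / d
  if (is.null(shrinkageIntensity)) {
    n <- n1 + n2
    xs2 <- xs * xs
    sw <- tcrossprod(xs)                    # sum_k w_kij
    sw2 <- tcrossprod(xs2)                  # sum_k w_kij^2
    varr <- n / ((n - 1)^3) * (sw2 - sw * sw / n)
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    lambda <- if (denom == 0) 1 else min(1, max(0, sum(varr[off]) / denom))
  } else {
    lambda <- shrinkageIntensity
  }
  Rstar <- (1 - lambda) * R
  diag(Rstar) <- 1
  sdv <- sqrt(v)
  Cstar <- Rstar * tcrossprod(sdv)
  prec <- chol2inv(chol(Cstar))
  dimnames(prec) <- list(rownames(x), rownames(x))
  list(precision = prec, shrinkageIntensity = lambda)
}

#' Pooled within-group covariance matrix
#'
#' \eqn{S = ((n_1 - 1) S_1 + (n_2 - 1) S_2) / (n_1 + n_2 - 2)} with
#' \eqn{S_1, S_2} the within-group sample covariances of the member genes.
#'
#' @inheritParams sumTSquare
#' @return symmetric p x p matrix.
#' @export
pooledCovariance <- function(data, geneSet) {
  idx <- .setIdx(data, geneSet)
  gi <- .groupIdx(data)
  if (length(gi$i1) < 2 || length(gi$i2) < 2)
    stop("each group needs at least 2 samples")
  x <- exprValues(data)[idx, , drop = FALSE]
  s1 <- cov(t(x[, gi$i1, drop = FALSE]))
  s2 <- cov(t(x[, gi$i2, drop = FALSE]))
  n1 <- length(gi$i1); n2 <- length(gi$i2)
  ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
}

#' Shrinkage estimate of the pooled precision matrix
#'
#' Estimates the inverse of the pooled covariance matrix for a gene set by
#' shrinking the pooled correlation matrix toward the identity with the
#' analytic intensity
#' \eqn{\lambda^{*} = \sum_{i \ne j} \widehat{var}(r_{ij}) /
#' \sum_{i \ne j} r_{ij}^2} (diagonal, unequal-variance target), clipped to
#' \[0, 1\], and inverting the shrunk covariance. This keeps the estimate
#' invertible when the set size exceeds the sample size. When all sample
#' correlations are exactly zero the intensity is defined as 1 (fully
#' diagonal), the limiting value.
#'
#' @inheritParams sumTSquare
#' @param shrinkageIntensity optional fixed intensity in \[0, 1\] overriding
#'   the analytic choice (0 disables shrinkage).
#' @return list with `precision` (p x p matrix) and `shrinkageIntensity`.
#' @export
shrinkagePrecision <- function(data, geneSet, shrinkageIntensity = NULL) {
  idx <- .setIdx(data, geneSet)
  gi <- .groupIdx(data)
  .shrinkagePrecisionRaw(exprValues(data)[idx, , drop = FALSE],
                         gi$i1, gi$i2, shrinkageIntensity)
}

.hotellingRaw <- function(x, i1, i2, shrinkageIntensity = NULL) {
  est <- .shrinkagePrecisionRaw(x, i1, i2, shrinkageIntensity)
  d <- rowMeans(x[, i2, drop = FALSE]) - rowMeans(x[, i1, drop = FALSE])
  n1 <- length(i1); n2 <- length(i2)
  drop(n1 * n2 / (n1 + n2) * crossprod(d, est$precision %*% d))
}

#' Hotelling's T-squared pathway statistic
#'
#' The self-contained multivariate statistic
#' \eqn{T^2 = \frac{n_1 n_2}{n_1 + n_2} \, d' \hat{K} d} with \eqn{d} the
#' difference of group mean vectors over the member genes and \eqn{\hat{K}}
#' the shrinkage precision estimate from [shrinkagePrecision()].
#'
#' @inheritParams shrinkagePrecision
#' @return the statistic (non-negative scalar).
#' @export
hotellingT2 <- function(data, geneSet, shrinkageIntensity = NULL) {
  idx <- .setIdx(data, geneSet)
  gi <- .groupIdx(data)
  .hotellingRaw(exprValues(data)[idx, , drop = FALSE], gi$i1, gi$i2,
                shrinkageIntensity)
}

## Enrichment score from sorted hit positions.
## pos: strictly increasing positions of member genes in the ranked list;
## w: their weights |stat|^q (same order); N: list length.
## The running sum is piecewise linear between hits, so its extrema occur
## just before or just after a hit; ES is the extremum of largest magnitude
## (signed), taking the earliest position on ties.
.gseaES <- function(pos, w, N) {
  k <- length(pos)
  nr <- sum(w)
  if (nr == 0)
    stop("all member statistics are zero: enrichment score undefined")
  ## a set covering every gene climbs to 1 and never decrements
  miss <- if (k == N) 0 else 1 / (N - k)
  cumw <- cumsum(w) / nr
  after <- cumw - (pos - seq_len(k)) * miss
  before <- c(0, cumw[-k]) - (pos - seq_len(k)) * miss
  vals <- as.vector(rbind(before, after))
  posAll <- as.vector(rbind(pos - 1L, pos))
  keep <- posAll > 0L
  vals <- vals[keep]
  ## earliest position wins on ties, robust to last-ulp rounding noise
  av <- abs(vals)
  vals[which(av >= max(av) - 1e-12)[1]]
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov–Smirnov-like running sum over a ranked gene list:
#' walking down the list, a member gene at rank i adds
#' \eqn{|s_i|^q / N_R} (with \eqn{N_R} the sum of member weights) and a
#' non-member subtracts \eqn{1 / (N - N_H)}. The enrichment score is the
#' running-sum value of maximal absolute deviation from zero, signed.
#' `weightExponent = 1` gives the standard weighted form; 0 the unweighted
#' KS form.
#'
#' @param rankedStats numeric vector of gene-level statistics sorted in
#'   decreasing order.
#' @param setMembership logical vector marking member genes in the same
#'   order.
#' @param weightExponent non-negative weighting exponent q.
#' @return the enrichment score in \[-1, 1\].
#' @export
gseaEnrichmentScore <- function(rankedStats, setMembership,
                                weightExponent = 1) {
  N <- length(rankedStats)
  stopifnot(length(setMembership) == N)
  if (is.unsorted(-rankedStats))
    stop("rankedStats must be sorted in decreasing order")
  nh <- sum(setMembership)
  if (nh == 0)
    stop("need at least one member gene")
  pos <- which(setMembership)
  .gseaES(pos, abs(rankedStats[pos])^weightExponent, N)
}

#' Permutation p-value from sample-label permutations
#'
#' Permutes the group labels B times (uniformly over permutations, group
#' sizes preserved) and reports the add-one estimator
#' \eqn{p = (1 + \#\{T^{*} \ge T_{obs}\}) / (1 + B)}, which never returns 0.
#'
#' @param data a [GroupedExpression-class]
#' @param geneSet character vector of member gene ids.
#' @param statistic `"sumTSquare"`, `"hotelling"`, or a function
#'   `f(values, ctrlIdx, treatIdx)` over the member-gene sub-matrix
#'   returning a scalar for which larger means more extreme.
#' @param B number of permutations (ignored with `exact = TRUE`).
#' @param seed integer seed.
#' @param exact enumerate all distinct group assignments instead of random
#'   permutations (feasible for small samples; at most 10000 assignments).
#' @return list with `statistic` (observed), `pValue`, `nPermutations`.
#' @export
sampleLabelPermutationP <- function(data, geneSet,
                                    statistic = "sumTSquare",
                                    B = 1000L, seed = 1L, exact = FALSE) {
  stopifnot(B >= 1)
  idx <- .setIdx(data, geneSet)
  gi <- .groupIdx(data)
  x <- exprValues(data)[idx, , drop = FALSE]
  fn <- if (is.function(statistic)) statistic
        else switch(match.arg(statistic, c("sumTSquare", "hotelling")),
          sumTSquare = function(v, i1, i2) sum(.tstats(v, i1, i2)^2),
          hotelling = function(v, i1, i2) .hotellingRaw(v, i1, i2))
  obs <- fn(x, gi$i1, gi$i2)
  n <- ncol(x); n1 <- length(gi$i1)
  count <- 0L
  if (exact) {
    if (choose(n, n1) > 10000)
      stop("too many assignments for exact enumeration")
    splits <- utils::combn(n, n1)
    B <- ncol(splits)
    for (b in seq_len(B)) {
      i1 <- splits[, b]
      stat <- fn(x, i1, setdiff(seq_len(n), i1))
      if (stat >= obs) count <- count + 1L
    }
  } else {
    set.seed(as.integer(seed))
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      stat <- fn(x, perm[seq_len(n1)], perm[(n1 + 1):n])
      if (stat >= obs) count <- count + 1L
    }
  }
  list(statistic = obs, pValue = (1 + count) / (1 + B),
       nPermutations = as.integer(B))
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Realizes the gene-label permutation null by drawing B random gene subsets
#' of the set's size from the ranked universe (equivalent to permuting gene
#' labels for a single set) and comparing \eqn{|ES^{*}|} with the observed
#' \eqn{|ES|} (two-sided: the alternative is a non-vanishing score of either
#' sign). Add-one estimator as in [sampleLabelPermutationP()].
#'
#' @param allGeneStats numeric vector of gene statistics for the full
#'   universe (any order).
#' @param setSize member count of the tested set.
#' @param observedES the observed enrichment score.
#' @param B number of null draws (ignored with `exact = TRUE`).
#' @param seed integer seed.
#' @param weightExponent weighting exponent q.
#' @param exact enumerate all subsets of the given size instead of random
#'   draws (feasible for tiny universes; at most 10000 subsets).
#' @return list with `pValue` and `nPermutations`.
#' @export
geneLabelPermutationP <- function(allGeneStats, setSize, observedES,
                                  B = 1000L, seed = 1L, weightExponent = 1,
                                  exact = FALSE) {
  N <- length(allGeneStats)
  if (setSize >= N)
    stop("setSize must be smaller than the gene universe")
  ## weights indexed by rank position: the list is ranked by the signed
  ## statistic, so both tails carry large absolute weights
  wByPos <- abs(sort(allGeneStats, decreasing = TRUE))^weightExponent
  count <- 0L
  thr <- abs(observedES)
  if (exact) {
    if (choose(N, setSize) > 10000)
      stop("too many subsets for exact enumeration")
    subsets <- utils::combn(N, setSize)
    B <- ncol(subsets)
    for (b in seq_len(B)) {
      es <- .gseaES(subsets[, b], wByPos[subsets[, b]], N)
      if (abs(es) >= thr) count <- count + 1L
    }
  } else {
    set.seed(as.integer(seed))
    for (b in seq_len(B)) {
      pos <- sort.int(sample.int(N, setSize))
      es <- .gseaES(pos, wByPos[pos], N)
      if (abs(es) >= thr) count <- count + 1L
    }
  }
  list(pValue = (1 + count) / (1 + B), nPermutations = as.integer(B))
}

#' Test every pathway of a collection
#'
#' Driver computing one statistic and permutation p-value per pathway.
#' `"sumt2"` and `"hotelling"` are self-contained tests with sample-label
#' permutation nulls. `"gsea"` is competitive: the ranked list spans the
#' data's genes plus the `background` genes when one is supplied (the
#' simulation type I design); without a background the rest of the data —
#' the complement of the tested pathway — plays that role, as for
#' simulation types II–IV. The significance of the enrichment score is
#' two-sided on \eqn{|ES|} against either of two nulls: `gseaNull =
#' "sample"` (default) permutes the phenotype labels and recomputes the
#' whole ranking per permutation, which preserves the gene-gene correlation
#' structure and therefore keeps the false-positive rate at its nominal
#' level under correlated null data; `gseaNull = "gene"` draws random gene
#' subsets of the set's size ([geneLabelPermutationP()]), which is cheaper
#' but anti-conservative when member genes are correlated.
#'
#' @param data a [GroupedExpression-class]
#' @param pathways a [PathwayCollection-class] over the data's genes.
#' @param method `"gsea"`, `"hotelling"` or `"sumt2"`.
#' @param B permutations per pathway.
#' @param alpha nominal level recorded alongside (used by callers).
#' @param background optional [GroupedExpression-class] of null genes with
#'   the same samples (GSEA only).
#' @param seed integer seed.
#' @param weightExponent GSEA weighting exponent q.
#' @param gseaNull `"sample"` or `"gene"` (see Details).
#' @return data.frame with columns `pathway`, `method`, `statistic`,
#'   `pValue`, `nPermutations`.
#' @export
testPathways <- function(data, pathways,
                         method = c("sumt2", "hotelling", "gsea"),
                         B = 1000L, alpha = 0.05, background = NULL,
                         seed = 1L, weightExponent = 1,
                         gseaNull = c("sample", "gene")) {
  method <- match.arg(method)
  stopifnot(is(data, "GroupedExpression"), is(pathways, "PathwayCollection"))
  gi <- .groupIdx(data)
  values <- exprValues(data)
  sets <- pathways@sets
  idxList <- lapply(sets, function(s) .setIdx(data, s))
  nPw <- length(sets)
  stat <- numeric(nPw); pval <- numeric(nPw)

  if (method == "sumt2") {
    tobs <- .tstats(values, gi$i1, gi$i2)
    obs <- vapply(idxList, function(ix) sum(tobs[ix]^2), numeric(1))
    set.seed(as.integer(seed))
    n <- ncol(values); n1 <- length(gi$i1)
    count <- integer(nPw)
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      tb <- .tstats(values, perm[seq_len(n1)], perm[(n1 + 1):n])
      tb2 <- tb * tb
      sb <- vapply(idxList, function(ix) sum(tb2[ix]), numeric(1))
      count <- count + (sb >= obs)
    }
    stat <- obs
    pval <- (1 + count) / (1 + B)
  } else if (method == "hotelling") {
    for (i in seq_len(nPw)) {
      res <- sampleLabelPermutationP(data, sets[[i]], "hotelling", B,
                                     seed = .deriveSeed(seed, i))
      stat[i] <- res$statistic
      pval[i] <- res$pValue
    }
  } else {
    gseaNull <- match.arg(gseaNull)
    if (!is.null(background)) {
      stopifnot(is(background, "GroupedExpression"))
      if (!identical(as.character(groupLabels(background)),
                     as.character(groupLabels(data))))
        stop("background must share the data's sample labels")
      universe <- rbind(values, exprValues(background))
    } else {
      universe <- values
    }
    N <- nrow(universe)
    ## ES for every pathway given column indices of the two groups;
    ## ranking is deterministic: decreasing statistic, ties by gene id
    esAll <- function(i1, i2) {
      t <- .tstats(universe, i1, i2)
      ord <- order(-t, rownames(universe))
      rankOf <- integer(N)
      rankOf[ord] <- seq_len(N)
      names(rankOf) <- rownames(universe)
      wByPos <- abs(t[ord])^weightExponent
      vapply(sets, function(s) {
        pos <- sort.int(unname(rankOf[s]))
        .gseaES(pos, wByPos[pos], N)
      }, numeric(1))
    }
    stat <- esAll(gi$i1, gi$i2)
    if (gseaNull == "sample") {
      set.seed(as.integer(seed))
      n <- ncol(universe); n1 <- length(gi$i1)
      count <- integer(nPw)
      for (b in seq_len(B)) {
        perm <- sample.int(n)
        esb <- esAll(perm[seq_len(n1)], perm[(n1 + 1):n])
        count <- count + (abs(esb) >= abs(stat))
      }
      pval <- (1 + count) / (1 + B)
    } else {
      tAll <- .tstats(universe, gi$i1, gi$i2)
      names(tAll) <- rownames(universe)
      for (i in seq_len(nPw)) {
        pv <- geneLabelPermutationP(tAll, length(sets[[i]]), stat[i], B,
                                    seed = .deriveSeed(seed, i),
                                    weightExponent = weightExponent)
        pval[i] <- pv$pValue
      }
    }
    stat <- unname(stat)
  }
  data.frame(pathway = names(sets), method = method, statistic = stat,
             pValue = pval, nPermutations = as.integer(B),
             row.names = NULL, stringsAsFactors = FALSE)
}
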