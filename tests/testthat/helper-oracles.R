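## Independent oracles, deliberately naive: each recomputes a quantity by the
## most direct route so tests never share code with the implementation.

## Partial correlation of (i, j) given the rest, as the correlation of the
## residuals from regressing samples of i and j on the remaining variables.
residualPartialCor <- function(x, i, j) {
  rest <- setdiff(seq_len(ncol(x)), c(i, j))
  ri <- if (length(rest)) resid(lm(x[, i] ~ x[, rest])) else x[, i]
  rj <- if (length(rest)) resid(lm(x[, j] ~ x[, rest])) else x[, j]
  cor(ri, rj)
}

## Textbook pooled-variance two-sample t for one gene.
directT <- function(ctrl, treat) {
  n1 <- length(ctrl); n2 <- length(treat)
  sp2 <- ((n1 - 1) * var(ctrl) + (n2 - 1) * var(treat)) / (n1 + n2 - 2)
  (mean(treat) - mean(ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## Brute-force GSEA running sum evaluated at every prefix position.
bruteForceES <- function(rankedStats, member, q) {
  N <- length(rankedStats)
  nh <- sum(member)
  w <- abs(rankedStats)^q
  nr <- sum(w[member])
  inc <- ifelse(member, w / nr, -1 / (N - nh))
  rs <- cumsum(inc)
  # same deterministic tie rule as the package: on (numerically) tied
  # absolute deviations the earliest position wins
  rs[which(abs(rs) >= max(abs(rs)) - 1e-12)[1]]
}

## Random two-group expression object.
randomExpression <- function(p = 10, n1 = 5, n2 = 5, seed = 1,
                             geneIds = sprintf("g%03d", seq_len(p))) {
  set.seed(seed)
  groupedExpression(matrix(rnorm(p * (n1 + n2)), p, n1 + n2),
                    geneIds = geneIds,
                    groupLabels = rep(c("control", "treatment"),
                                      c(n1, n2)))
}

## Random SPD matrix with unit-scale entries.
randomSPD <- function(p, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) / p + diag(p)
}
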