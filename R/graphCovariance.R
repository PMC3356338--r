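#' Partial correlations from a covariance matrix
#'
#' For a multivariate normal vector with covariance \eqn{\Sigma} and
#' precision \eqn{K = \Sigma^{-1}}, the partial correlation between genes i
#' and j given all remaining genes is
#' \eqn{\rho_{ij|rest} = -k_{ij} / \sqrt{k_{ii} k_{jj}}}. A zero partial
#' correlation is equivalent to conditional independence, which is the
#' property the network-constrained simulators control.
#'
#' @param sigma symmetric positive-definite covariance matrix.
#' @return symmetric matrix of partial correlations with unit diagonal.
#' @examples
#' partialCorrelations(diag(3))             # all zero off-diagonal
#' partialCorrelations(matrix(c(1, .5, .5, 1), 2))
#' @export
partialCorrelations <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (max(abs(sigma - t(sigma))) > 1e-10)
    stop("sigma must be symmetric")
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf("sigma is not positive definite: min eigenvalue %g",
                 min(ev)))
  }
  k <- chol2inv(ch)
  d <- sqrt(diag(k))
  p <- -k / tcrossprod(d)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(sigma)
  p
}

## Partial correlations straight from a precision matrix (no inversion).
.partialFromPrecision <- function(k) {
  d <- sqrt(diag(k))
  p <- -k / tcrossprod(d)
  diag(p) <- 1
  p
}

#' Network-consistent covariance by iterative proportional scaling
#'
#' Builds a unit-diagonal covariance matrix \eqn{\Sigma} whose precision
#' matrix carries exact zeros on every non-edge of `graph` and whose marginal
#' correlation on every edge equals `targetEdgeCorrelation`. This is the
#' maximum-entropy Gaussian fit to pairwise edge constraints, computed by
#' iterative proportional scaling over edges (plus vertex margins): starting
#' from the identity precision, each edge's 2x2 precision block is updated so
#' the implied 2x2 marginal covariance matches the target block
#' \eqn{[[1, r], [r, 1]]}; sweeps repeat until \eqn{\Sigma} stabilizes.
#' Because updates only ever touch edge blocks, off-graph precision entries
#' are zero by construction.
#'
#' Pairwise (edge) sweeps rather than maximal-clique sweeps give the correct
#' fixed point for arbitrary graphs without clique enumeration, at the cost
#' of more sweeps. Each update is applied to the running covariance with a
#' rank-2 Woodbury identity, so a sweep costs O(|E| p^2).
#'
#' @param graph a [GeneNetwork-class]; must have at least one node.
#' @param targetEdgeCorrelation marginal correlation requested on every edge,
#'   in (-1, 1).
#' @param tol convergence tolerance on the maximum absolute change of
#'   \eqn{\Sigma} between sweeps.
#' @param maxIter maximum number of sweeps.
#' @param model a [CovarianceModel-class] (accessors).
#' @return a [CovarianceModel-class]
#' @examples
#' g <- geneNetwork(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' m <- ipfCovariance(g, 0.5)
#' covarianceMatrix(m)["a", "c"]   # 0.25: product along the chain
#' @export
ipfCovariance <- function(graph, targetEdgeCorrelation, tol = 1e-8,
                          maxIter = 5000L) {
  stopifnot(is(graph, "GeneNetwork"))
  if (abs(targetEdgeCorrelation) >= 1)
    stop("|targetEdgeCorrelation| must be < 1")
  p <- length(graph@nodes)
  if (p == 0)
    stop("graph must be non-empty")
  r <- targetEdgeCorrelation
  ei <- match(graph@edges[, 1], graph@nodes)
  ej <- match(graph@edges[, 2], graph@nodes)
  nE <- length(ei)
  K <- diag(p)
  Sig <- diag(p)
  target <- matrix(c(1, r, r, 1), 2)
  targetInv <- solve(target)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    SigPrev <- Sig
    for (e in seq_len(nE)) {
      idx <- c(ei[e], ej[e])
      S22 <- Sig[idx, idx]
      delta <- targetInv - solve(S22)
      if (max(abs(delta)) < .Machine$double.eps * 10) next
      K[idx, idx] <- K[idx, idx] + delta
      ## Woodbury: (K + U delta U')^{-1} = Sig - Sig_U (I + delta S22)^{-1}
      ## delta Sig_U'
      SigU <- Sig[, idx, drop = FALSE]
      M <- tryCatch(solve(diag(2) + delta %*% S22, delta),
                    error = function(e) NULL)
      if (is.null(M))
        stop(sprintf(
          "edge constraints infeasible (update for edge %s-%s singular)",
          graph@edges[e, 1], graph@edges[e, 2]))
      Sig <- Sig - SigU %*% M %*% t(SigU)
      if (any(diag(Sig) <= 0) || max(abs(K)) > 1e8)
        stop(sprintf(
          "edge constraints infeasible at target correlation %g", r))
    }
    if (nE == 0) break
    resid <- max(abs(Sig - SigPrev))
    marginResid <- max(abs(Sig[cbind(ei, ej)] - r), abs(diag(Sig) - 1))
    if (resid < tol) {
      ## with infeasible margins the sweeps stall with the constraints
      ## unmet (the maximum-entropy fit does not exist); fail fast rather
      ## than return a model missing its targets
      if (marginResid > 1e-4)
        stop(sprintf(
          "edge constraints infeasible at target correlation %g (margin residual %g)",
          r, marginResid))
      break
    }
    if (resid < marginResid * 1e-4)
      stop(sprintf(
        "edge constraints infeasible at target correlation %g (sweeps stalled at margin residual %g)",
        r, marginResid))
    if (iter >= maxIter)
      stop(sprintf(
        "iterative proportional scaling did not converge in %d sweeps (last sweep change %g)",
        maxIter, resid))
  }
  ch <- tryCatch(chol(K), error = function(e)
    stop(sprintf("edge constraints infeasible at target correlation %g", r)))
  Sig <- chol2inv(ch)
  Sig <- (Sig + t(Sig)) / 2
  dimnames(Sig) <- list(graph@nodes, graph@nodes)
  dimnames(K) <- dimnames(Sig)
  new("CovarianceModel", sigma = Sig, precision = K, graph = graph,
      targetEdgeCorrelation = r)
}

#' Network-consistent covariance by alternating projection
#'
#' Builds a unit-diagonal covariance matrix whose precision is consistent
#' with `graph` by alternating projection from a seeded random
#' positive-definite start: non-edge precision entries are zeroed (projection
#' onto the graph's sparsity subspace), then positive definiteness is
#' restored by flooring eigenvalues at 1e-6 (projection onto the SPD cone),
#' until the zero pattern and positive definiteness hold simultaneously; the
#' result is rescaled to unit diagonal, which preserves both properties.
#' Unlike [ipfCovariance()], edge-correlation magnitudes are not controlled —
#' they are whatever the projection lands on, giving a heterogeneous,
#' network-shaped correlation structure.
#'
#' @param graph a [GeneNetwork-class]
#' @param seed integer seed for the random start.
#' @param tol minimum eigenvalue regarded as positive definite when testing
#'   convergence.
#' @param maxIter maximum number of projection rounds.
#' @return a [CovarianceModel-class] with `targetEdgeCorrelation = NA`
#' @export
projectionCovariance <- function(graph, seed = 1L, tol = 1e-6,
                                 maxIter = 5000L) {
  stopifnot(is(graph, "GeneNetwork"))
  p <- length(graph@nodes)
  if (p == 0)
    stop("graph must be non-empty")
  set.seed(as.integer(seed))
  A <- matrix(rnorm(p * p), p, p)
  S0 <- crossprod(A) / p + diag(p) * 0.1
  d <- 1 / sqrt(diag(S0))
  S0 <- S0 * tcrossprod(d)
  K <- chol2inv(chol(S0))
  free <- adjacencyMatrix(graph)
  diag(free) <- TRUE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    K[!free] <- 0
    K <- (K + t(K)) / 2
    eg <- eigen(K, symmetric = TRUE)
    lmin <- min(eg$values)
    if (lmin >= tol) break
    if (iter >= maxIter)
      stop(sprintf(
        "alternating projection did not converge in %d rounds (min eigenvalue %g)",
        maxIter, lmin))
    K <- eg$vectors %*% (pmax(eg$values, 1e-6) * t(eg$vectors))
  }
  Sig <- chol2inv(chol(K))
  s <- sqrt(diag(Sig))
  Sig <- Sig / tcrossprod(s)          # unit diagonal
  K <- K * tcrossprod(s)              # congruence keeps the zero pattern
  Sig <- (Sig + t(Sig)) / 2
  K <- (K + t(K)) / 2
  dimnames(Sig) <- list(graph@nodes, graph@nodes)
  dimnames(K) <- dimnames(Sig)
  new("CovarianceModel", sigma = Sig, precision = K, graph = graph,
      targetEdgeCorrelation = NA_real_)
}

#' Verify that a covariance model matches its network
#'
#' Reports how well a [CovarianceModel-class] realizes the conditional
#' independence structure of its graph: the largest absolute partial
#' correlation on any non-edge (should be ~0), the smallest eigenvalue of
#' the covariance (must be positive), and the mean marginal correlation over
#' edges.
#'
#' @param model a [CovarianceModel-class]
#' @param tol pass threshold for the maximum off-graph partial correlation.
#' @return a list with `maxOffGraphPartial`, `minEigenvalue`,
#'   `meanOnEdgeCorrelation` and logical `pass`.
#' @export
checkConsistency <- function(model, tol = 1e-8) {
  stopifnot(is(model, "CovarianceModel"))
  pc <- partialCorrelations(model@sigma)
  free <- adjacencyMatrix(model@graph)
  diag(free) <- TRUE
  offGraph <- abs(pc)[!free]
  maxOff <- if (length(offGraph)) max(offGraph) else 0
  ev <- eigen(model@sigma, symmetric = TRUE, only.values = TRUE)$values
  edges <- model@graph@edges
  onEdge <- if (nrow(edges)) {
    i <- match(edges[, 1], model@graph@nodes)
    j <- match(edges[, 2], model@graph@nodes)
    mean(model@sigma[cbind(i, j)])
  } else NA_real_
  list(maxOffGraphPartial = maxOff,
       minEigenvalue = min(ev),
       meanOnEdgeCorrelation = onEdge,
       pass = maxOff < tol && min(ev) > 0)
}

#' Sample multivariate normal expression values
#'
#' Draws `n` iid p-variate normal samples (columns) with the given mean and
#' the model's covariance, via the Cholesky factor.
#'
#' @param mean numeric vector of length p (the model's gene count).
#' @param model a [CovarianceModel-class]
#' @param n number of samples.
#' @param seed integer seed.
#' @return p x n numeric matrix with the model's gene ids as rownames.
#' @export
sampleMVN <- function(mean, model, n, seed = 1L) {
  stopifnot(is(model, "CovarianceModel"), n >= 1)
  p <- nrow(model@sigma)
  if (length(mean) != p)
    stop(sprintf("mean has length %d but the model covers %d genes",
                 length(mean), p))
  set.seed(as.integer(seed))
  z <- matrix(rnorm(p * n), p, n)
  x <- crossprod(chol(model@sigma), z) + mean
  rownames(x) <- model@graph@nodes
  x
}
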