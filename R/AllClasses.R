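#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cov rnorm runif sd var qt pt p.adjust lm coef
#'   anova pf quantile setNames ave
#' @importFrom utils head read.table write.table
NULL

#' Undirected gene network
#'
#' A simple undirected graph over an ordered gene universe. The node order is
#' fixed and defines the row/column order of every covariance matrix and
#' expression matrix built on top of it.
#'
#' @slot nodes character vector of unique gene identifiers; the order is part
#'   of the object's identity.
#' @slot edges two-column character matrix, one row per undirected edge; no
#'   self-loops, no duplicate edges (in either orientation).
#'
#' @seealso [geneNetwork()], [readEdgeList()], [generateFixtureNetwork()]
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "matrix"))

setValidity("GeneNetwork", function(object) {
  msgs <- character()
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "node identifiers must be unique")
  e <- object@edges
  if (ncol(e) != 2 && nrow(e) > 0)
    msgs <- c(msgs, "edges must be a two-column matrix")
  if (nrow(e) > 0) {
    if (!all(e %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be network nodes")
    if (any(e[, 1] == e[, 2]))
      msgs <- c(msgs, "self-loops are not allowed")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Covariance model consistent with a gene network
#'
#' A symmetric positive-definite covariance matrix whose inverse (the
#' precision or concentration matrix) carries exact zeros on every non-edge
#' of the accompanying network, i.e. a Gaussian graphical model covariance:
#' missing edges are conditional independences.
#'
#' @slot sigma symmetric positive-definite covariance matrix (unit diagonal
#'   for the constructors in this package).
#' @slot precision the inverse of `sigma`.
#' @slot graph the [GeneNetwork-class] the model is Markov with respect to.
#' @slot targetEdgeCorrelation the marginal correlation requested on every
#'   edge by [ipfCovariance()]; `NA` for [projectionCovariance()], which does
#'   not control edge strength.
#'
#' @seealso [ipfCovariance()], [projectionCovariance()], [checkConsistency()]
#' @export
setClass("CovarianceModel",
  representation(sigma = "matrix", precision = "matrix",
                 graph = "GeneNetwork", targetEdgeCorrelation = "numeric"))

setValidity("CovarianceModel", function(object) {
  msgs <- character()
  s <- object@sigma; k <- object@precision
  p <- length(object@graph@nodes)
  if (!all(dim(s) == c(p, p)) || !all(dim(k) == c(p, p)))
    msgs <- c(msgs, "sigma and precision must be p x p for p network nodes")
  else {
    if (max(abs(s - t(s))) > 1e-10)
      msgs <- c(msgs, "sigma must be symmetric within 1e-10")
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msgs <- c(msgs, sprintf("sigma must be positive definite (min eigenvalue %g)",
                              min(ev)))
    if (max(abs(k %*% s - diag(p))) > 1e-8)
      msgs <- c(msgs, "precision %*% sigma must equal the identity within 1e-8")
  }
  if (length(msgs)) msgs else TRUE
})

#' Two-group expression data
#'
#' Expression values (genes x samples) with a two-group phenotype label,
#' stored as a [SummarizedExperiment::SummarizedExperiment-class] whose
#' `colData` carries a `group` factor with levels `control` and `treatment`.
#'
#' @seealso [groupedExpression()], [exprValues()], [groupLabels()]
#' @export
setClass("GroupedExpression", contains = "SummarizedExperiment")

setValidity("GroupedExpression", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    return("colData must contain a 'group' column")
  g <- cd$group
  if (!is.factor(g) || !identical(levels(g), c("control", "treatment")))
    msgs <- c(msgs, "group must be a factor with levels control, treatment")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene identifiers must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Named gene sets over a gene universe
#'
#' Possibly overlapping gene sets (pathways). For simulated data each set
#' carries a ground-truth flag (is the pathway truly differentially
#' expressed?) and the realized detection call, i.e. the fraction of its
#' genes actually shifted.
#'
#' @slot sets named list of character vectors (ordered member gene ids).
#' @slot truth logical vector, one flag per set.
#' @slot detectionCall numeric vector in \[0, 1\], one realized DC per set.
#'
#' @seealso [pathwayCollection()], [readGmt()], [generateFixturePathways()]
#' @export
setClass("PathwayCollection",
  representation(sets = "list", truth = "logical", detectionCall = "numeric"))

setValidity("PathwayCollection", function(object) {
  msgs <- character()
  n <- length(object@sets)
  if (is.null(names(object@sets)) && n > 0)
    msgs <- c(msgs, "sets must be named")
  if (length(object@truth) != n || length(object@detectionCall) != n)
    msgs <- c(msgs, "truth and detectionCall must have one entry per set")
  if (n > 0 && any(lengths(object@sets) < 2))
    msgs <- c(msgs, "every set must contain at least 2 genes")
  if (length(msgs)) msgs else TRUE
})

#' Simulation design
#'
#' Parameters of one simulated two-group expression study. `simType` selects
#' the generative model: `"I"` global factor correlation plus a null
#' background set, `"II"` independent per-pathway factor correlation,
#' `"III"`/`"IV"` multivariate normal sampling under a network-constrained
#' covariance (projection- and IPF-built, respectively).
#'
#' @slot simType one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @slot nPerGroup samples per condition (n1 = n2).
#' @slot rho correlation parameter in \[0, 1): global (ST I), within-pathway
#'   (ST II) or the IPF edge target (ST IV); ignored for ST III.
#' @slot detectionCall fraction of genes per truly-DE pathway that are
#'   shifted, in \[0, 1\].
#' @slot effectSize mean shift added to differentially expressed genes in the
#'   treatment group (expression is on a unit-variance scale, so this is in
#'   standard-deviation units).
#' @slot pathwaySizes,pathwaysPerSize the non-overlapping pathway grid for
#'   ST I/II.
#' @slot nBackground number of additional null background genes (ST I only).
#' @slot alpha nominal significance level.
#' @slot seed integer seed making the simulation reproducible.
#'
#' @seealso [simulationDesign()]
#' @export
setClass("SimulationDesign",
  representation(simType = "character", nPerGroup = "integer", rho = "numeric",
                 detectionCall = "numeric", effectSize = "numeric",
                 pathwaySizes = "integer", pathwaysPerSize = "integer",
                 nBackground = "integer", alpha = "numeric", seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msgs <- character()
  if (!object@simType %in% c("I", "II", "III", "IV"))
    msgs <- c(msgs, "simType must be one of I, II, III, IV")
  if (object@nPerGroup < 2L)
    msgs <- c(msgs, "nPerGroup must be at least 2")
  if (object@rho < 0 || object@rho >= 1)
    msgs <- c(msgs, "rho must lie in [0, 1)")
  if (object@detectionCall < 0 || object@detectionCall > 1)
    msgs <- c(msgs, "detectionCall must lie in [0, 1]")
  if (any(object@pathwaySizes < 2L))
    msgs <- c(msgs, "pathway sizes must be at least 2")
  if (length(msgs)) msgs else TRUE
})
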