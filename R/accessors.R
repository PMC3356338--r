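#' @rdname geneNetwork
#' @param network a [GeneNetwork-class]
#' @export
numNodes <- function(network) length(network@nodes)

#' @rdname geneNetwork
#' @export
numEdges <- function(network) nrow(network@edges)

#' @rdname geneNetwork
#' @export
networkNodes <- function(network) network@nodes

#' @rdname geneNetwork
#' @export
networkEdges <- function(network) network@edges

#' Logical adjacency matrix in node order
#' @param network a [GeneNetwork-class]
#' @return p x p logical matrix, TRUE on edges, FALSE on the diagonal
#' @export
adjacencyMatrix <- function(network) {
  p <- length(network@nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(network@nodes, network@nodes))
  if (nrow(network@edges) > 0) {
    i <- match(network@edges[, 1], network@nodes)
    j <- match(network@edges[, 2], network@nodes)
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  adj
}

#' @rdname ipfCovariance
#' @export
covarianceMatrix <- function(model) model@sigma

#' @rdname ipfCovariance
#' @export
precisionMatrix <- function(model) model@precision

#' @rdname groupedExpression
#' @param x a [GroupedExpression-class]
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname groupedExpression
#' @export
groupLabels <- function(x) SummarizedExperiment::colData(x)$group

#' @rdname groupedExpression
#' @export
nControl <- function(x) sum(groupLabels(x) == "control")

#' @rdname groupedExpression
#' @export
nTreatment <- function(x) sum(groupLabels(x) == "treatment")

#' @rdname pathwayCollection
#' @param x a [PathwayCollection-class]
#' @export
pathwaySets <- function(x) x@sets

#' @rdname pathwayCollection
#' @export
pathwayTruth <- function(x) setNames(x@truth, names(x@sets))

#' @rdname pathwayCollection
#' @export
realizedDetectionCall <- function(x) setNames(x@detectionCall, names(x@sets))

#' @describeIn pathwayCollection number of sets
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' @describeIn pathwayCollection set names
#' @export
setMethod("names", "PathwayCollection", function(x) names(x@sets))

#' @describeIn pathwayCollection extract one set's member genes by name or
#'   index
#' @param i set name or index
#' @export
setMethod("[[", "PathwayCollection", function(x, i) x@sets[[i]])

#' @describeIn pathwayCollection subset to selected pathways
#' @param j,drop,... ignored
#' @export
setMethod("[", "PathwayCollection", function(x, i, j, ..., drop = FALSE) {
  idx <- if (is.character(i)) match(i, names(x@sets)) else i
  new("PathwayCollection", sets = x@sets[idx], truth = x@truth[idx],
      detectionCall = x@detectionCall[idx])
})

#' @export
setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork with %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  cat("  nodes: ", paste(head(object@nodes, 5), collapse = ", "),
      if (length(object@nodes) > 5) ", ..." else "", "\n", sep = "")
})

#' @export
setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel over %d genes (%d graph edges)\n",
              nrow(object@sigma), nrow(object@graph@edges)))
  if (!is.na(object@targetEdgeCorrelation))
    cat(sprintf("  target edge correlation: %g\n",
                object@targetEdgeCorrelation))
})

#' @export
setMethod("show", "PathwayCollection", function(object) {
  cat(sprintf("PathwayCollection with %d sets (sizes %s), %d flagged DE\n",
              length(object@sets),
              if (length(object@sets))
                paste(range(lengths(object@sets)), collapse = "-") else "-",
              sum(object@truth)))
})

#' @export
setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: ST %s, n = %d/group, rho = %g, DC = %g, effect = %g\n",
    object@simType, object@nPerGroup, object@rho, object@detectionCall,
    object@effectSize))
})
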