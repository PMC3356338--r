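#' Construct a GeneNetwork
#'
#' @param nodes character vector of unique gene identifiers; the order fixes
#'   matrix row/column order throughout the package.
#' @param edges two-column character matrix or data.frame of undirected
#'   edges. Duplicate edges (in either orientation) are collapsed; self-loops
#'   are an error.
#' @return a [GeneNetwork-class]
#' @examples
#' g <- geneNetwork(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' numNodes(g); numEdges(g)
#' @export
geneNetwork <- function(nodes, edges = matrix(character(), 0, 2)) {
  nodes <- as.character(nodes)
  edges <- as.matrix(edges)
  if (nrow(edges) > 0) {
    storage.mode(edges) <- "character"
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(a, b))
    edges <- cbind(a[keep], b[keep])
  } else {
    edges <- matrix(character(), 0, 2)
  }
  dimnames(edges) <- NULL
  new("GeneNetwork", nodes = nodes, edges = edges)
}

#' Convert between GeneNetwork and igraph
#'
#' @param network a [GeneNetwork-class]
#' @return an [igraph::igraph] with the same vertex order
#' @export
asIgraph <- function(network) {
  g <- igraph::make_empty_graph(n = length(network@nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network@nodes)
  if (nrow(network@edges) > 0)
    g <- igraph::add_edges(g, t(network@edges))
  g
}

#' @rdname asIgraph
#' @param graph an undirected igraph; vertex names become gene ids (vertices
#'   without names are numbered).
#' @export
fromIgraph <- function(graph) {
  graph <- igraph::as_undirected(igraph::simplify(graph), mode = "collapse")
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  el <- igraph::as_edgelist(graph, names = FALSE)
  geneNetwork(nm, cbind(nm[el[, 1]], nm[el[, 2]]))
}

#' Construct two-group expression data
#'
#' @param values numeric matrix, genes x samples.
#' @param geneIds character vector of row identifiers (defaults to existing
#'   rownames).
#' @param groupLabels character/factor of length `ncol(values)` with exactly
#'   the two values `control` and `treatment` (order in the matrix is free).
#' @return a [GroupedExpression-class]
#' @examples
#' ge <- groupedExpression(matrix(rnorm(20), 4, 5),
#'                         geneIds = paste0("g", 1:4),
#'                         groupLabels = c("control", "control", "control",
#'                                         "treatment", "treatment"))
#' nControl(ge); nTreatment(ge)
#' @export
groupedExpression <- function(values, geneIds = rownames(values), groupLabels) {
  values <- as.matrix(values)
  if (is.null(geneIds))
    geneIds <- paste0("g", seq_len(nrow(values)))
  if (length(geneIds) != nrow(values))
    stop("geneIds must match the number of rows")
  if (length(groupLabels) != ncol(values))
    stop("groupLabels must match the number of columns")
  lev <- unique(as.character(groupLabels))
  if (!setequal(lev, c("control", "treatment")))
    stop("groupLabels must take exactly the two values 'control' and 'treatment'")
  rownames(values) <- geneIds
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(
      group = factor(as.character(groupLabels),
                     levels = c("control", "treatment"))))
  new("GroupedExpression", se)
}

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param truth logical per-set flag: truly differentially expressed?
#' @param detectionCall numeric per-set realized detection call in \[0, 1\].
#' @return a [PathwayCollection-class]
#' @export
pathwayCollection <- function(sets,
                              truth = rep(FALSE, length(sets)),
                              detectionCall = rep(0, length(sets))) {
  new("PathwayCollection", sets = sets, truth = truth,
      detectionCall = detectionCall)
}

#' Construct a SimulationDesign
#'
#' Defaults mirror a mid-sized two-group microarray study: pathway sizes 20
#' to 100 in steps of 20 with 10 pathways per size (50 non-overlapping
#' pathways, 3000 genes) and 7000 additional null background genes for the
#' competitive background of simulation type I.
#'
#' @param simType one of "I", "II", "III", "IV".
#' @param nPerGroup samples per condition.
#' @param rho correlation parameter in \[0, 1) (meaning depends on simType).
#' @param detectionCall fraction of genes shifted per truly-DE pathway.
#' @param effectSize mean shift in SD units (default 1).
#' @param pathwaySizes,pathwaysPerSize the ST I/II pathway grid.
#' @param nBackground null background genes for ST I.
#' @param alpha nominal significance level.
#' @param seed integer random seed.
#' @return a [SimulationDesign-class]
#' @export
simulationDesign <- function(simType = "II", nPerGroup = 20L, rho = 0,
                             detectionCall = 0.5, effectSize = 1,
                             pathwaySizes = seq(20L, 100L, by = 20L),
                             pathwaysPerSize = 10L, nBackground = 7000L,
                             alpha = 0.05, seed = 1L) {
  new("SimulationDesign", simType = as.character(simType),
      nPerGroup = as.integer(nPerGroup), rho = as.numeric(rho),
      detectionCall = as.numeric(detectionCall),
      effectSize = as.numeric(effectSize),
      pathwaySizes = as.integer(pathwaySizes),
      pathwaysPerSize = as.integer(pathwaysPerSize),
      nBackground = as.integer(nBackground),
      alpha = as.numeric(alpha), seed = as.integer(seed))
}
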