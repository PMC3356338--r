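#' Fixture specification for synthetic networks and pathway collections
#'
#' Bundles the knobs of the synthetic input generators: a
#' preferential-attachment (scale-free) gene network and a collection of
#' (optionally overlapping) pathways carved out of it as breadth-first
#' neighborhoods. These stand in for curated gene-ontology pathway sets and
#' experimentally determined interaction networks in tests and simulations.
#'
#' @param nGenes number of network nodes (genes).
#' @param edgesPerNode edges attached by each new node in the
#'   preferential-attachment growth (1 gives a tree).
#' @param nPathways number of pathways to carve.
#' @param sizeRange integer (min, max) pathway size; sizes are drawn
#'   uniformly from this range.
#' @param overlapAllowed may pathways share genes?
#' @param seed integer seed.
#' @return a `FixtureSpec` S4 object.
#' @export
fixtureSpec <- function(nGenes = 200L, edgesPerNode = 2L, nPathways = 10L,
                        sizeRange = c(10L, 20L), overlapAllowed = TRUE,
                        seed = 1L) {
  new("FixtureSpec", nGenes = as.integer(nGenes),
      edgesPerNode = as.integer(edgesPerNode),
      nPathways = as.integer(nPathways),
      sizeRange = as.integer(sizeRange),
      overlapAllowed = overlapAllowed, seed = as.integer(seed))
}

#' @rdname fixtureSpec
#' @export
setClass("FixtureSpec",
  representation(nGenes = "integer", edgesPerNode = "integer",
                 nPathways = "integer", sizeRange = "integer",
                 overlapAllowed = "logical", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  msgs <- character()
  if (object@nGenes <= object@edgesPerNode)
    msgs <- c(msgs, "nGenes must exceed edgesPerNode")
  if (any(object@sizeRange < 2L) || length(object@sizeRange) != 2L ||
      object@sizeRange[1] > object@sizeRange[2])
    msgs <- c(msgs, "sizeRange must be an increasing pair of sizes >= 2")
  if (length(msgs)) msgs else TRUE
})

#' Generate a scale-free fixture network
#'
#' Grows a connected preferential-attachment (Barabási–Albert) graph with
#' `edgesPerNode` edges per new node — the standard artificial stand-in for
#' experimentally determined protein-interaction or transcriptional
#' regulatory networks, whose degree distributions are likewise scale-free.
#'
#' @param spec a `FixtureSpec` from [fixtureSpec()].
#' @return a [GeneNetwork-class] with nodes `g0001`, `g0002`, ...
#' @export
generateFixtureNetwork <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  set.seed(spec@seed)
  g <- igraph::sample_pa(spec@nGenes, m = spec@edgesPerNode,
                         directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name",
                               value = sprintf("g%04d",
                                               seq_len(spec@nGenes)))
  fromIgraph(g)
}

#' Generate overlapping fixture pathways from a network
#'
#' Each pathway is the breadth-first neighborhood of a seeded random root,
#' truncated to a size drawn from the spec's size range — so pathways are
#' connected, network-local gene sets, mimicking the locality of biological
#' process annotations. With `overlapAllowed = FALSE` roots are redrawn and
#' members removed from the candidate pool until the collection is
#' pairwise disjoint.
#'
#' @param network a [GeneNetwork-class]
#' @param spec a `FixtureSpec` from [fixtureSpec()].
#' @return a [PathwayCollection-class] (truth flags all FALSE)
#' @export
generateFixturePathways <- function(network, spec) {
  stopifnot(is(network, "GeneNetwork"), is(spec, "FixtureSpec"))
  if (length(network@nodes) == 0)
    stop("network is empty")
  g <- asIgraph(network)
  set.seed(.deriveSeed(spec@seed, 17L))
  sizeChoices <- spec@sizeRange[1]:spec@sizeRange[2]
  sizes <- sizeChoices[sample.int(length(sizeChoices), spec@nPathways,
                                  replace = TRUE)]
  available <- network@nodes
  sets <- vector("list", spec@nPathways)
  for (i in seq_len(spec@nPathways)) {
    if (length(available) == 0)
      stop("ran out of genes for disjoint pathways")
    root <- sample(available, 1)
    bfs <- igraph::bfs(g, root = root, unreachable = FALSE)
    order <- igraph::V(g)$name[bfs$order[!is.na(bfs$order)]]
    if (!spec@overlapAllowed)
      order <- order[order %in% available]
    if (length(order) < sizes[i])
      stop(sprintf("component around root '%s' too small for size %d",
                   root, sizes[i]))
    sets[[i]] <- order[seq_len(sizes[i])]
    if (!spec@overlapAllowed)
      available <- setdiff(available, sets[[i]])
  }
  names(sets) <- sprintf("fix_pw_%02d", seq_len(spec@nPathways))
  pathwayCollection(sets)
}
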