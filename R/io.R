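#' Read and write GMT gene-set files
#'
#' The GMT dialect: one set per line, `name TAB description TAB gene TAB
#' gene ...`. Duplicate genes within a set are collapsed with a warning;
#' lines with fewer than three fields are an error.
#'
#' @param path file path.
#' @return [readGmt()]: a [PathwayCollection-class] (truth flags all FALSE).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(pathwayCollection(setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes collapsed in set '%s'", f[1]))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(fields, `[`, character(1), 1)
  descr <- vapply(fields, `[`, character(1), 2)
  out <- pathwayCollection(sets)
  attr(out, "description") <- setNames(descr, names(sets))
  out
}

#' @rdname readGmt
#' @param pathways a [PathwayCollection-class]
#' @param descriptions optional character vector of per-set descriptions.
#' @export
writeGmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- rep("na", length(pathways@sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(pathways@sets), descriptions, pathways@sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read and write labeled expression matrices as TSV
#'
#' Format: first header row holds the sample labels (exactly two distinct
#' values), the first column holds gene ids, the body is numeric. Labels
#' other than `control`/`treatment` are mapped in order of first appearance
#' (first label seen becomes `control`). Values are written with 17
#' significant digits so a round trip is bit-exact.
#'
#' @param path file path.
#' @return [readExpressionTsv()]: a [GroupedExpression-class]
#' @export
readExpressionTsv <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  labels <- header[-1]
  lev <- unique(labels)
  if (length(lev) != 2)
    stop(sprintf("expected exactly 2 distinct sample labels, found %d",
                 length(lev)))
  body <- read.table(path, sep = "\t", skip = 1, header = FALSE,
                     colClasses = c("character", rep("numeric",
                                                     length(labels))),
                     check.names = FALSE)
  if (ncol(body) != length(labels) + 1)
    stop("body width does not match the header")
  m <- as.matrix(body[, -1, drop = FALSE])
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (anyNA(m)) {
    w <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-numeric value at gene '%s', sample %d",
                 body[[1]][w[1]], w[2]))
  }
  mapped <- if (setequal(lev, c("control", "treatment"))) labels
            else c("control", "treatment")[match(labels, lev)]
  groupedExpression(m, body[[1]], mapped)
}

#' @rdname readExpressionTsv
#' @param data a [GroupedExpression-class]
#' @export
writeExpressionTsv <- function(data, path) {
  v <- exprValues(data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", as.character(groupLabels(data))),
                   collapse = "\t"), con)
  body <- apply(v, 1, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Read an undirected network from an edge list or GraphML
#'
#' Edge lists are whitespace/tab separated, two gene ids per line, `#`
#' comments ignored; duplicate edges are collapsed. `giantComponent = TRUE`
#' (the default for loaded external networks) restricts the result to the
#' largest connected component.
#'
#' @param path file path.
#' @param giantComponent restrict to the giant connected component?
#' @return a [GeneNetwork-class]
#' @export
readEdgeList <- function(path, giantComponent = TRUE) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(geneNetwork(character()))
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 2)
  if (length(bad))
    stop(sprintf("edge-list line %d does not have two columns", bad[1]))
  e <- t(vapply(fields, function(f) f[1:2], character(2)))
  net <- geneNetwork(unique(as.vector(t(e))), e)
  if (giantComponent) .giantComponent(net) else net
}

#' @rdname readEdgeList
#' @export
readGraphML <- function(path, giantComponent = TRUE) {
  g <- igraph::read_graph(path, format = "graphml")
  net <- fromIgraph(g)
  if (giantComponent) .giantComponent(net) else net
}

.giantComponent <- function(network) {
  g <- asIgraph(network)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  fromIgraph(igraph::induced_subgraph(g, keep))
}

#' Write a covariance matrix as TSV with gene-id headers
#'
#' @param model a [CovarianceModel-class] or plain matrix with dimnames.
#' @param path file path.
#' @export
writeCovarianceTsv <- function(model, path) {
  m <- if (is(model, "CovarianceModel")) model@sigma else model
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCovarianceTsv
#' @return [readCovarianceTsv()]: a numeric matrix with gene-id dimnames.
#' @export
readCovarianceTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write the simulation truth sidecar as JSON
#'
#' Records per-pathway truth flags and realized detection calls so a
#' simulated dataset exported as TSV + GMT stays fully self-describing.
#'
#' @param pathways a [PathwayCollection-class]
#' @param path file path.
#' @export
writeTruthJson <- function(pathways, path) {
  jsonlite::write_json(
    list(pathways = names(pathways@sets),
         truth = pathways@truth,
         detectionCall = pathways@detectionCall),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
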