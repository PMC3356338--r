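## Deterministic derived seeds: distinct streams for sub-steps of one design
## without consuming the caller's RNG state. Kept below 2^31.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

## Non-overlapping pathway grid for ST I/II: gene ids in fixed order, sets
## partitioning the universe.
.designPathways <- function(design) {
  sizes <- rep(design@pathwaySizes, each = design@pathwaysPerSize)
  total <- sum(sizes)
  genes <- sprintf("g%05d", seq_len(total))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  sets <- lapply(seq_along(sizes), function(i) genes[starts[i]:ends[i]])
  names(sets) <- sprintf("pw_s%03d_%02d", sizes,
                         ave(sizes, sizes, FUN = seq_along))
  list(genes = genes, sets = sets, sizes = sizes)
}

## Apply the detection-call mean shift to the treatment columns: the first
## ceiling(DC * size) genes of each truly-DE pathway, in gene order.
## signSplit = FALSE shifts all by +effect; TRUE shifts half by +effect and
## half by -effect (odd counts: extra gene positive), assigning each gene at
## most once when pathways overlap.
.applyDcShift <- function(values, treatIdx, sets, geneIds, dc, effect,
                          signSplit = FALSE) {
  shift <- rep(0, length(geneIds))
  names(shift) <- geneIds
  assigned <- rep(FALSE, length(geneIds))
  names(assigned) <- geneIds
  for (s in sets) {
    k <- ceiling(dc * length(s))
    if (k == 0) next
    sel <- s[seq_len(k)]
    if (signSplit) {
      npos <- ceiling(k / 2)
      sgn <- rep(c(1, -1), c(npos, k - npos))
    } else {
      sgn <- rep(1, k)
    }
    fresh <- !assigned[sel]
    shift[sel[fresh]] <- effect * sgn[fresh]
    assigned[sel] <- TRUE
  }
  values[, treatIdx] <- values[, treatIdx] + shift
  values
}

.truthFlags <- function(sets, dc) {
  k <- vapply(sets, function(s) ceiling(dc * length(s)), numeric(1))
  list(truth = k > 0, dcRealized = k / lengths(sets))
}

#' Simulate uncorrelated two-group expression data
#'
#' Every entry is an iid standard-normal draw; the treatment group is then
#' shifted by `+effectSize` on the first \eqn{\lceil DC \cdot size \rceil}
#' genes of every pathway. Pathways are non-overlapping and partition the
#' gene universe according to the design's size grid.
#'
#' @param design a [SimulationDesign-class] with `rho = 0`.
#' @return a list with `expression` ([GroupedExpression-class]) and
#'   `pathways` ([PathwayCollection-class], truth flags and realized
#'   detection calls filled in).
#' @export
simulateUncorrelated <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  if (design@rho != 0)
    stop("simulateUncorrelated requires rho = 0; use simulateType1/2")
  .simulateFactorType(design, perPathwayFactor = FALSE, background = FALSE)
}

#' Impose a constant average correlation via a shared factor
#'
#' Transforms a unit-variance matrix \eqn{Z} into
#' \eqn{\sqrt{1-\rho}\, Z + \sqrt{\rho}\, \mathbf{1} z'}, adding one
#' standard-normal draw per sample (column) to every gene (row), so that
#' every pair of genes has population correlation \eqn{\rho} while marginal
#' variances stay at 1. With `rho = 0` the input is returned unchanged.
#'
#' @param values numeric matrix (genes x samples) of unit-variance values.
#' @param rho average correlation in \[0, 1).
#' @param seed integer seed for the factor draws.
#' @return a matrix of the same shape.
#' @export
applyFactorCorrelation <- function(values, rho, seed = 1L) {
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  if (rho == 0) return(values)
  set.seed(as.integer(seed))
  z <- rnorm(ncol(values))
  sqrt(1 - rho) * values +
    sqrt(rho) * matrix(z, nrow(values), ncol(values), byrow = TRUE)
}

## Shared engine for ST I (global factor, optional background) and ST II
## (per-pathway factors). The DC shift is applied after the correlation
## transform so the realized mean difference is exactly effectSize.
.simulateFactorType <- function(design, perPathwayFactor, background) {
  pw <- .designPathways(design)
  n <- design@nPerGroup
  labels <- rep(c("control", "treatment"), each = n)
  treatIdx <- which(labels == "treatment")
  set.seed(design@seed)
  vals <- matrix(rnorm(length(pw$genes) * 2 * n), length(pw$genes), 2 * n)
  rownames(vals) <- pw$genes
  if (design@rho > 0) {
    if (perPathwayFactor) {
      for (i in seq_along(pw$sets)) {
        idx <- match(pw$sets[[i]], pw$genes)
        vals[idx, ] <- applyFactorCorrelation(vals[idx, , drop = FALSE],
                                              design@rho,
                                              .deriveSeed(design@seed, i))
      }
    } else {
      vals <- applyFactorCorrelation(vals, design@rho,
                                     .deriveSeed(design@seed, 0L))
    }
  }
  vals <- .applyDcShift(vals, treatIdx, pw$sets, pw$genes,
                        design@detectionCall, design@effectSize)
  tf <- .truthFlags(pw$sets, design@detectionCall)
  out <- list(
    expression = groupedExpression(vals, pw$genes, labels),
    pathways = pathwayCollection(pw$sets, tf$truth, tf$dcRealized))
  if (background) {
    set.seed(.deriveSeed(design@seed, 1L))
    bg <- matrix(rnorm(design@nBackground * 2 * n), design@nBackground, 2 * n)
    rownames(bg) <- sprintf("bg%05d", seq_len(design@nBackground))
    if (design@rho > 0)
      bg <- applyFactorCorrelation(bg, design@rho,
                                   .deriveSeed(design@seed, 2L))
    out$background <- groupedExpression(bg, rownames(bg), labels)
  }
  out
}

#' Simulation type I: global correlation plus a null background set
#'
#' Pathway data are generated as in [simulateUncorrelated()] and a single
#' shared factor is applied across all genes jointly, giving every gene pair
#' the same population correlation `rho`. A separate background dataset of
#' `nBackground` null genes — no expression difference between the groups —
#' is generated with the same global correlation; it serves as the
#' competitive background for GSEA.
#'
#' @param design a [SimulationDesign-class] with `simType = "I"`.
#' @return list with `expression`, `pathways` and `background`
#'   (a [GroupedExpression-class] of null genes).
#' @export
simulateType1 <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  if (design@simType != "I")
    stop("design@simType must be 'I'")
  .simulateFactorType(design, perPathwayFactor = FALSE, background = TRUE)
}

#' Simulation type II: independent within-pathway correlation
#'
#' Each pathway receives its own independent shared factor, so genes within
#' a pathway have population correlation `rho` while the between-pathway
#' population correlation is exactly 0.
#'
#' @param design a [SimulationDesign-class] with `simType = "II"`.
#' @return list with `expression` and `pathways`.
#' @export
simulateType2 <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  if (design@simType != "II")
    stop("design@simType must be 'II'")
  .simulateFactorType(design, perPathwayFactor = TRUE, background = FALSE)
}

#' Simulation types III/IV: network-constrained correlation structure
#'
#' Both groups are sampled from the multivariate normal distribution of a
#' network-consistent [CovarianceModel-class] (from [projectionCovariance()]
#' for ST III or [ipfCovariance()] for ST IV). The control group has mean
#' zero; in the treatment group, each truly-DE pathway has
#' \eqn{\lceil DC \cdot size \rceil} genes shifted, half by `+effectSize`
#' and half by `-effectSize` (odd counts: the extra gene positive). Pathways
#' may overlap; an overlapping gene keeps the shift of the first pathway
#' that claims it.
#'
#' @param design a [SimulationDesign-class] with `simType` `"III"` or
#'   `"IV"`.
#' @param model a [CovarianceModel-class] covering the pathway gene
#'   universe.
#' @param pathways a [PathwayCollection-class] over the model's genes.
#' @return list with `expression` and `pathways` (truth flags updated).
#' @export
simulateNetworkType <- function(design, model, pathways) {
  stopifnot(is(design, "SimulationDesign"), is(model, "CovarianceModel"),
            is(pathways, "PathwayCollection"))
  if (!design@simType %in% c("III", "IV"))
    stop("design@simType must be 'III' or 'IV'")
  genes <- model@graph@nodes
  missing <- setdiff(unique(unlist(pathways@sets)), genes)
  if (length(missing))
    stop(sprintf("pathway genes absent from the covariance model: %s",
                 paste(head(missing, 5), collapse = ", ")))
  n <- design@nPerGroup
  ctrl <- sampleMVN(rep(0, length(genes)), model, n,
                    seed = .deriveSeed(design@seed, 3L))
  treat <- sampleMVN(rep(0, length(genes)), model, n,
                     seed = .deriveSeed(design@seed, 4L))
  vals <- cbind(ctrl, treat)
  colnames(vals) <- paste0("s", seq_len(2 * n))
  labels <- rep(c("control", "treatment"), each = n)
  vals <- .applyDcShift(vals, which(labels == "treatment"), pathways@sets,
                        genes, design@detectionCall, design@effectSize,
                        signSplit = TRUE)
  tf <- .truthFlags(pathways@sets, design@detectionCall)
  list(expression = groupedExpression(vals, genes, labels),
       pathways = pathwayCollection(pathways@sets, tf$truth, tf$dcRealized))
}
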