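## Generate one dataset for a design, dispatching on simulation type.
## model/pathways are required for ST III/IV.
.simulateDesign <- function(design, model = NULL, pathways = NULL) {
  switch(design@simType,
    I = simulateType1(design),
    II = simulateType2(design),
    {
      if (is.null(model) || is.null(pathways))
        stop("simulation types III/IV need a CovarianceModel and a PathwayCollection")
      simulateNetworkType(design, model, pathways)
    })
}

.bootstrapSd <- function(perRun, nBoot = 200L, seed = 1L) {
  if (length(perRun) < 2) return(0)
  set.seed(as.integer(seed))
  m <- vapply(seq_len(nBoot), function(b)
    mean(perRun[sample.int(length(perRun), replace = TRUE)]), numeric(1))
  sd(m)
}

.withSeed <- function(design, seed) {
  design@seed <- as.integer(seed)
  design
}

## Shared engine for estimatePower / estimateFpr: runs the simulation nRuns
## times, tests every pathway, and pools rejection fractions over
## (pathway, run) pairs restricted to `subset` ("true" or "null").
.assess <- function(design, method, nRuns, B, seed, model, pathways,
                    subset = c("true", "null")) {
  subset <- match.arg(subset)
  perRun <- numeric(nRuns)
  perRunCount <- numeric(nRuns)
  sizes <- NULL
  hitBySize <- list()
  for (run in seq_len(nRuns)) {
    runSeed <- .deriveSeed(seed, run)
    sim <- .simulateDesign(.withSeed(design, runSeed), model, pathways)
    res <- testPathways(sim$expression, sim$pathways, method, B = B,
                       alpha = design@alpha, background = sim$background,
                       seed = .deriveSeed(runSeed, 101L))
    keep <- if (subset == "true") sim$pathways@truth else !sim$pathways@truth
    rej <- res$pValue <= design@alpha
    perRun[run] <- mean(rej[keep])
    perRunCount[run] <- sum(rej)
    sz <- lengths(sim$pathways@sets)[keep]
    hitBySize[[run]] <- tapply(rej[keep], sz, mean)
  }
  est <- mean(perRun)
  out <- data.frame(
    simType = design@simType, method = method, nPerGroup = design@nPerGroup,
    rho = design@rho, detectionCall = design@detectionCall,
    effectSize = design@effectSize, alpha = design@alpha,
    power = if (subset == "true") est else NA_real_,
    fpr = if (subset == "null") est else NA_real_,
    nSignificant = mean(perRunCount),
    sdPower = if (subset == "true")
      .bootstrapSd(perRun, seed = .deriveSeed(seed, 901L)) else NA_real_,
    sdFpr = if (subset == "null")
      .bootstrapSd(perRun, seed = .deriveSeed(seed, 902L)) else NA_real_,
    sdCount = .bootstrapSd(perRunCount, seed = .deriveSeed(seed, 903L)),
    nRuns = as.integer(nRuns), stringsAsFactors = FALSE)
  sizeTabs <- do.call(rbind, lapply(hitBySize, function(h)
    h[order(as.integer(names(h)))]))
  attr(out, "bySize") <- colMeans(sizeTabs)
  out
}

#' Estimate the power of a pathway test by repeated simulation
#'
#' Simulates `nRuns` datasets under the design, tests every pathway, and
#' estimates the power as the fraction of (truly-DE pathway, run) pairs with
#' \eqn{p \le \alpha}; the standard deviation comes from 200 bootstrap
#' resamples of the per-run fractions. A per-pathway-size breakdown of the
#' rejection fraction is attached as attribute `"bySize"`.
#'
#' @param design a [SimulationDesign-class] with `detectionCall > 0`.
#' @param method `"gsea"`, `"hotelling"` or `"sumt2"`.
#' @param nRuns number of independent simulated datasets.
#' @param B permutations per pathway test.
#' @param seed master integer seed; per-run seeds are derived
#'   deterministically from it.
#' @param model,pathways required for simulation types III/IV: the
#'   [CovarianceModel-class] and [PathwayCollection-class] to simulate from.
#' @return one-row data.frame (design columns, `power`, `nSignificant`,
#'   bootstrap SDs, `nRuns`).
#' @export
estimatePower <- function(design, method, nRuns = 10L, B = 1000L, seed = 1L,
                          model = NULL, pathways = NULL) {
  stopifnot(is(design, "SimulationDesign"), nRuns >= 1)
  if (design@detectionCall == 0)
    stop("detectionCall is 0: no truly-DE pathways; use estimateFpr")
  .assess(design, method, nRuns, B, seed, model, pathways, subset = "true")
}

#' Estimate the false-positive rate of a pathway test
#'
#' Forces the detection call to zero — no differentially expressed pathways
#' — and reports the fraction of (null pathway, run) pairs with
#' \eqn{p \le \alpha}, which estimates the type-I error at level alpha.
#'
#' @inheritParams estimatePower
#' @return one-row data.frame as in [estimatePower()], with `fpr` filled.
#' @export
estimateFpr <- function(design, method, nRuns = 10L, B = 1000L, seed = 1L,
                        model = NULL, pathways = NULL) {
  stopifnot(is(design, "SimulationDesign"), nRuns >= 1)
  design@detectionCall <- 0
  .assess(design, method, nRuns, B, seed, model, pathways, subset = "null")
}

#' Count significant results
#'
#' @param results data.frame with a `pValue` column (from [testPathways()]).
#' @param alpha significance level.
#' @return number of pathways with \eqn{p \le \alpha}.
#' @export
countSignificant <- function(results, alpha = 0.05) {
  sum(results$pValue <= alpha)
}

#' Run a grid of designs and methods
#'
#' Executes the Cartesian product of designs and methods with
#' deterministically derived per-cell seeds; a failing cell is recorded
#' (its error message in the `error` column) and the grid continues.
#'
#' @param designs list of [SimulationDesign-class] objects.
#' @param methods character vector of method names.
#' @param nRuns,B,seed as in [estimatePower()].
#' @param model,pathways passed through for ST III/IV designs.
#' @return data.frame of assessment rows sorted by (simType, method,
#'   nPerGroup, detectionCall, rho), with an `error` column.
#' @export
runGrid <- function(designs, methods, nRuns = 10L, B = 1000L, seed = 1L,
                    model = NULL, pathways = NULL) {
  cells <- expand.grid(d = seq_along(designs), m = seq_along(methods))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    design <- designs[[cells$d[k]]]
    method <- methods[cells$m[k]]
    cellSeed <- .deriveSeed(seed, k)
    rows[[k]] <- tryCatch({
      row <- if (design@detectionCall > 0)
        estimatePower(design, method, nRuns, B, cellSeed, model, pathways)
      else
        estimateFpr(design, method, nRuns, B, cellSeed, model, pathways)
      row$error <- NA_character_
      attr(row, "bySize") <- NULL
      row
    }, error = function(e) {
      data.frame(simType = design@simType, method = method,
                 nPerGroup = design@nPerGroup, rho = design@rho,
                 detectionCall = design@detectionCall,
                 effectSize = design@effectSize, alpha = design@alpha,
                 power = NA_real_, fpr = NA_real_, nSignificant = NA_real_,
                 sdPower = NA_real_, sdFpr = NA_real_, sdCount = NA_real_,
                 nRuns = as.integer(nRuns), error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out[order(out$simType, out$method, out$nPerGroup, out$detectionCall,
            out$rho), , drop = FALSE]
}
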