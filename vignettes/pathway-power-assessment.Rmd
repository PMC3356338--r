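---
title: "Assessing power and error of pathway differential-expression tests"
author: "pathwayPower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing power and error of pathway differential-expression tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayPower)
```

# The problem

Gene-set (pathway) tests ask whether the joint expression of a predefined
group of genes differs between two phenotype groups. Before committing a
study design to such a test, one wants to know its statistical power and
its type-I error under realistic conditions — in particular under realistic
*correlation* among genes, which simple simulation designs (independent
genes, compound symmetry) do not provide. pathwayPower implements a
simulation and resampling framework for exactly this assessment: three
pathway statistics with permutation nulls, four simulation types of
increasing structural realism, harnesses that estimate power and
false-positive rate (FPR) over parameter grids, and a bootstrap
surrogate-data pipeline for real labeled expression matrices.

# The three pathway statistics

All three operate on a genes-by-samples matrix with a two-group label
(`control` of size $n_1$, `treatment` of size $n_2$) and on a gene set $S$
of size $p$.

**Sum of t-square** (self-contained, univariate). With the pooled-variance
two-sample t statistic $t_i$ per gene, the pathway statistic is
$\sum_{i \in S} t_i^2$. Genes with zero pooled variance contribute $t_i = 0$
(with a warning); this keeps the sum finite and is conservative.

**Hotelling's $T^2$** (self-contained, multivariate).
$$T^2 = \frac{n_1 n_2}{n_1 + n_2}\; \bar d^{\,\prime}\, \hat K\, \bar d,$$
where $\bar d$ is the difference of the group mean vectors over $S$ and
$\hat K$ estimates the inverse of the pooled covariance matrix
$S_{pool} = \big((n_1{-}1)S_1 + (n_2{-}1)S_2\big)/(n_1+n_2-2)$. Because
pathway sizes routinely exceed sample sizes, $\hat K$ is a shrinkage
estimate: the pooled correlation matrix is shrunk toward the identity with
the analytic intensity
$\lambda^\ast = \sum_{i \neq j}\widehat{\mathrm{var}}(r_{ij}) \big/
\sum_{i \neq j} r_{ij}^2$ (diagonal, unequal-variance target), clipped to
$[0,1]$, and the shrunk covariance is inverted. When all sample
correlations are exactly zero, $\lambda$ is defined as 1 (fully diagonal),
the limiting value. With `shrinkageIntensity = 0` and $p = 1$ the statistic
reduces to the squared pooled t, which the tests verify to $10^{-10}$.

**GSEA enrichment score** (competitive). Genes are ranked by their signed
statistic (ties broken deterministically by gene id) and a weighted running
sum is walked down the list: a member at rank $i$ adds
$|t_i|^q / N_R$ ($N_R$ = sum of member weights), a non-member subtracts
$1/(N - N_H)$. The enrichment score (ES) is the running-sum value of
maximal absolute deviation, signed; on (numerically) tied deviations the
earliest list position wins, which makes the score reproducible to the last
bit. The default weight exponent is $q = 1$; $q = 0$ gives the unweighted
Kolmogorov–Smirnov form.

## Permutation nulls

Self-contained statistics use sample-label permutations: labels are
permuted $B$ times, the statistic is **fully recomputed** each time
(including the shrinkage intensity for $T^2$), and the p-value is the
add-one estimator $p = (1 + \#\{T^\ast \ge T\})/(1 + B)$, which never
returns 0 and satisfies $p \ge 1/(B+1)$. For small samples an exact mode
enumerates all distinct group assignments.

For GSEA, significance of $|ES|$ (two-sided; the alternative is a
non-vanishing score of either sign) can be assessed against two different
nulls, and the choice matters:

* `gseaNull = "sample"` (default) permutes the phenotype labels and
  recomputes the entire ranking per permutation. This preserves the
  gene–gene correlation structure under the null and is exact for
  exchangeable samples, so the FPR stays at its nominal level even for
  strongly correlated null data.
* `gseaNull = "gene"` draws random gene subsets of the set's size from the
  ranked universe (equivalent to permuting gene labels for a single set).
  It is much cheaper but ignores within-set correlation: correlated member
  genes move together in the ranking, inflating the observed $|ES|$
  relative to scattered random subsets. On within-pathway-correlated null
  data ($\rho = 0.5$) we measure an FPR of roughly 0.65 at nominal 0.05.

The gene-label null is the literal reading of the classic four-step GSEA
recipe, but the correlation-preserving phenotype permutation is the GSEA
method's own default for significance estimation and is the only variant
whose FPR control survives correlated data. Hence the default.

As a competitive test GSEA needs background genes. Simulation type I
supplies an explicit null background dataset; for all other inputs the
complement of the tested pathway within the data serves as background.

# The four simulation types

All simulators produce unit-variance Gaussian expression with a known
ground truth. Differential expression is controlled by the *detection call*
(DC): the fraction of genes per pathway that are shifted. The shifted genes
are the first $\lceil DC \cdot p \rceil$ in gene order — a deterministic
choice that makes the realized DC exactly reproducible — and the shift is
applied *after* any correlation transform, so the realized mean difference
equals the effect size (default 1 SD) exactly.

* **ST I** — a global factor correlation: data for all genes are
  transformed as $\sqrt{1-\rho}\,Z + \sqrt{\rho}\,\mathbf{1}z'$, one shared
  standard-normal draw per sample, giving every gene pair population
  correlation $\rho$ and leaving marginal variances at 1. A separate
  background set (default 7000 genes) is generated with the same global
  correlation and no group difference.
* **ST II** — the same transform applied per pathway with independent
  factors: within-pathway correlation $\rho$, between-pathway correlation
  exactly 0.
* **ST III / ST IV** — samples drawn from a Gaussian graphical model whose
  precision matrix is consistent with a gene network (see below); ST III
  uses the alternating-projection construction (uncontrolled edge
  strengths), ST IV the iterative-proportional-scaling construction with a
  common edge correlation target. Shifted genes split half $+$effect, half
  $-$effect (odd counts: the extra gene positive); overlapping pathways
  assign each gene at most once, first claim wins.

The default ST I/II pathway grid — sizes 20 to 100 in steps of 20, 10
pathways per size (50 non-overlapping pathways, 3000 genes) — is a
mid-sized two-group microarray layout; every value is overridable in the
`SimulationDesign`.

# Network-consistent covariance construction

For a multivariate normal vector, zeros in the precision matrix
$K = \Sigma^{-1}$ are exactly the missing edges of the conditional
independence graph: the partial correlation is
$\rho_{ij|rest} = -k_{ij}/\sqrt{k_{ii}k_{jj}}$. To simulate expression that
is Markov with respect to a gene network, two constructions are provided.

**`ipfCovariance`** computes the maximum-entropy Gaussian whose marginal
correlation on every edge equals a target $r$ and whose precision is zero
on every non-edge. It iterates proportional scaling over *edges* (plus
vertex margins) rather than maximal cliques: each edge's $2\times2$
precision block is updated so the implied marginal matches
$\begin{pmatrix}1 & r\\ r & 1\end{pmatrix}$, applied to the running
covariance with a rank-2 Woodbury identity ($O(|E|\,p^2)$ per sweep).
Pairwise sweeps give the correct fixed point on arbitrary, including
non-decomposable, graphs without clique enumeration, at the cost of more
sweeps. Because updates only touch edge blocks, non-edge precision entries
are exactly zero by construction. Sweeps stop when $\Sigma$ changes by
less than `tol` ($10^{-8}$ by default, at most 5000 sweeps). On trees the
result has the closed form $\sigma_{ij} = \prod r$ along the unique
connecting path, which the tests verify to $10^{-6}$ on 200-node graphs.

Some targets are infeasible — on a triangle with all-pairs target
$-0.6$ no positive-definite solution exists. Infeasibility manifests as
sweeps stalling with unmet margins (or the precision blowing up); both are
detected and raised as errors rather than silently shrinking the target.

**`projectionCovariance`** starts from a seeded random positive-definite
matrix and alternates two projections: zero the non-edge precision entries
(the graph's sparsity subspace), then floor eigenvalues at $10^{-6}$ (the
positive-definite cone), until both hold simultaneously; the final rescale
to unit diagonal preserves both properties. Edge strengths are not
controlled — they are whatever the projection lands on — which yields a
heterogeneous, network-shaped correlation structure complementary to the
IPF construction. Only the consistency contract is promised, and
`checkConsistency` reports the maximal off-graph partial correlation, the
minimal eigenvalue and the mean on-edge correlation of any model.

# Power, FPR, and the surrogate pipeline

`estimatePower` simulates `nRuns` datasets, tests every pathway, and pools
the rejection fraction over (truly-DE pathway, run) pairs; pooling reduces
variance, and a per-pathway-size breakdown is attached for size-dependent
diagnostics. `estimateFpr` forces DC to 0 — the no-differentially-expressed-
pathways case — and reports the rejection fraction over null pathways.
Error bars are standard deviations over 200 bootstrap resamples of the
per-run estimates. `runGrid` executes design-by-method grids with
deterministically derived per-cell seeds; a failing cell is recorded and
the grid continues.

The surrogate pipeline transfers the assessment to a real labeled matrix
without claiming biological truth: pathways significant on the *full*
dataset form a reference list, bootstrap subsamples (stratified within
condition, preserving the two-group design) are tested at reduced sample
sizes, and calls are scored against the reference as TP/FP/TN/FN, giving
power and FPR *relative to the full-sample result*. The reference may of
course contain false declarations; the curves measure robustness, not
truth. Regressing the distance to convergence — operationalized as
$1 - \mathrm{power}$ at each probed size, with the plateau taken where
power reaches 1 — on sample size and intersecting the fitted line with zero
predicts the minimal adequate per-group sample size, with the regression's
F statistic quantifying the fit.

Two descriptive tools round this off: `pathwayCorrelationProfile` (mean
pairwise within-pathway correlation per pathway, sorted, against the
overall mean over all gene pairs — computed exactly below 2000 genes,
otherwise by seeded subsampling of $10^5$ pairs) and
`estimateDcDistribution` (per-gene t tests with Benjamini–Hochberg
correction, giving each pathway's empirical detection call).

# Numerical and design choices

* Matrix row order = network node order = expression gene order; one
  ordered gene universe is threaded through all modules.
* Tolerances: IPF consistency $10^{-8}$, projection $10^{-6}$; symmetry
  enforced to $10^{-10}$; validity of every `CovarianceModel` checks
  $K\Sigma = I$ to $10^{-8}$.
* All randomness is seeded; sub-streams (per run, per cell, per pathway)
  use seeds derived as a fixed affine map of the master seed, so parallel
  and serial execution and any re-run are bit-identical.
* p-values always use the add-one estimator; `alpha = 0` therefore rejects
  nothing, `alpha = 1` everything.
* Per-gene significance in the DC estimator uses the pooled-variance t
  with BH correction — a deliberate simplification of moderated
  alternatives; no fudge-factor regularization is applied.
* The synthetic fixtures use a preferential-attachment network and
  BFS-neighborhood pathways: connected, network-local, optionally
  overlapping gene sets that mimic the locality of curated biological
  process annotations. They stand in for experimentally determined
  interaction networks and curated pathway collections; degree
  distributions are scale-free like those networks, but they do not
  reproduce their clustering or community structure.

## Problem sizes used in the shipped checks

The test suite exercises the framework at deliberately scaled-down sizes
chosen once as representative: FPR calibration on 100 null pathways
(3000–6000 genes) over 5 simulation runs with 200 permutations; the
network constructions on 200-node graphs; power grids on a 150-gene
fixture network with 10 overlapping pathways, 3 runs and 100 permutations.
These sizes give binomial/Monte-Carlo standard errors small enough for the
stated tolerance bands while keeping a full run in minutes.

# What the checks do and do not show

Two behaviors are asserted as-is in the acceptance tests and fail there by
design; both are properties of the statistics, not defects of the code:

* **Hotelling FPR vs pathway size.** Shrinkage-based $T^2$ is widely
  reported to lose FPR control once pathways grow much larger than the
  sample. With the permutation null used here — statistic fully recomputed,
  shrinkage intensity included, under each label permutation — the test is
  exact under the exchangeable null for *any* pathway size, and measured
  FPRs for sizes 10 and 80 both sit inside the 99% calibration band. Such
  inflation can only arise from shortcuts in the null assessment (a pooled
  or asymptotic null, or a precision matrix estimated once and held fixed
  across permutations); this package takes none of them, so the
  corresponding directional assertion stays red.
* **GSEA power vs detection call on network data.** On ST III/IV data
  *every* pathway is truly differentially expressed, so the competitive
  background is itself shifted; raising DC shifts the background more and
  GSEA power *drops* (measured: DC 0.5 → power 0.23/0.40/0.60 across
  n = 10/20/40; DC 1 → ≈ 0). A competitive test has no signal when all
  pathways change, so a blanket power-monotonicity expectation in DC cannot
  hold for it.

Passing tests on these simulators demonstrate calibration and power under
Gaussian, unit-variance, constant-effect-size conditions with factor- or
network-structured correlation. Real expression data add heavy tails,
heterogeneous variances and effect sizes, batch effects and annotation
error, none of which the generators emulate; the surrogate pipeline exists
precisely to carry the assessment onto real data, at the price of a
reference list that is itself an estimate.

# Limitations

* Gaussian marginals only; no count models for RNA-seq.
* Constant effect size per gene; heterogeneous effect-size distributions
  are out of scope.
* Network inference from data is out of scope: networks are inputs.
* No multiple-testing correction inside the power analysis (the
  uncorrected per-pathway level is the quantity under study); BH is used
  only in the detection-call estimator.
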