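---
title: "Multi-kernel BLUP for phenotype prediction: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel BLUP for phenotype prediction: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicblup)
```

## The problem

In panels of fully inbred lines — genotyped once, phenotyped as line means —
genomic prediction asks how well a line's phenotype can be predicted from
its relatives' phenotypes, with relatedness measured on some molecular
layer. `omicblup` implements five such predictors that differ only in which
similarity kernel(s) enter one common linear mixed model:

$$y = 1\mu + \textstyle\sum_k u_k + e, \qquad
  u_k \sim N(0, K_k\,\sigma_k^2), \quad e \sim N(0, I\,\sigma_e^2)$$

| model  | kernels | similarity measured on |
|--------|---------|------------------------|
| gblup  | $G$             | genome-wide SNP dosages |
| tblup  | $E = RR'$       | standardized expression, linear |
| rkhs   | $K(h)$          | standardized expression, Gaussian |
| gtblup | $G + E$         | both layers |
| grblup | $G + K(h)$      | both layers |

The scientific motivation for the two-kernel models is that regulatory
interactions between loci (epistasis) that are invisible to an additive
SNP kernel can surface as *additive* signal on the transcriptome: a
product of two genotypes is just another covariate once it has been
transcribed. The simulator in this package (below) encodes exactly that
mechanism, which makes the central qualitative claim — that the combined
genomic + Gaussian-expression model explains more phenotypic variance than
GBLUP when expression-mediated variance exists — testable end to end at
desk scale.

## Kernels

**Genomic kernel.** Dosages (counts of the minor allele; the kernel is
provably invariant to which allele is counted) are centered by twice the
allele frequency, $Z_{ij} = x_{ij} - 2p_j$, and
$G = ZZ' / \big(2\sum_j p_j(1-p_j)\big)$. The denominator is stored in the
kernel's metadata because it reappears in the ridge-duality identity
(tested): GBLUP's line effects equal $Z\hat\beta$ where $\hat\beta$ solves a
ridge regression with penalty $\lambda = \hat\sigma_e^2/\hat\sigma_g^2
\cdot 2\sum_j p_j(1-p_j)$.

**Expression kernels.** Expression levels are column-standardized,
$r_{ij} = (x_{ij} - \bar x_j)/s_j$, using the sample ($n-1$) standard
deviation; the choice of denominator only rescales $E$ by a constant that
the REML variance component absorbs. Constant genes are dropped with a
warning. The linear kernel is $E = RR'$ with no further normalization (an
optional mean-diagonal-1 rescaling exists for numerical comparability,
default off). The Gaussian kernel is

$$K_{ij} = \exp\!\big(-\lVert r_i - r_j \rVert^2 / h\big),$$

with the squared distance *divided* by the bandwidth. Under this
convention useful bandwidths scale with the number of genes (squared
distances between standardized profiles grow linearly in $m$), which is
why the default search grid is data-adaptive: 13 log-spaced values from
$0.1\bar d$ to $100\bar d$, where $\bar d$ is the mean pairwise squared
distance between line profiles.

## REML estimation

Variance components are estimated by average-information (AI) REML with an
intercept as the only fixed effect. Three numerical choices matter:

* **EM fallback and monotonicity.** An AI step is accepted only if it stays
  in the feasible region ($\sigma^2 \ge 0$) and does not decrease the
  restricted log-likelihood; otherwise one EM step is taken, which is
  monotone. The reported log-likelihood therefore never falls below its
  value at the initialization ($\sigma_k^2 = \mathrm{var}(y)/(\#\text{kernels}+1)$
  for every component).
* **Pseudo-inverse AI solve.** With two identical (or nearly identical)
  kernels the AI matrix is singular: the likelihood is flat along the split
  between the two components and only their sum is identifiable. The AI
  system is solved through an eigendecomposition that drops near-null
  directions, so the informative direction (the sum) still converges at
  Newton speed; tests assert that the sum matches the single-kernel fit to
  1e-4 while the individual split is reported as arbitrary.
* **Active-set boundary polish.** EM approaches a zero boundary
  geometrically and can stall visibly short of the constrained optimum
  (in experiments, up to ~0.02 log-likelihood units). After the main loop,
  any component below $0.05\,\mathrm{var}(y)$ — and, if the loop stalled,
  the smallest component — is pinned exactly at zero and the remaining
  components re-optimized; the solution with the higher restricted
  log-likelihood is kept. Pinned components are flagged as boundary
  estimates rather than dropped and refit.

Convergence requires a log-likelihood change below 1e-6 *and* a maximum
relative parameter change below 1e-5, within 200 iterations. $V$ is
factorized by Cholesky; if that fails near a boundary, a ridge of
$10^{-8}$ times the mean diagonal is added (this is why likelihood values
agree with a dense-formula oracle to ~1e-6 relative near boundaries, and
to 1e-8 elsewhere). Single-kernel fits are verified against a brute-force
grid maximization of the closed-form restricted likelihood, with one local
grid refinement because a 200-point-per-axis global grid resolves the
variance ratio only to ~5e-3.

## Prediction and heritability

Held-out lines are predicted from the train-only fit through kernel
cross-blocks, $\hat u_{\text{test}} = \hat\sigma_k^2 K[\text{test},
\text{train}] V_{\text{train}}^{-1}(y - 1\hat\mu)$ — algebraically
equivalent to Henderson's mixed-model equations with the test records
unobserved (tested against an MME oracle in a rank-reduced
parameterization). No refit on train + test occurs, so no phenotype
information leaks.

Heritability is the fraction of phenotypic variance attached to the
kernels: $h_G^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$ for GBLUP, and
omics-augmented broad-sense versions
$H^2 = (\sigma_g^2 + \sigma_{\text{omics}}^2)/(\sigma_g^2 +
\sigma_{\text{omics}}^2 + \sigma_e^2)$ for the two-kernel models, which
reduce exactly to $h_G^2$ when the omics component is zero.

**A caveat on near-identity kernels.** When the Gaussian bandwidth is
small relative to the distance scale, $K$ approaches the identity and
$\sigma_v^2$ becomes confounded with $\sigma_e^2$: their sum is well
identified but the split is not, and the REML optimum often pins
$\sigma_e^2$ at zero, pushing the broad-sense heritability toward 1 even
though cross-validated predictive ability remains perfectly well behaved.
Broad-sense estimates from Gaussian-kernel models should therefore be read
together with the selected bandwidth. The same reasoning dictated the
design of the parameter-recovery experiment in the acceptance suite: the
Gaussian kernel there is built on genotype-independent expression with few
(30) genes and bandwidth $\bar d/3$, giving enough off-diagonal contrast
to make all three components identifiable; with many genes and
$h = \bar d$, the kernel is nearly $c_1 I + c_2 J$ and no estimator could
separate $\sigma_v^2$ from $\sigma_e^2$.

## Cross-validation protocol

Replicated k-fold cross-validation (default 20 replicates of 5 folds,
giving 100 per-fold Pearson correlations between predicted genetic values
and observed phenotypes) drives model comparison. Choices worth knowing:

* All randomness derives from one master seed: replicate seeds are drawn
  once from it, so runs are bit-reproducible and all models share identical
  fold plans, making comparisons paired.
* Kernels are built once from all lines' predictors. Genotype and
  expression are predictors, not responses; subsetting happens at the
  fitting stage, so no phenotype information crosses fold boundaries.
* One correlation is computed per (replicate, fold); the summary is the
  mean of those values. Folds with non-converged fits or constant
  predictions (a zero-variance boundary estimate makes every prediction
  $\hat\mu$) yield undefined correlations and are excluded from the
  summary with a logged count, rather than set to 0. Under pure-noise
  phenotypes roughly half the folds end at the boundary, which is the
  statistically expected behavior of constrained REML.
* The bandwidth grid search runs on the same fold plans later used for the
  reported cross-validation and fixes the winning $h$ (ties go to the
  smaller bandwidth). This reuse is mildly optimistic for the
  Gaussian-kernel models; it is retained deliberately as the standard
  protocol for this model family.
* Tukey's honest significant difference test compares the per-fold
  abilities of several models as a one-way layout (studentized-range
  adjustment, verified against `stats::TukeyHSD` to 1e-6). Because models
  share fold plans the observations are positively correlated between
  groups; ignoring that pairing makes the test conservative for
  between-model contrasts.

In self-consistency experiments the grid search recovers a generative
bandwidth reliably only when neighboring grid points differ by an order of
magnitude or more; at desk-scale sample sizes (~100 lines) the predictive
ability surface is too flat in $h$ to distinguish 2-fold bandwidth changes
from cross-validation noise. The corresponding test therefore spaces its
grid by a factor of 20.

## The simulator

`simulate_dataset()` generates the three data layers with known truth:

* **Genotypes** of fully homozygous lines: each marker draws a minor
  allele frequency $q \sim U[0.05, 0.5]$ (lines carry dosage 2 with
  probability $q$, else 0). The default lower bound stays above typical
  MAF filter thresholds so that filtering is a no-op on defaults. Markers
  are independent — no linkage disequilibrium. Real panels have LD, which
  mainly changes the effective number of independent loci; the estimators
  under test operate on the kernel scale and do not depend on LD structure
  for their correctness, so passing tests say nothing about LD-related
  phenomena (e.g., marker-density requirements).
* **Expression**: each gene is a few cis-like additive marker effects (2
  by default) plus optional additive-by-additive epistatic terms (products
  of centered dosages of random marker pairs, 1 per gene by default) plus
  Gaussian noise with unit sd. The product encoding is the simplest signal
  that is orthogonal to every single centered dosage (hence invisible to
  $G$) yet linearly expressible through expression columns.
* **Phenotype**: a polygenic term on centered dosages, a mediated term on
  standardized expression columns, and Gaussian noise, each rescaled post
  hoc to an exact empirical standard deviation of $\sqrt{\text{share}}$
  (default shares 0.4 / 0.3 / 0.3, mid-range of heritabilities commonly
  reported for line-mean traits in inbred panels). Post-hoc scaling gives
  exact share control at the cost of slightly distorting the effect-size
  distribution; realized shares are stored with the truth object and are
  reproducible from the stored effect vectors.

What the simulator does **not** emulate: linkage disequilibrium (an
optional block-correlated mode was considered and rejected as unnecessary
for testing the estimators), sex-stratified architectures, array-specific
expression noise, and missing-data mechanisms other than missing completely
at random.

## Problem sizes and runtime choices

The test and acceptance workloads use panels of 120–400 lines with
250–1000 markers and 30–200 genes. These sizes were chosen so that REML
fits are well conditioned (n below ~50 makes two-kernel fits boundary-prone)
while a complete run of the suite stays in the minutes range on a single
core; they are the package's own desk-scale working points, and all of the
package's guarantees are asserted at these sizes. The acceptance script
uses 200 lines, 500 markers, 150 genes, a 13-point bandwidth grid under
2-replicate cross-validation for selection, and 5 replicates of 5-fold
cross-validation for the reported predictive abilities.

## Known limitations

* Only an intercept is supported as a fixed effect; covariates or sex
  effects must be handled upstream (e.g., by stratifying the input).
* Standard errors for heritability estimates are not provided.
* Mean imputation of missing genotypes ignores LD; for real data a
  haplotype-aware imputer upstream is preferable.
* Boundary variance estimates make broad-sense heritabilities from
  Gaussian-kernel models sensitive to the selected bandwidth (see the
  near-identity caveat above).
* The VCF reader supports a minimal biallelic GT-only dialect; anything
  richer should be converted to dosage TSV upstream.
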