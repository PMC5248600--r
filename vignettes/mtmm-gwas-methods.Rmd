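---
title: "Multi-trait mixed-model GWAS with a factor-analytic covariance: models and methods"
author: "mtmmGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait mixed-model GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmmGWAS)
```

# The problem

Plants in the field face many stresses — drought, salt, herbivores,
pathogens — and resistance mechanisms are often shared or traded off between
them. Mapping the genetics of many stress responses *jointly* in a
structured panel of inbred accessions asks more of a model than running one
GWAS per trait: the polygenic background is correlated across traits, the
panel has population structure, and the interesting hypotheses are about
*patterns* of SNP effects across traits (a consistent effect everywhere; an
opposed effect between, say, abiotic- and biotic-stress responses), not just
about any effect anywhere.

`mtmmGWAS` implements a multi-trait mixed model (MTMM) for this setting:
standardized stress-response traits derived from raw plant observations, a
marker-based kinship compressed over genetic groups so that the multivariate
REML problem stays tractable, a second-order factor-analytic genetic
covariance among traits, per-SNP Wald tests for three effect patterns,
regression-based genomic control, and candidate-region post-processing. A
simulation module generates data with exactly the covariance structure the
model assumes, which is how the package validates itself.

# The model

For $n$ accessions and $p$ traits, the phenotype matrix $Y$ ($n \times p$,
columns standardized) follows

$$ Y = XB + G + E, $$

where $XB$ holds trait-specific intercepts (and, during a scan, SNP
effects), the random genetic term satisfies
$\mathrm{vec}(G) \sim N(0,\, V_g \otimes K)$ and the residual term
$\mathrm{vec}(E) \sim N(0,\, V_e \otimes I_n)$. $K$ is the marker-based
relatedness among accessions, $V_g$ the $p \times p$ genetic covariance
among traits, and $V_e$ the residual covariance, taken diagonal because the
traits are measured on different plants (so residuals cannot be correlated
through shared measurement).

An unstructured $V_g$ has $p(p+1)/2$ parameters and becomes impractical
beyond roughly ten traits. We therefore assume a second-order
factor-analytic (FA2) structure

$$ V_g = \sigma_g^2\,(\lambda \lambda^t + \mathrm{diag}(\tau_1^2, \dots, \tau_p^2)), $$

a rank-2 loading part capturing the dominant axes of shared genetic
variation plus trait-specific genetic variances. The scale $\sigma_g^2$ is
not separately identifiable from the loadings and is fixed at 1 during
optimization; rotational invariance of $\lambda \lambda^t$ is pinned by
$\lambda_{1,2} = 0$ and a positive leading entry per column (any fit can be
rotated into this form without changing $V_g$).

## Compressed kinship

REML for the Kronecker model is dominated by operations in the
eigenbasis of $K$. Replacing $K$ by the *compressed* kinship
$Z K_C Z^t$ — where $Z$ assigns each accession to one of $m$ internally
homogeneous groups and $K_C$ is the average kinship within and between
groups — reduces the effective rank to $m$ while retaining the structure
relevant for confounding control. Groups are formed by Ward clustering (on
squared Euclidean distances) of the first $k - 1$ principal components of
the standardized SNP scores, cutting the dendrogram at $k$ groups; group
averages include the self-kinship diagonal.

Choosing $m$ trades model fidelity against stability: `selectCompression()`
profiles, over a range of group counts (default 4–100), the *correspondence*
between the compressed kinship and phenotypic or geographic dissimilarity,
and returns the smallest converging $m$ whose correspondence approximates
(within 5%) that at 35 groups. Correspondence is measured as the Frobenius
norm of the difference between the complement of the compressed kinship and
the Euclidean distance matrix. "Complement" is an interpretive choice here:
we min–max rescale both matrices to $[0,1]$ and take max-entry minus entry,
so that kinship similarity becomes a dissimilarity comparable to a rescaled
distance; zero means perfect agreement.

## REML estimation

Write $K = U S U^t$ (one symmetric eigendecomposition per fit, eigenvalues
clipped at zero) and rotate $Y^\ast = U^t Y$. With $V_e = L_e L_e^t$ and the
whitened genetic covariance $L_e^{-1} V_g L_e^{-t} = Q D Q^t$, the fully
transformed data $T = Y^\ast L_e^{-t} Q$ have *independent* entries with
variance $S_i d_j + 1$. The restricted likelihood (trait intercepts
profiled out by GLS, which is diagonal in these coordinates) therefore costs
$O(np^2 + p^3)$ per evaluation instead of the $O((np)^3)$ of a dense
multivariate-normal evaluation. The test suite verifies this evaluation
against an explicit dense $(np \times np)$ computation to $10^{-6}$ on
small panels.

The FA2 parameters (free loadings, $\log \tau^2$, $\log v_e$) are estimated
by repeated quasi-Newton (BFGS) maximization of the profiled restricted
likelihood: each outer iteration restarts the optimizer from the incumbent
and can only improve it, so the recorded log-likelihood trace is monotone
non-decreasing by construction, and convergence is declared when an outer
iteration improves the restricted log-likelihood by less than `tol`
(default $10^{-6}$ relative). We chose direct quasi-Newton over an EM
scheme: with the likelihood this cheap to evaluate, BFGS on the
unconstrained parameterization converges in a handful of outer iterations
and avoids the slow terminal phase EM is known for in variance-component
problems. Loadings are initialized from the top-2 eigenvectors of the
sample covariance of the per-trait univariate G-BLUPs; $\tau^2$ and $v_e$
from the univariate variance components. The initialization is
deterministic, so fits are reproducible without a seed.

Single traits use the classical spectral trick: a 1-D optimization of the
profiled restricted likelihood over $h^2 = \sigma_A^2 / (\sigma_A^2 +
\sigma_E^2)$, with G-BLUPs
$\hat\sigma_A^2 K (\hat\sigma_A^2 K + \hat\sigma_E^2 I)^{-1}(y - \hat\mu)$.

## Genetic correlations and the G-BLUP fallback

Pairwise genetic correlations use the bivariate model with an unstructured
$2 \times 2$ $V_g$ (log-Cholesky parameterized, hence positive
semi-definite by construction) and a diagonal $V_e$ — unless the two traits
were measured on the same plants (`sharedPlants = TRUE`), in which case
$V_e$ is unstructured too. For some pairs the likelihood is monotone in the
correlation and the REML estimate is not interior. The fallback triggers
when a genetic variance is pinned at numerical zero, when $|\hat r_g|$ is
pinned at 1, or when the optimizer fails to converge; the genetic
correlation is then estimated by the Pearson correlation of the two
univariate G-BLUP vectors and flagged as a fallback. The trigger thresholds
($10^{-6}$ of the phenotypic scale for variances, $1 - 10^{-6}$ for the
correlation) are our choice; the fallback itself follows the estimation
strategy the model family prescribes.

## Per-SNP Wald tests

Variance parameters are estimated once on the null model (intercepts only)
and held fixed across SNPs — the standard two-step approximation; at
hundreds of thousands of SNPs per-marker REML would be prohibitive and
changes little when single-SNP effects are small. For each SNP the GLS
system in the whitened coordinates is assembled from a handful of matrix
products shared across all SNPs, so a scan is linear in the number of
markers. Three hypotheses are tested:

* **general** — $H_0: \beta_1 = \dots = \beta_p = 0$ against trait-specific
  effects; Wald statistic with $p$ degrees of freedom;
* **consistent** — effects constrained equal across traits,
  $H_0: \beta = 0$; 1 df;
* **contrast** — effects constrained equal within each of two predefined
  trait groups, $H_0: \alpha_1 = \alpha_2$; 1 df.

P-values come from the chi-square upper tail; no small-sample F correction
is applied. SNPs with numerically singular systems (constant dosage, or an
effect-covariance condition number above $10^{12}$) are flagged and skipped
rather than aborting the scan.

## Genomic control

The Wald tests show genome-wide inflation affecting small *and* large
P-values, which makes the usual median-based inflation factor overly
optimistic. Instead, the observed $-\log_{10}(P)$ order statistics are
regressed on their uniform expectations $-\log_{10}(i/(N+1))$ by least
squares *through the origin* — both sets of quantiles share the point
$(0, 0)$ in distribution, so an intercept has no place — and observed
values are divided by the slope, which is reported as the inflation factor.
Unweighted regression over all order statistics is used; the extreme tail is
neither trimmed nor down-weighted.

## Trait derivation

Raw plant observations become analysis-ready traits in four steps: (i) a
variance-stabilizing transformation where residuals deviate from normality
(`log`, `sqrt`, or the angular `asin(sqrt(x))` for proportions); (ii)
per-treatment accession means as BLUEs from a fixed-effects OLS with
accession plus design covariates — the per-experiment random design effects
of a full mixed-model analysis are out of scope here, and on balanced
designs the fixed-effects BLUE coincides; (iii) control correction, either
the difference (stress minus control) or the residual from regressing
stress on control means, yielding a stress response orthogonal to the
control level; (iv) optional PC1 collapsing: within one experiment,
standardized traits are replaced by their first principal component when it
explains more than half the total variance (computed on standardized
traits, the sensible convention for mixed-unit traits), with the PC1 sign
fixed by its largest-absolute loading. Accessions missing any derived trait
are dropped listwise before fitting. Columns are standardized to mean 0,
sample SD 1 before the MTMM.

## Candidate regions and enrichment

After genomic control, SNPs with corrected $P$ strictly below $10^{-4}$ are
selected. Significant SNPs within 20 kb of each other on the same
chromosome are chained *transitively* into one LD block (a run of SNPs each
within 20 kb of its neighbor is one block even when the total span is
larger); each block is represented by the member with the strongest mean
absolute effect across traits, ties going to the smaller position. Genes
are paired with significant SNPs when the gene interval intersects the
SNP's ±20 kb half-window (boundary touching counts), each gene reported
once with its nearest SNP. Two sanity numbers accompany a selection: the
naive expected false-positive count (number of tests × threshold) and the
Benjamini–Hochberg adjusted P-value at the selection rank.

Enrichment of significant genes in a candidate class uses the one-sided
hypergeometric mid-P, $P(X > k_1) + \tfrac12 P(X = k_1)$ — one-sided
because the hypothesis is directional (over-representation); a two-sided
variant is available by flag. The fold enrichment is the ratio of the two
proportions, and $1/\text{ratio}$ is reported as an upper bound on the
false discovery rate of the candidate class.

## Genetic-correlation networks

Groups of traits are connected in a network when the mean genetic
correlation over all cross-group trait pairs exceeds 0.2 in absolute value
(strictly); within-group mean correlations are reported only for groups
with at least two traits.

# The simulation module and what it does (not) show

`simulateGenotypes()` draws ancestral allele frequencies uniformly on
$[0.1, 0.9]$, drifts them into $m$ ancestry groups by a Balding–Nichols
beta model with differentiation parameter `fst`, and samples fully inbred
dosages in $\{0, 2\}$. `simulatePhenotypes()` then draws
$\mathrm{vec}(G) \sim N(0, V_g \otimes K)$ and independent residuals, adds
optional causal-SNP effects, and leaves standardization to the caller. This
emulates exactly the covariance structure the MTMM assumes: discrete
ancestry groups, Kronecker-structured polygenic effects, diagonal
residuals. It deliberately does *not* emulate linkage disequilibrium decay
along chromosomes, rare-allele site-frequency spectra, admixture clines,
genotype-by-environment interaction, or non-additive genetic effects — so
passing tests demonstrate the estimator and tests work *when the model
holds*, not that the model is adequate for any particular real panel.

The power study compares, on the same simulated data per replicate, the
general Wald test, the contrast Wald test and a univariate mixed-model test
of the trait with the highest estimated heritability (same two-step
machinery with $p = 1$, for a fair comparison). Two effect scenarios are
built in: group-opposed signs (positive in one trait group, negative in the
other — scenario A) and fair-coin signs per trait (scenario B); magnitudes
are half-normal, so effects are positive but never exactly equal. Defaults:
$n = 300$ accessions, 500 SNPs for the kinship, $p = 6$ traits in two
groups of three, one causal SNP (the first with MAF ≥ 0.2), an
equicorrelated $V_g$ (variance 0.3, correlation 0.5), $v_e = 0.7$, 200
replicates, rejection threshold $10^{-3}$. The effect-magnitude scale
defaults to 0.15, which places all three tests in the interior of the power
range (roughly 0.1–0.7) under these settings — a deliberate choice so the
qualitative ordering (contrast ≥ general under scenario A, general ≥
contrast under B, best-heritability univariate below the better MTMM test)
is resolved rather than hidden at a power ceiling or floor. Non-convergent
replicates are dropped and counted.

# Numerical choices and degenerate inputs

* Kinship eigenvalues are clipped at zero; compressed kinships are
  PSD-repaired by eigenvalue clipping only when numerically indefinite, so
  singleton-group compression reproduces the original matrix bit-for-bit.
* $\tau^2$ and $v_e$ are optimized on the log scale (positive by
  construction); $V_g$ in the bivariate model is log-Cholesky parameterized.
* Monomorphic SNPs are rejected by `standardizedScores()` (filter first);
  missing genotypes are mean-imputed per SNP at read time; heterozygous
  calls in an inbred panel are kept as dosage 1 with a warning;
  multi-allelic VCF records are rejected.
* Constant trait columns are an error wherever standardization is implied.
* Ward clustering uses `hclust` on squared Euclidean distances, whose
  lowest-index-first merging makes assignments deterministic.
* `genomicControl()` refuses nonpositive P-values and warns below 100 tests.
* Scan tables are written with 17 significant digits so a TSV round trip
  preserves values to better than $10^{-12}$.

# Problem sizes used in the validation suite

The dense-oracle equivalence checks run at $n \le 30$, $p \le 3$, where the
explicit $(np \times np)$ covariance is cheap. Parameter-recovery suites
use $n = 300$–$350$, $p = 6$, 10 ancestry groups, 20 seeds (FA2
correlations, heteroscedastic $v_e$) and 200 replicates (single-trait
$h^2$); calibration uses ~1100 null SNPs per test plus $10^4$ uniform
P-values for the genomic-control slope; the power study runs 200 replicates
per scenario. These sizes resolve each property comfortably on a single
CPU while keeping the default test run in the minutes range.

# Known limitations

* The factor-analytic rank is fixed at 2; traits whose genetic covariance
  needs more axes will load the remainder onto $\mathrm{diag}(\tau^2)$.
* Residual covariance is diagonal except in the bivariate shared-plants
  case; multi-trait shared-plant designs are not modeled.
* The two-step (fixed variance components) scan slightly misstates
  per-SNP uncertainty for large-effect markers; genomic control absorbs
  the genome-wide component of this.
* BLUEs come from fixed-effects OLS; experiment-specific random design
  effects are not reproduced.
* Compression-level selection is validated against its stated selection
  logic on synthetic data, not against any particular real panel.
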