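---
title: "Gene set analysis with sliced average variance estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set analysis with sliced average variance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrgsa)
```

## The model and its null hypothesis

A self-contained gene set analysis asks whether the expression vector
$X \in \mathbb{R}^p$ of a predefined gene set carries any information about a
phenotype $Y$. sdrgsa frames this in the language of sufficient dimension
reduction: if $Y \mid X$ and $Y \mid \eta^\top X$ have the same distribution
for some $p \times d$ matrix $\eta$, the column space of $\eta$ is a
dimension-reduction subspace, and the central subspace is the smallest such
space. "No association" is exactly the statement that its dimension $d$ is
zero, so the test of independence becomes the marginal dimension test of
$H_0\colon d = 0$ against $d > 0$.

Sliced average variance estimation (SAVE) estimates the central subspace
through the kernel $E[\operatorname{Var}(Z \mid Y) - \operatorname{Var}(Z)]^2$,
where $Z = \hat\Sigma_X^{-1/2}(X - \bar X)$ is the standardized expression
vector. After grouping the $n$ samples into $H$ slices by their phenotype
values, the kernel is estimated by
$\sum_s \hat p_s (\hat\Sigma_{Z|s} - I_p)^2$ with $\hat p_s = n_s/n$ the slice
proportions. Its squared Frobenius norm is the test statistic

$$T \;=\; \sum_{s=1}^{H} \hat p_s\, \operatorname{tr}(\hat\Sigma_{Z|s} - I_p)^2
  \;=\; \sum_{s=1}^{H} \hat p_s \sum_{i=1}^p \sum_{j=1}^p
        (\hat\sigma_{ij|s} - \sigma_{ij})^2 ,$$

large when slicing by the phenotype perturbs the second moments of $Z$. $T$
also reacts to mean shifts, but only weakly when the conditional means are
uncorrelated across genes, so the package provides the mean-augmented
variant

$$V \;=\; \sum_{s=1}^{H} \hat p_s\,
  \operatorname{tr}\bigl\{(\hat\Sigma_{Z|s}^{1/2} - I_p)^2
  + \bar Z_s \bar Z_s^\top\bigr\},$$

whose second term is the squared norm of the slice mean, giving differential
mean expression full weight. In practice `T` is the better detector of
differential coexpression/variance and `V` of mean or regression-type
signal; `statistic = "auto"` in `sdr_test()` picks `T` for categorical and
`V` for continuous phenotypes accordingly.

The unstandardized variants replace the whitening step by centering only:
$T^* = \sum_s \hat p_s \operatorname{tr}(\hat\Sigma_{X|s} - \hat\Sigma_X)^2$
and
$V^* = \sum_s \hat p_s \operatorname{tr}\{(\hat\Sigma_{X|s}^{1/2} -
\hat\Sigma_X^{1/2})^2 + (\bar X_s - \bar X)(\bar X_s - \bar X)^\top\}$.
Both square-root forms are taken literally (the root inside the square), not
as a typographical variant of the unrooted expression. $T$ and $T^*$
decompose exactly over genes, $T = \sum_i T_i$ with
$T_i = \sum_s \hat p_s \sum_j (\hat\sigma_{ij|s} - \sigma_{ij})^2$, which is
what `coef()` and the per-gene tables report; the fractions $T_i/T$ rank hub
genes within a significant set.

## Slicing

Categorical phenotypes have a natural slicing, one slice per level in sorted
level order; every level must contain at least two samples so a within-slice
covariance exists. Continuous phenotypes are discretized monotonically:
samples are ranked and cut into $H$ contiguous bins whose sizes differ by at
most one (the first `n %% H` bins take the extra sample), so the partition is
invariant under strictly increasing transforms of $y$. Ties are broken by
original sample order — deterministic, and reported by message when a tied
group straddles a boundary. The default is $H = 2$ equal slices, the choice
used throughout the package's continuous-response simulations;
`slices = "auto"` applies the $\max(2, \mathrm{round}(0.1\,n))$ rule of
thumb from the dimension-reduction literature. With limited samples fewer
slices are safer, and `V` is considerably more robust to the slice count
than `T`.

## Standardization and the p ≥ n regime

Exact whitening uses the symmetric inverse square root of the pooled sample
covariance, computed by eigendecomposition with eigenvalues below
$10^{-10} \times \lambda_{\max}$ treated as zero. The centered sample
covariance has rank at most $n - 1$, so exact mode is impossible whenever
$p \ge n$ — a regime that includes even the smallest routine gene sets. Two
escapes are provided and `standardize = "auto"` picks the first:

* **Shrinkage** (`shrinkage_cov()`): the sample correlation matrix is shrunk
  toward the identity with the analytic (never cross-validated, hence
  deterministic) intensity
  $\lambda = \sum_{i \ne j} \widehat{\operatorname{Var}}(r_{ij}) /
  \sum_{i \ne j} r_{ij}^2$, clipped to $[0,1]$, and rescaled by the gene
  variances. The result is positive definite for any $\lambda > 0$, so its
  inverse square root always exists.
* **Skipping standardization** via the starred statistics.

A design point worth stating explicitly: after shrinkage standardization the
empirical pooled covariance is only approximately the identity, yet `T` and
`V` still compare within-slice covariances against $I_p$ — the population
target of the shrunk whitening — rather than against the empirical pooled
matrix. Under label permutation the observed and replicated statistics are
computed identically, so the test remains exact in level regardless of this
choice; it only shifts the (unknown) power trade-off.

Covariances use the maximum-likelihood divisor $n$ on both the pooled and
the within-slice side, the convention that makes the single-slice identity
$T = V = 0$ hold exactly; `divisor = "n-1"` switches both sides together.

## Permutation inference

Significance comes from permuting phenotype labels: the standardizing
transform depends on the expressions only, so it is computed once and reused
across all $B$ replicates (unit tests assert this equals re-standardizing per
permutation), and permuting labels preserves slice sizes, so $\hat p_s$ is
constant across replicates by construction. The p-value is the add-one
estimator $p = (1 + \#\{b : T_b \ge T_{\mathrm{obs}}\})/(B+1)$, with ties
counted in the numerator — conservative, never zero, and bounded below by
$1/(B+1)$. One seeded generator drives the whole invocation, so results are
reproducible and independent of any chunking. Per-gene p-values for the
decomposable statistics reuse the same replicates: each observed $T_i$ is
referred to its own permutation distribution. These per-gene values are
self-contained screens and are reported unadjusted; `summary(fit,
p_adjust = "BH")` appends a Benjamini–Hochberg column as a clearly optional
extension. The default is $B = 1000$ permutations.

A computational note: for `V` with an identity target only the eigenvalues
of the within-slice covariance are needed, and when $p > n_s$ these are
taken from the $n_s \times n_s$ Gram matrix of the centered slice (identical
nonzero spectrum; each of the $p - n_s$ exact zeros contributes 1 to the
trace term). This makes the permutation loop linear in $p$ for the common
wide-set case; agreement with the direct $p \times p$ route is unit-tested
to about $10^{-8}$ relative.

## What the simulation designs emulate

The generator reproduces three multivariate-normal designs and their
defaults are the study conditions themselves, not tuning knobs.

* **Binary**: two groups of $n/2$; group 1 uncorrelated with unit
  (homogeneous) or $U(1,5)$ (heterogeneous) variances; under the alternative
  the first $\gamma p$ genes of group 2 are equi-correlated at $\rho$ and
  heterogeneous variances are redrawn independently of group 1 (under the
  null the two covariance matrices are shared, including the drawn
  variances). Covariances are assembled as $D^{1/2} R D^{1/2}$ — variances
  first, then the correlation structure — so $\rho$ is a correlation, never
  a covariance. Heterogeneous variances are redrawn for every replicate
  dataset.
* **Three-class**: three groups of $n/3$, all variances $U(1,5)$; classes 2
  and 3 have block-diagonal covariances with four blocks of size $p/4$, the
  first $\gamma p/4$ genes of every block correlated in class 2 and the last
  $\gamma p/4$ in class 3, so the coexpressed positions shift between
  classes.
* **Continuous**: $X \sim \mathrm{MVN}(0, \Sigma_X)$ with unit variances, an
  equi-correlated block on genes $1..p_1$ and an AR-decay block
  ($\rho^{|i-j|}$) on genes $p_1+1..2p_1$; the phenotype is $N(0,1)$ noise
  (null), $N(x^\top\beta, 1)$ (linear) or $N(e^{x^\top\beta}, 1)$
  (nonlinear). $\beta$ has exactly ten nonzero entries, five random
  positions per correlated block, drawn as $N(\nu, |\nu|)$ and
  $N(-\nu, |\nu|)$ — we read the second parameter as a **variance** — with
  positions redrawn per replicate and recorded in the `beta` attribute;
  $\nu = 0$ yields $\beta = 0$ exactly, collapsing both alternatives onto
  the null.

What these designs do *not* emulate about real expression data: non-normal
marginals, heavy tails and outliers, technical batch structure, correlated
null genes outside the designated blocks, and measured-but-unmodelled
confounders. Calibration results under the generator therefore demonstrate
permutation validity and relative power ordering, not field performance on
any particular platform.

`estimate_size_power()` replicates a scenario, runs the permutation test on
every replicate and reports the rejection fraction at level $\alpha$ with
its binomial standard error $\sqrt{r(1-r)/\text{datasets}}$;
`rejection_band()` gives the closed-form calibration band (at a true rate of
0.05 with 1000 replicates the standard error is 0.0069 and the upper 97.5%
limit about 0.064; at 0.01, about 0.016).

## Numerical choices and degenerate inputs

* Eigenvalue clipping: within-slice covariances are PSD up to round-off;
  eigenvalues are clipped at zero before square roots, and a violation
  beyond $-10^{-10}$ (relative) is treated as a real error rather than
  repaired. Because $\sqrt{\lambda}$ is non-Lipschitz at zero, the
  square-root statistics are reproducible only to about
  $\sqrt{\varepsilon} \approx 10^{-8}$ across algebraically equivalent
  computation routes whenever a slice covariance is rank-deficient (slice
  size $\le p$); $T$ and $T^*$, which involve no root, agree to $10^{-12}$.
* Symmetry tolerances: $10^{-10}$ relative for inputs to the matrix-power
  routine, $10^{-12}$ for within-slice covariances.
* Missing expression values are an error naming the offending cells;
  imputation is upstream of this package.
* Duplicate gene ids are an error by default (collapsing by first occurrence
  is opt-in and warned about); duplicate genes inside a GMT set are removed
  with a warning.
* A slice with fewer than two samples — a phenotype level observed once, or
  $H > n/2$ — is refused outright.
* Constant expression blocks make every statistic zero for every labelling;
  with the starred statistics this yields p-value 1, the honest answer.

## Problem sizes used by the shipped checks

The package's own test suite and the reproduction script run the calibration
designs at desk scale: 500 replicate datasets with $B = 300$ permutations
for the null rejection rates (acceptance band: three binomial standard
errors, about $\pm 0.03$), and 300 datasets with $B = 200$ for the power
orderings. These sizes put the Monte-Carlo noise well inside the bands being
checked while keeping a full run in the minutes range; the full-scale
convention (1000 replicates, $B = 1000$) is the package default for actual
analyses.

## Limitations

The tests assess $d = 0$ only; they neither estimate dimension-reduction
directions nor the structural dimension beyond the null, and no asymptotic
reference distribution is provided (inference is purely permutation-based).
Power depends on the slice count for `T`, on the standardization route in
the $p \ge n$ regime (shrinkage versus starred statistics — the level is
exact either way, the power trade-off is design-dependent), and local
alternatives favour purpose-built tests: a linear-correlation method will
beat `V` under a purely linear signal, while `V` dominates under nonlinear
links and `T` under differential coexpression.
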