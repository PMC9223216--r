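---
title: "Predicting miRNA-disease associations: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmfpred)
```

## The problem

Experimentally verified miRNA-disease associations form a sparse binary
matrix $A \in \{0,1\}^{n_m \times n_d}$ (miRNAs in rows, diseases in
columns). The entries that are 0 are not verified negatives -- they are
simply unknown -- and the verified entries themselves contain redundant or
spurious records. The task is bipartite link prediction: produce a score
for every pair so that unobserved true associations rank above random
pairs. `scmfpred` implements a three-stage pipeline: denoise $A$, build one
fused similarity kernel per entity class, and factorize the denoised matrix
under similarity constraints.

## Stage 1: matrix decomposition (denoising)

The association matrix is decomposed by low-rank self-expression,

$$\min_{Y,X} \|Y\|_* + \varphi \|X\|_{2,1}
  \quad \text{s.t.} \quad A = AY + X,$$

where $\|Y\|_*$ is the nuclear norm (so the disease-by-disease coefficient
matrix $Y$ is low rank), $\|X\|_{2,1}$ is the sum of column norms (so the
outlier matrix $X$ is column-sparse -- whole diseases' profiles are treated
as partially corrupt, not isolated cells), and $\varphi > 0$ trades the two
off. With $A Y$ read as "each disease's profile expressed as a combination
of the others", $X$ absorbs what cannot be expressed that way, and
$A^* = AY^*$ is the denoised matrix passed downstream.

The problem is solved by the inexact augmented Lagrange multiplier (IALM)
scheme: alternating singular value thresholding for the nuclear-norm block,
a single cached Cholesky solve of $(I + A^\top A)$ for $Y$, columnwise
shrinkage for $X$, multiplier updates, and a geometric penalty schedule
$\alpha \leftarrow \min(1.1\,\alpha, 10^{10})$ starting at $10^{-4}$. The
iteration stops when both feasibility residuals
$\|A - AY - X\|_\infty$ and $\|Y - J\|_\infty$ drop below $10^{-8}$;
non-convergence within 500 iterations returns a flagged result with a
warning rather than an error, because a near-feasible $A^*$ is still usable.
Note that the residuals are not monotone: the growing penalty makes them
oscillate at the $10^{-8}$ scale just before convergence, which is why the
test suite asserts a downward trend rather than per-step decrease.

$\varphi$ has no published reference value; the package default is 1.0. The
printed source formulation contains two typos that this implementation
resolves the standard way: the prox subproblems are the usual
$\arg\min \tau\|\cdot\| + \tfrac12\|\cdot - B\|_F^2$ forms (not the printed
"$\tfrac12 J$" variants, which the printed closed-form updates do not
solve), and the shrinkage argument is $A - AY + F_1/\alpha$ (the printed
$AY + F_1/\alpha$ contradicts the constraint).

## Stage 2: similarity construction and fusion

Two similarity sources exist per entity class:

* **Gaussian interaction profile (GIP) kernels** on the rows (miRNAs) and
  columns (diseases) of $A$:
  $K(i,j) = \exp(-\rho \|a_i - a_j\|^2)$ with bandwidth
  $\rho = \rho' / \overline{\|a_i\|^2}$. The original bandwidth $\rho'$
  defaults to 1, the convention of the GIP literature.
* **miRNA functional similarity** is a precomputed input (any labeled
  square matrix). **Disease semantic similarity** is computed from
  MeSH-style DAGs: each disease's ancestors receive contributions either by
  geometric decay ($\Delta = 0.5$ per generation, maximum over equally
  short paths) or by corpus frequency ($-\log$ of the fraction of DAGs
  containing the term, natural log -- the base is unstated in the source
  and cancels only partially, so a fixed choice matters for
  reproducibility); pairwise similarity is the shared-ancestor contribution
  mass normalized by the two semantic values, and the two models are
  averaged. Diseases with no DAG get zero semantic similarity to others;
  the fused GIP signal covers them.

Each class's two kernels are combined by similarity kernel fusion: a
column-normalized kernel $F_n$ and a row-stochastic $k$-nearest-neighbor
kernel $S_n$ per input, then the cross-diffusion iteration

$$F_n^{(l+1)} = \tau\, S_n \left(\tfrac{F_t^{(l)}}{2}\right) S_n^\top
  + (1-\tau)\,\tfrac{F_t^{(0)}}{2}, \qquad t \ne n,$$

re-symmetrizing after every step, followed by averaging and an entrywise
neighbor-agreement mask $W \in \{0, \tfrac12, 1\}$ (mutual neighbors keep
full weight, one-sided pairs half, mutual strangers are zeroed). Three
choices here are deliberately conservative readings of an ambiguous
formulation: the division by 2 in the cross terms is kept although only one
other kernel exists (`divisor_mode = "n-minus-1"` switches to the standard
normalization); the mask is applied as a Hadamard product, since a matrix
product would destroy the similarity interpretation; and the mask's
neighborhoods are taken on the fused kernel itself, which is the matrix the
mask is meant to clean. Defaults: $\tau = 0.5$, 20 iterations, tolerance
$10^{-6}$, $k = \max(3, n/10)$ -- none of these have published values.

## Stage 3: similarity-constrained matrix factorization

The denoised matrix is factorized as $A^* \approx UV^\top$ with latent
dimension $\gamma$ by minimizing

$$L = \tfrac12 \sum_{ij} (a^*_{ij} - u_i v_j^\top)^2
 + \tfrac{\vartheta}{2}\Big(\textstyle\sum_i \|u_i\|^2 + \sum_j \|v_j\|^2\Big)
 + \tfrac{\sigma}{2} \sum_{ij} \|u_i - u_j\|^2 SM_{ij}
 + \tfrac{\sigma}{2} \sum_{ij} \|v_i - v_j\|^2 SD_{ij},$$

where $SM$ and $SD$ are the fused kernels. $\vartheta$ controls
overfitting, $\sigma$ the smoothness of the latent space along the
similarity graph; the defaults $\vartheta = 2^2$, $\sigma = 2^0$ are the
best cell of the reference grid search over $2^{-3}\ldots 2^3$.

Each row of $U$ (then of $V$) is updated by its exact Newton step -- the
closed-form minimizer of the strictly convex quadratic obtained by fixing
everything else:

$$u_i \leftarrow \Big(A^*(i,{:})V + \sigma \textstyle\sum_{j \ne i}(SM_{ij}+SM_{ji})\,u_j\Big)
  \Big(V^\top V + \vartheta I + \sigma \textstyle\sum_{j \ne i}(SM_{ij}+SM_{ji})\, I\Big)^{-1}.$$

The self term $j = i$ is excluded from both sums: it cancels identically in
the penalty (because $u_i - u_i = 0$), and carrying it with the stale
$u_i$ -- a literal reading of the printed update -- would leave a residual
gradient of $2\sigma SM_{ii}\|u_i^{new} - u_i^{old}\|$ at every step. With
the exclusion, every update is an exact coordinate minimization, so the
objective trace is non-increasing by construction; the test suite verifies
both the gradient identity (against central differences) and the trace.
Updates sweep rows in ascending order Gauss-Seidel style; within a $U$
phase $V^\top V$ is constant, so it is eigendecomposed once per sweep and
each row costs one diagonal solve.

Two further deliberate choices: although the source describes the base
method as non-negative factorization, the printed updates are unconstrained
closed forms with no projection step, and this package follows the printed
updates (no non-negativity projection). Initialization is unstated in the
source; the default is the deterministic truncated SVD
($U = U_\gamma \Sigma_\gamma^{1/2}$), with a seeded small-uniform
alternative for robustness testing. Latent dimension defaults to
$\gamma = 50$ (capped at $\min(n_m, n_d)$); the source never states its
value. Convergence: relative objective change below $10^{-6}$ or 200
sweeps.

Predicted scores are $A' = UV^\top$; per-disease candidate lists sort each
column in decreasing score, ties broken lexicographically by miRNA id, with
known associations optionally excluded.

## Evaluation protocols

* **Fivefold CV**: known pairs are split at random into five folds; each
  fold's positives are zeroed in the training matrix, *all* kernels and
  both model stages are recomputed on the masked matrix (the GIP kernels
  would otherwise leak the test associations -- functional and semantic
  similarities are fold-independent inputs and are not masked), and the
  fold's positives are ranked against the candidate set (all pairs unknown
  in the full matrix). The per-repeat AUC is the mean of the five fold
  AUCs; repeats default to 5 here (100 in the reference protocol; the test
  suite uses 1-3).
* **Global LOOCV**: each positive held out and refit in turn, ranked
  against all candidates; the reported AUC is the mean per-pair win
  probability, i.e. the pooled Mann-Whitney statistic.
* **Local LOOCV**: per disease, all of its positives are held out at once
  and ranked against that disease's unknown miRNAs only; diseases with no
  positives or no negatives are skipped with a warning.

AUC is computed in rank (Mann-Whitney) form with ties counted one half,
verified against a brute-force pair-counting oracle. All randomness
(folds, initializations, synthetic data) descends from explicit integer
seeds; two runs with the same seed are bit-identical.

## The synthetic world

Real benchmarks for this problem require database downloads, so the package
ships a generator that plants exactly the structure the method assumes:
non-negative factors $U_0, V_0$ (i.i.d. $|N(0,1)|$), positives = the top
`density` quantile of $U_0 V_0^\top$, symmetric label noise (a fraction
`noise_rate` of positives flipped out, the same count of zeros flipped in),
functional similarity = cosine similarity of $U_0$ rows, and a DAG corpus
built by nearest-predecessor linkage in $V_0$ space so that shared ancestry
tracks latent proximity. Defaults ($n_m = 120$, $n_d = 80$, $r = 5$,
density 0.05, noise 0.1) are the benchmark configuration used by the
acceptance tests.

What a green synthetic benchmark does and does not establish: it shows the
pipeline recovers planted low-rank structure consistent with its own
modeling assumptions (held-out AUC > 0.85 at the default settings); it does
not emulate the degree distribution of real association databases, real
MeSH topology, or literature-confirmation case studies, and it says nothing
about the published real-data AUC values.

A known honest failure: the reference work reports that the denoising stage
improves fivefold AUC on real data. On this synthetic world, at
$\varphi = 1$, the decomposition is nearly the identity
($\|X\|_F \approx 0.1 \|A\|_F$) and the measured with/without-denoising
margin is a numerical tie (about $-10^{-4}$ over five seeds). The
corresponding acceptance test is implemented exactly as specified and left
failing rather than tuned: neither the generator's noise model nor
$\varphi$ was adjusted after observing the outcome. Smaller $\varphi$
(e.g. 0.1) makes the denoiser far more aggressive and is worth exploring on
real data, but no published value exists to anchor it.

## Numerical notes and limitations

* The IALM inner solve caches one Cholesky factorization of
  $I + A^\top A$; cost per iteration is dominated by an
  $n_d \times n_d$ SVD.
* `svt` relies on LAPACK's deterministic SVD; singular-vector sign
  ambiguity cancels in the reconstruction.
* The factorization's per-row systems are positive definite whenever
  $\vartheta > 0$; $\vartheta = 0$ with rank-deficient $V$ raises an error
  naming the row rather than silently regularizing.
* Quantile ties in the generator are resolved by taking exactly the
  `round(density * nm * nd)` strongest pairs.
* Scaling: all stages are dense; the intended regime is up to a few
  thousand entities per class. The reference-scale dataset
  (853 x 591) fits comfortably; tens of thousands would need sparse or
  truncated-SVD variants that are out of scope.
* Identifier matching between association and similarity inputs must be
  done upstream; `align_inputs()` intersects and warns, it does not map
  synonyms.
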