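---
title: "Permutation inference for the PLS correlation: models, rotations, and what they test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for the PLS correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsperm)
```

## The model

The PLS correlation asks which weighted combinations of the features of
one block covary most with weighted combinations of the features of a
second block measured on the same $n$ observations. With column
z-scored matrices $X$ ($n \times p$) and $Y$ ($n \times q$), the
cross-correlation matrix

$$C = \tfrac{1}{n-1} X^\top Y$$

is decomposed by SVD, $C = U \Sigma V^\top$. A latent variable (LV) is
a matched pair of columns of $U$ and $V$ (brain and behaviour feature
weights) with its singular value $\sigma_i$; LVs are orthogonal,
ranked by $\sigma_i$, and there are always $k = \min(p, q)$ of them.
The fraction of cross-block covariance an LV captures is
$\sigma_i^2 / \sum_j \sigma_j^2$ (its *strength*).

Conventions worth stating because the literature leaves them implicit:

* **Variance denominator.** $n - 1$ throughout, in the z-scoring and in
  $C$, so every entry of $C$ is an exact Pearson correlation. The
  alternative ($n$) changes nothing downstream as long as it is used
  consistently; we standardise on $n-1$ because the definition of $C$
  prints that factor.
* **Sign convention.** SVD signs are arbitrary; each LV's sign is fixed
  so the largest-magnitude element of its $V$ column is positive.
  Stability metrics take absolute values anyway; the convention only
  makes outputs reproducible across LAPACK builds.
* **Rank deficiency.** $k$ is always $\min(p,q)$ even when $C$ is
  numerically rank deficient; trailing near-zero singular values are
  retained so the null-distribution bookkeeping has a fixed LV count.
  Tied singular values keep the order LAPACK returns; tied LVs are not
  individually identifiable.

## The four permutation tests

Significance of LV $i$ is assessed by re-running the decomposition on
row-shuffled data. On instance $t$ the rows of $Y$ are permuted and
$C^{(p)} = U^{(p)} \Sigma^{(p)} V^{(p)\top}$ recomputed. The four
methods differ in what is added to the null distribution of LV $i$:

* **none** — the permuted singular value $\sigma^{(p)}_i$ itself.
* **behaviour** — the orthogonal Procrustes problem is solved to find
  the $k\times k$ orthogonal $R$ mapping $V^{(p)}$ as closely as
  possible to $V$ in least squares: from the SVD
  $V^{(p)\top}V = N O P^\top$, $R = N P^\top$. Each row $i$ of $R$ is
  scaled by $\sigma^{(p)}_i$ and the null value is the L2 norm of
  column $i$ of $V^{(p)}\Sigma^{(p)}R$ — equivalently, of
  $\Sigma^{(p)} R$, since $V^{(p)}$ has orthonormal columns.
* **brain** — the same construction on the $U$ side.
* **both** — the behaviour-side and brain-side values on the same
  permuted decomposition, averaged elementwise.

The p-value for LV $i$ is the proportion of its null values greater
than or equal to $\sigma_i$. Ties count as exceedances and values below
$10^{-12}$ are floored to zero before comparison, both conservative. A
`(count + 1)/(nPerm + 1)` estimator is available behind `addOne =
TRUE` (it guarantees validity but is off by default to match the
literal proportion definition). Whether the null values are compared
with strict `>` or `≥` is not fixed by the definition "proportion
exceeding"; `≥` was chosen as the conservative reading.

### Shared shuffle indices

All four methods consume identical permutation instances: a single
table of row shuffles is drawn from the seed up front, so cross-method
p-value differences are attributable to the rotation alone. One design
choice deserves emphasis. The brain-side test is defined by permuting
the rows of $X$; here the shared index row is applied to $X$ as its
*inverse* permutation. Pairing $X[\pi^{-1},]$ with $Y$ is row-for-row
identical to pairing $X$ with $Y[\pi,]$, so all four methods score the
*same* permuted cross-correlation per instance. This is the strongest
reading of "identical indices across tests": with it, the methods
coincide exactly (bit for bit) when $k = 1$, and per-instance
differences cannot arise from summation order. Degenerate draws (the
identity permutation) are kept; rejecting them would bias the null.

### Why rotated tests favour LV1

Write $d = \operatorname{diag}(\Sigma^{(p)})$. The rotated null value
for LV $i$ is $\big(\sum_j d_j^2 R_{ji}^2\big)^{1/2}$ with the columns
of $R$ unit vectors. Two consequences are load-bearing and are asserted
as invariants in the test suite:

1. **Conservation**: $\sum_i val_i^2 = \sum_i d_i^2$ — the rotation
   redistributes permuted covariance across LVs but cannot create it.
2. **LV1 dominance**: $val_i \le d_1$ for every $i$ — no rotated value
   can exceed the largest permuted singular value. Since the unrotated
   LV1 null value *is* $d_1$, the rotated LV1 null is weakly smaller on
   every instance, hence (with shared indices) the rotated LV1 p-value
   is never larger than the unrotated one on any dataset. This is the
   mechanism behind the high LV1 error rates of rotated tests on null
   data.

## Strength and stability

Covariance explained complements the p-value as an effect-size
measure. Split-half stability (`splitHalfStability()`) randomly halves
the sample (odd $n$: the extra row goes to the first half), runs the
decomposition on each half, and records the absolute Pearson
correlation between the halves' weight vectors per LV and block, over
`nSplits` splits (study default 100). LVs are matched between halves
by rank order — deliberately *without* Procrustes alignment, which is
a bootstrap convention, not part of this metric. Under the null,
half-sample weight vectors are near-independent random directions, so
the expected stability floor is $E|r| \approx \sqrt{2/(\pi p)}$
(about 0.08 at $p = 90$); values near the floor mean "not stable", not
zero exactly.

Bootstrap reliability (`bootstrapReliability()`) resamples
observations with replacement (study default 10,000), re-runs the
decomposition, and Procrustes-aligns each resample to the original via
the brain component — the bootstrap is where the rotation is
historically at home, since a resample contains the same effects
possibly reordered. It reports bootstrap ratios (mean aligned weight /
SD across resamples; SD below $10^{-12}$ is floored, the ratio capped
and flagged) and behavioural loadings with percentile 2.5/97.5%
intervals. Loadings are correlations between each $Y$ variable and the
$Y$ latent scores on the original sample; the intervals are computed
from loadings recomputed inside each aligned resample. Whether
reference implementations compute those resample loadings before or
after alignment is not documented anywhere we know of; aligned was
chosen for coherence with the ratio computation. Percentile rather
than BCa intervals: nothing in the procedure being emulated specifies
more than "95% confidence intervals across bootstrap samples".

## The generative model

`buildJointCorrelation(p, q, r)` constructs a population correlation
matrix with exactly one cross-block latent effect: unit-vector pair
$(a, b)$ drawn uniformly on the spheres of the whitened spaces and

$$C_{XY} = C_{XX}^{1/2}\, a\, r\, b^\top C_{YY}^{1/2},$$

which makes the first population canonical correlation exactly $r$ and
leaves the remaining pairs unconstrained. By default
$C_{XX} = I_p$, $C_{YY} = I_q$. Real brain measures are not
uncorrelated within block; the identity default is a deliberate
simplification that keeps the embedded canonical correlation
analytically exact (verified to $10^{-8}$ against an independent
generalized-eigenvalue computation in the tests). A `within = "decay"`
mode provides power-law eigenvalue-decay within-block correlation
(random eigenvectors, eigenvalues $\propto i^{-\alpha}$, rescaled to
unit diagonal); the embedded $r$ remains exact by construction because
the cross block is defined through the whitened spaces. Datasets are
drawn from the multivariate normal with this joint correlation
(`sampleDataset()`); `addNoise()` adds iid $N(0, s^2)$ measurement
noise to both blocks *after* sampling and *before* the z-scoring that
happens inside the PLS, so noise SD $s = 1$ on unit-variance data
halves every pairwise correlation.

What the generator does **not** emulate: within-block correlation
matched to empirical cortical covariance, non-Gaussian margins,
multiple latent effects ($m = 1$ always), missing data, and
site/batch structure. Passing simulation results therefore speak to
the statistical behaviour of the tests under a clean single-effect
model, not to robustness against those features of real data.

## The simulation sweeps

`runAnalysis()` orchestrates the four study designs: `random`
(iid-normal null data across sample sizes), `sample_size` (one effect
at $r = 0.3$), `canonical_correlation` (effects of varying $r$ at
$n = 1000$), and `noise` (noise SD swept at $n = 1000$, $r = 0.3$),
always with $p = 90$, $q = 10$. Study-scale grids are 10 sample sizes
log-spaced 10–10,000, 10 correlations linearly spaced 0.1–0.9, 10
noise SDs linearly spaced 0–1, with 100 replicates, 10,000
permutations and 100 splits per dataset. Per-replicate seeds are
derived from the master seed up front, so results are reproducible and
independent of evaluation order; stability is computed once per
dataset (it does not depend on the rotation method). `passRate()`
aggregates the fraction of replicates with $p < \alpha$ (strict, at
$\alpha = 0.05$), which is the empirical type-I error on null data and
power otherwise.

The packaged test suite exercises scaled-down versions of these
sweeps: 500 replicate null datasets at $n = 100$ with 1000
permutations for the calibration check, and 20 replicates with 500
permutations and 20 splits per grid point for the trend checks over
$n \in \{10, 100, 1000, 10000\}$, $r \in \{0.1, 0.5, 0.9\}$ and noise
SD $\in \{0, 0.5, 1\}$. These sizes were chosen so the full suite runs
in minutes while keeping the binomial error of a pass-rate estimate
(about $0.01$ at 500 replicates) well below the effects being
detected.

One boundary of the trend checks is intrinsic rather than a matter of
replicates: when $n$ is below the larger feature count (here
$n = 10 \ll p = 90$) the sample decomposition overfits, inflating LV1
covariance explained, while split-half stability sits at the
random-direction floor and the unrotated pass rate at the $\alpha$
floor. Monotone growth in $n$ is therefore asserted from $n = 100$
upward, with the $n = 10$ point checked against its floor instead.

## Numerical choices and degenerate inputs

* Zero-variance columns are rejected at validation with the offending
  column named; z-scoring is undefined there. Bootstrap resamples that
  make a column constant are redrawn and counted.
* Orthonormality, reconstruction and conservation identities hold to
  $10^{-8}$ in the tests; p-value comparisons floor singular values at
  $10^{-12}$.
* `numLV` is fixed at $\min(p,q)$; degenerate (rank-deficient) inputs
  keep their trailing zero LVs.
* All randomness is consumed through explicit integer seeds
  (`withr::with_seed`), so every object in the package is bit
  reproducible from its arguments.

## Limitations

The p-values of both rotated and unrotated tests should be read with
the study's central caution in mind: rotated tests systematically
favour passing LV1 (the dominance invariant above makes this a
theorem, not an empirical tendency), while unrotated tests become
non-selective at very large $n$. Strength and stability metrics are
reported alongside significance precisely because neither family of
p-values is sufficient on its own.
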