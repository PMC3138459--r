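---
title: "B-spline mutual information and network inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{B-spline mutual information and network inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splineMI)
```

## The estimator

Mutual information between two gene-expression profiles `X` and `Y`
with `M` measurements each is estimated as
`MI(X, Y) = H(X) + H(Y) − H(X, Y)`, with all three Shannon entropies
taken over a discretisation of the continuous measurements into `R`
bins. Hard histogram binning assigns each measurement to exactly one
bin, which makes the estimate sensitive to measurements sitting near bin
edges. The B-spline estimator softens the assignment: each measurement
is first normalised onto the spline domain,

$$z_i = \frac{x_i - x_{\min}}{x_{\max} - x_{\min}} \,(R - k + 1),$$

and then given fractional membership $B_{j,k}(z_i)$ in bin $j$, where
$B_{j,k}$ are the `R` B-spline basis functions of order $k$ on the
clamped uniform knot vector ($k$ zeros, the integers $1 \dots R-k$, and
$k$ copies of $R-k+1$). The memberships of one gene form its $M \times R$
*weighting matrix*; each valid row sums to 1 (partition of unity), so
marginal bin probabilities are column means and the joint distribution
of a pair is the cross-product of the two weighting matrices divided by
`M`. With `k = 1` the basis degenerates to bin indicators and the whole
pipeline reproduces hard-binning MI exactly — a property the test suite
checks against an independently coded contingency-table estimator.

### Parameters

* `bins` (`R`, default 10): discretisation resolution. More bins resolve
  finer dependence structure but raise the variance of each cell.
* `order` (`k`, default 3, constrained to `1 ≤ k ≤ R − 1`): each
  measurement spreads over up to `k` adjacent bins. Order 3 is the
  conventional compromise between noise robustness (higher `k`) and
  resolution (lower `k`).
* `log_base` (default 2): entropies and MI in bits. The base is a global
  rescaling only; it never changes rankings, thresholds expressed in the
  same base, or network topology.

### Numerical conventions

* **Right endpoint.** The order-1 base case uses half-open intervals
  $[t_i, t_{i+1})$, which would leave the domain maximum uncovered; the
  last basis function is defined to take value 1 there. Without this the
  largest measurement of every gene would receive zero total weight and
  row normalisation would break.
* **Degenerate genes.** A gene whose observed values are all identical
  has an undefined normalisation (zero denominator). The package raises
  a classed error by default; `pairwise_mi(..., on_degenerate = "drop")`
  and the CLI flag `--drop-degenerate` instead remove the gene with a
  warning. Silent zero-filling would corrupt downstream MI values.
* **Interior ties.** A measurement falling exactly on an interior knot
  belongs to the right-hand interval (half-open convention). For orders
  above 1 the basis is continuous, so the choice only matters at
  `k = 1`, where it matches the usual histogram convention.
* **Negative clamping.** Estimated MI is a KL divergence of the
  estimated joint against the product of its own marginals and is
  therefore nonnegative; values in `(−1e−9, 0)` arising from summation
  roundoff are reported as 0, anything more negative raises an
  internal-consistency error rather than being hidden.
* All arithmetic is double precision.

### Missing measurements

Missing cells (`NA`, blank or the `NA` token on disk) are handled
pairwise complete-case. Weighting matrices are built per gene over that
gene's own observed values, but for each pair the joint *and* both
marginals entering the entropies are recomputed over the measurements
observed in both genes, so the marginals are exact marginals of the
joint — the only convention under which the nonnegativity guarantee
survives missingness. Fully observed data takes a fast path that skips
the intersection logic.

A consequence worth noting: with missing data the diagonal self-entropy
of the MI matrix (computed from each gene's own observed values) is not
the same quantity as the marginal entropies used inside a particular
pair, which are restricted to that pair's shared measurements.

### Blocked execution

Storing all weighting matrices costs `8 · N · M · R` bytes in double
precision. `partition_plan()` bounds peak memory: genes are split into
`P` groups for weighting-matrix construction and into `Q` groups for
the pairwise stage, which walks all group pairs and computes each
block's joints with one stacked matrix product. A `memory_budget` in
bytes derives the group size from the footprint formula (keeping two
groups resident); a budget too small for even one pair of weighting
matrices is rejected as infeasible. Every plan visits each pair's full
measurement set in the same order, so results agree across plans to
floating-point roundoff (the contract is 1e−12, in practice ~1e−15),
and within-group blocks are explicitly symmetrised so the returned
matrix equals its transpose exactly.

## What the estimator converges to

For fixed `R` and `k` the estimator's large-`M` limit is the mutual
information of the *spline-smoothed discretisation*, not of the
underlying continuous pair. Discretisation can only destroy information,
and the soft assignment smooths further, so the limit sits strictly
below the continuous MI whenever the dependence is strong relative to
the bin resolution. Numerical quadrature of the estimator's defining
expectation against an exact bivariate normal density with correlation
0.9 gives a population value of about 0.51 bits at `R = 10, k = 3`,
versus 1.198 bits for the continuous MI. Finite samples add a positive
bias that shrinks as `M` grows, so estimates approach that population
value from above; the test suite asserts exactly this convergence
direction (and that independent pairs drift toward 0 as `M` grows)
rather than convergence to the continuous value. For network inference
this underestimation is immaterial: thresholding and DPI pruning depend
only on the ordering of MI values, which the smoothing preserves.

## Network inference

`infer_grn()` chains four stages, all deterministic given `seed`:

1. **Pairwise MI** for all unordered pairs (blocked, as above).
2. **Permutation null.** Each of `B` samples (default 10,000, at least
   1,000) is the MI of a randomly chosen gene pair after permuting one
   gene's measurement order — dependence is destroyed, both marginals
   are preserved. Because normalisation is order-invariant, the
   permuted gene's weighting matrix is just a row permutation of the
   original, so the null costs one small matrix product per sample.
3. **Threshold.** For a target P-value at or above `1/B` the threshold
   is the empirical `1 − p` quantile of the null. The default P-value of
   1e−5 lies below the resolution of any affordable `B`, so the upper
   tail is extrapolated with a log-linear fit of the survival function
   (`ln P ≈ a + b·MI` on the top 5% of samples), the classic
   large-deviation tail form; the fit is validated in the tests against
   the closed-form quantile of an exponential null. Edges at or above
   the threshold enter the network.
4. **DPI pruning** at tolerance τ (default 0.01): in every fully
   connected triangle, edge `(i, j)` is marked when
   `MI(i,j) < (1 − τ)·min(MI(i,k), MI(j,k))`, all marks computed against
   the original thresholded network and removed simultaneously. This
   makes the result independent of edge enumeration order — a 4-node
   test case in the suite distinguishes it from sequential removal —
   and makes `apply_dpi` idempotent. τ is dimensionless, so the choice
   of entropy base does not interact with it.

All edges are undirected (MI is symmetric); directed gold standards are
collapsed to unordered pairs before scoring, and scoring counts
TP/TN/FP/FN over all `C(N, 2)` pairs, with precision reported as `NA`
(never 0 or 1) when no edges were inferred.

## The synthetic generator

`simulate_network_expression()` emulates the statistical shape of
simulator-generated benchmark data: a directed acyclic topology sampled
over an ordered gene list (preferential attachment by regulator
out-degree, or uniform), Hill-type responses per interaction
(activation with probability 0.7, coefficient in {1, 2, 4},
half-saturation uniform in [0.3, 0.7]), multiple regulators combined by
averaging, and independent steady-state conditions with uniform root
inputs and additive Gaussian noise (`noise_sd` default 0.1 on the unit
response scale — strong enough that hard binning is visibly noisy,
weak enough that direct interactions stay detectable, which is the
regime such benchmarks are built for). Defaults of 250 genes, 500
experiments and 385 interactions match the scale at which MI-based
inference is commonly benchmarked. The generator is a pure function of
its arguments including `seed`.

What it does **not** emulate: curated source-network topologies,
interpolated kinetics fitted to real organisms, time-series dynamics,
biological replicate structure, or microarray-specific noise
(saturation, spatial artefacts). Passing tests therefore demonstrate
correct estimator arithmetic and a working inference pipeline under
controlled nonlinear dependence — not performance claims on real
expression compendia, where edge density, noise and confounding are far
less favourable.

## Problem sizes used in the tests

The routine suite exercises genes × measurements up to 30 × 200 for
oracle-equivalence checks, 50,000-sample Gaussian pairs for calibration,
2,000-measurement three-gene chains for DPI behaviour, and one full
250 × 500 inference run; scalability-oriented shapes are exercised in
reduced form, with larger matrices generated on demand by
`random_expression()`. These sizes keep the whole suite in the
tens-of-seconds range while covering every code path, including blocked
execution with several partition plans.

## Known limitations

* Absolute MI values depend on (`R`, `k`) and sit below the continuous
  MI (see above); compare MI values only across a fixed configuration.
* The permutation null draws gene pairs at random, pooling over genes;
  per-pair nulls would be more faithful for very heterogeneous marginal
  distributions at quadratically higher cost.
* The tail extrapolation assumes an asymptotically exponential null
  tail; for very small `B` or heavily tied null samples it refuses to
  extrapolate rather than guessing.
* Knot vectors are fixed to the clamped uniform form; non-uniform or
  data-adaptive knots, spline derivatives and adaptive bin counts are
  out of scope.
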