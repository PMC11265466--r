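---
title: "Multi-weight multimorbidity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-weight multimorbidity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnet)
```

## The problem

Multimorbidity — two or more chronic conditions in one person — is usually
described through a co-occurrence network: conditions are nodes, and an edge
connects two conditions that occur together more often than some benchmark.
Everything downstream of that network (its communities, its central
conditions, its visual story) depends on the *weight* chosen for the edges,
and the applied literature uses several inequivalent ones. `mmnet`
implements five common choices side by side, so that the sensitivity of the
network's composition to the weight can be examined directly on the same
cohort.

The input is a binary cohort matrix $X \in \{0,1\}^{N \times D}$ (subjects
by conditions), or equivalently its co-occurrence summary: the symmetric
joint-count matrix $A$ with $A_{ij} = \#\{s : X_{si} = X_{sj} = 1\}$, a
structurally zero diagonal, marginal counts $n_i$, and the total $N$.

## The five association weights

For a pair $(i, j)$, write the 2×2 contingency cells as $n_{11}, n_{10},
n_{01}, n_{00}$ with $N = n_{11} + n_{10} + n_{01} + n_{00}$.

* **Odds ratio** $\mathrm{OR} = (n_{11} n_{00}) / (n_{10} n_{01})$.
* **Lift** $= \dfrac{n_{11}/N}{(n_{1\cdot}/N)(n_{\cdot 1}/N)}$, equal to 1
  under independence.
* **Phi** — the Pearson correlation of the two binary indicators,
  $\phi = (n_{11} n_{00} - n_{10} n_{01}) / \sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}$.
* **Salton cosine index** $\mathrm{SCI} = n_{11} / \sqrt{n_{1\cdot} n_{\cdot 1}}$,
  the joint count over the geometric mean of the marginals; in $[0, 1]$.
* **Normalised joint frequency (NF)** — iterative proportional fitting (IPF)
  applied to the zero-diagonal joint-count matrix until every row and column
  sums to one; the fitted off-diagonal entries are the weights. This removes
  the direct effect of differing prevalences and depends only on the matrix
  up to a global scale.

All five are computed from counts, never from rounded proportions, and all
are symmetric in the two conditions.

### Numerical choices

* **Zero cells (OR).** A zero cell makes the OR 0, infinite or undefined.
  The default policy is the Haldane–Anscombe correction: add 0.5 to all four
  cells, and flag the pair (`flag_zero_cell`). An `error` policy is
  available for users who prefer to fail loudly. Rare-condition pairs in
  realistic cohorts do hit zero cells, so a default policy is needed.
* **Undefined weights.** If a condition is absent from (or universal in)
  the cohort, lift, phi and SCI are undefined for its pairs; these are `NA`,
  flagged, and excluded from percentile computation rather than imputed —
  an absent condition has no meaningful association to rank.
* **IPF.** Alternating row/column scaling, tolerance `1e-10` on the maximum
  margin deviation, cap of 10,000 sweeps, and final symmetrisation by
  averaging with the transpose (alternate scaling transiently breaks
  symmetry). Some sparse supports (a path, a star) admit no doubly
  stochastic matrix at all; the function then raises a non-convergence error
  carrying the final margin deviation instead of returning a half-converged
  matrix.

## Top-pair selection

For each measure, the pairs whose weight lies **strictly above the 90th
percentile** of that measure's defined weights are the "top pairs"; only
they become edges. The percentile uses the linear-interpolation empirical
quantile (type 7, the default of mainstream numerical software). Both the
convention and the strictness are exposed (`percentile`, `strict`) because
neither is forced by the rule's usual verbal statement; with 351 distinct
weights the default yields exactly 35 selected pairs. Ties exactly at the
threshold are dropped (a literal reading of "above"), and a degenerate
all-equal weight column selects nothing, with a warning. Because selection
is a rank rule it is invariant to strictly increasing transforms of a
weight, e.g. OR versus log-OR. Negative phi values enter the percentile
as-is; top-decile selection only ever retains large positive values, so no
absolute-value convention is needed.

## Communities and centralities

Each measure's network keeps **all** conditions as nodes (isolated nodes
included, so "did not join a community" is observable) and carries the
measure's weight on the selected edges. Partitions are scored by weighted
modularity at resolution $\gamma$:

$$Q = \frac{1}{2m} \sum_{ij} \left[ A_{ij} - \gamma\,\frac{K_i K_j}{2m} \right] \delta(c_i, c_j),$$

with $2m = \sum_{ij} A_{ij}$ and $K_i$ the node strengths. The default
$\gamma = 1$ is used for all five networks. Communities are found with the
Leiden algorithm (igraph's implementation; greedy local moving with
refinement and aggregation) restarted `n_restarts = 10` times from seeded
RNG states; the partition with the highest `modularity_q()` wins, which
makes the result deterministic given `seed` and never worse than the best
restart. On all small graphs we can check exhaustively, the returned Q
matches the true optimum (see the test suite); "unjoined" conditions are
operationalised as singleton communities, which automatically includes
every degree-0 node.

Centralities are weighted degree (strength), closeness (reciprocal of the
summed shortest-path lengths) and betweenness (fractional shortest-path
pass-through credit). Shortest paths need *lengths*, and an association
weight is a proximity, not a cost; the default transform is therefore
`1/w`, with `identity` available to reproduce tools that read weights as
costs. The choice can flip rankings, which is exactly why it is explicit.
Closeness on a disconnected network is restricted to the node's component
(component size is reported alongside); isolated nodes get closeness 0 by
convention, and disconnected pairs contribute nothing to betweenness.

## Concordance between measures

`overlap_summary()` counts pairs selected by at least one, by all five, and
by exactly one measure, and computes the 5×5 Cohen's kappa matrix,
$\kappa = (p_o - p_e)/(1 - p_e)$. The **base set** for kappa is a genuine
modelling choice: agreement can be evaluated over the union of top pairs or
over all $D(D-1)/2$ candidate pairs (where the many joint non-selections
inflate agreement). The default is the union base: on the bundled reference
selection it gives $\kappa_{\mathrm{OR,lift}} = 0.85$, versus ≈ 0.94 under
the all-pairs base. The reported summary always states which base was used.
This default was chosen because it is the only base consistent with the
reference study's published kappa; the original base set was not stated, so
the reconstruction is documented here rather than asserted.

Prevalence-stratified contributions (`prevalence_group_contributions()`)
count, per measure, the selected pairs containing at least one condition
from a given set of prevalence ranks. Counting *pairs* (rows of the
selection table) reproduces every published trio summary the bundled table
supports; an `incidence` option counts each in-set member separately (a
pair with both members in the set counts twice) and satisfies the identity
"contributions over all ranks = 2 × per-measure totals". One residual
discrepancy is inherent to the bundled table: for the three
lowest-prevalence conditions the odds-ratio column supports a count of 12,
while the prose summary published alongside the original tables says 13 —
the table as typeset cannot yield 13, so the package reports 12.

## The synthetic cohort generator

There is no public subject-level cohort behind the reference tables, so the
package ships a generator rather than data. `generate_cohort()` draws from
a **Gaussian copula**: a latent $\mathcal{N}(0, R)$ vector is thresholded
coordinate-wise at $\Phi^{-1}(1 - p_d/100)$, giving exact marginal control
(the study conditions: the 27 reference prevalences, 33.4% down to 1.5%)
with tunable dependence. $R$ comes from a planted block structure:
`rho_within` for same-block pairs, `rho_between` across blocks, 0 for
conditions declared `isolated`. If the implied matrix is not positive
semi-definite it is repaired by clipping negative eigenvalues at zero and
renormalising to unit diagonal (tolerance `1e-8`). An optional
multimorbidity filter redraws subjects with fewer than two conditions
(rejection sampling, so `n_subjects` is exact; a rejection rate above 99%
errors out). A single integer seed governs the whole draw, redraws
included.

What the generator does **not** emulate: age/sex structure, ICD coding,
cause-of-death ordering, and the particular joint frequencies of the
reference cohort. Tests that pass on synthetic cohorts therefore validate
the *pipeline* — marginal control, monotone dependence, recovery of planted
structure — not any claim about real death-certificate data.

### The end-to-end recovery experiment

The strongest pipeline test plants two blocks over the 27 reference
conditions (blocks interleaved by prevalence rank, so both contain common
and rare conditions, as real comorbidity clusters do), `rho_within = 0.5`,
`rho_between = 0`, one mid-prevalence condition (rank 5) structurally
isolated, and $n = 50{,}000$ subjects per draw across 10 seeds. On each
draw, the phi top-pair network is clustered by Leiden. Because the 90th
percentile retains only ~35 of 351 pairs, the rarest conditions are
isolated *by construction of the threshold*; exact recovery is therefore
defined as ARI = 1 between planted block labels and community labels over
the nodes with degree ≥ 1 (about 14–15 of 27), with the structurally
isolated condition required to appear in the unjoined list. The suite
requires success in at least 9 of 10 seeds.

## Limitations

* No inference: the selection is percentile-based, and no confidence
  intervals, p-values or FDR control are attached to weights or kappa.
* The NF weight requires every condition to co-occur with something;
  cohorts violating that fail at the IPF stage by design.
* Closeness/betweenness depend on the distance convention; comparisons
  across published analyses must match conventions before comparing ranks.
* Modularity at a single resolution inherits modularity's resolution
  limit; $\gamma$ is exposed but only $\gamma = 1$ is exercised here.
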