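---
title: "The variance of leaf depths as a tree shape index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The variance of leaf depths as a tree shape index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthvar)
```

## The index

For a rooted tree $T$ with $n$ leaves and leaf depths $\delta_T(x)$ (arcs from
the root), the package centres on the population variance of the depth
multiset $\Delta(T)$,

$$V(T) \;=\; \frac{1}{n}S^{(2)}(T) - \frac{1}{n^2}S(T)^2,
\qquad S(T) = \sum_x \delta_T(x),\quad S^{(2)}(T) = \sum_x \delta_T(x)^2 .$$

$V$ was the quantity behind the earliest proposals of measuring tree
imbalance by the "variation" of leaf depths, later displaced in practice by
the Sackin index $S$.  $V$, $S$, $\hat S = S/n$ and $S^{(2)}$ depend on a
tree only through $\Delta(T)$, so depth-equivalent trees (equal depth
multisets) are indistinguishable to them.  The total cophenetic index
$\Phi(T)$ — the sum over unordered leaf pairs of the depth of their lowest
common ancestor — is also provided; it does depend on more than $\Delta(T)$.

Trees here are rooted, without out-degree-1 nodes, and compared up to
isomorphism of unordered trees.  A phylogenetic tree additionally carries a
bijective leaf labeling, which all depth indices ignore.

## Exact arithmetic

Every index value and every model moment in this package is a rational
number, and the package computes them exactly: $n^2 V = nS^{(2)} - S^2$ is a
non-negative integer and is used as the comparison key whenever minima or
ties are at stake, so no tolerance parameter exists anywhere in the extremal
machinery.  Because no arbitrary-precision arithmetic package is available
in R's standard ecosystem installed here, `depthvar` carries a small exact
layer of its own: big integers as base-$10^7$ limb vectors stored in
doubles (every intermediate product stays below $2^{53}$, so limb
arithmetic is exact), and an `rq` rational class on top with normalized
fractions and cross-multiplied comparisons.  Doubles appear only at output
boundaries, rendered at 4 decimals by default to match the precision at
which the reference quantities are conventionally printed.  For routine
inputs (`depth_statistics()` on trees of ordinary size) plain double
arithmetic is provably exact and is used for speed; the big-integer path
engages automatically when $S^2$ or $nS^{(2)}$ could exceed $2^{53}$.

## Extremal trees

**Maximum.**  The maximum of $V$ over all rooted trees with $n$ leaves
(multifurcating included) is attained exactly at the comb $K_n$, whose
depth multiset is $\{1,2,\dots,n-2,n-1,n-1\}$, giving
$V(K_n) = (n-1)(n-2)(n^2+3n-6)/(12n^2)$.  `max_variance()` implements the
closed form; the test suite checks maximality exhaustively over all shapes
with up to 12 leaves and on random multifurcating trees.

**Minimum.**  Over bifurcating trees the minimum is subtler.  The candidate
classes are the depth-equivalence types $T_{n;\,l_1,\dots,l_j}$: trees with
one leaf at depth $\delta - l_i$ for each $i$ and all remaining leaves at
depths $\delta$ or $\delta-1$.  The empty sequence ($j=0$) is the
minimal-Sackin class $F_n$ — exactly the trees depth-equivalent to the
maximally balanced tree $B_n$, with $V(F_{2^m+k}) = 2k(2^m-k)/n^2$.
Writing $n = 2^m + k$, the counts $p_1$ (depth $\delta-1$) and $p_0$
(depth $\delta$) of a type fall into four cases resolved by
`type_profile()`; one case is infeasible (no such tree exists), and the
package routes *all* feasibility decisions through this single function.
Feasible types have
$V = \big(n(p_1 + \sum l_i^2) - (p_1 + \sum l_i)^2\big)/n^2$.

Any minimizer of $V$ on bifurcating trees with $n \ge 5$ leaves is of some
type with $5 \le l_1 < \dots < l_j \le \lfloor\log_2 n\rfloor$, so
`min_variance()` enumerates the $2^{m-4}$ l-subsets of
$\{5,\dots,m\}$, skips infeasible ones, and minimizes the exact integer key
$n^2V$ — $O(n\log n)$ work in total.  The subset tables are built once per
$m$ and cached, which makes range scans (`scan_min_variance()`) cheap.  All
co-minimizers are reported: uniqueness of the optimal type is an open
conjecture, so the code never assumes it (empirically the argmin is unique
at every $n$ we scan).

The looser classification bound $2 \le l_1 \le \delta-2$ (used by
`classify_type()` when reading a type off a tree) is deliberately distinct
from the search bound $l_1 \ge 5$: the former defines the type family, the
latter is the proven necessary condition for minimizers and is what keeps
the search quasilinear.

This machinery reproduces a striking phenomenon: for every $n \le 183$ the
minimum of $V$ sits at the maximally balanced class, but at $n = 184$ a
tree with 174 leaves at depth 8, 9 at depth 7 and one at depth 2 does
better ($8055/33856 \approx 0.2379$ versus $8064/33856 \approx 0.2382$),
and beyond that the balanced class is optimal only in small dyadic windows
around powers of 2 — e.g. throughout $[2^m-29,\,2^m]$, with type
$T_{n;6}$ taking over at $n = 2^m - 30$.  So $V$, taken literally as a
balance index, stops agreeing with every other standard balance index for
almost all large $n$; the scan summaries (`first_unbalanced()`,
`argmin_runs()`, `balanced_fraction()`) expose exactly this structure.

## Materializing types

Types are depth-equivalence classes, and nothing in the theory singles out
a canonical member, so `tree_from_depths()` materializes one representative
by Huffman-style pairing: repeatedly merge two deepest pending nodes into a
parent one level up.  When more than two nodes share the maximum depth the
pair choice is arbitrary — the resulting depth multiset is invariant under
that choice, which is what the indices see; tests assert this.  The same
bottom-up pairing, run in exact integer counts, decides realizability: a
depth multiset is realizable by a bifurcating tree iff its Kraft sum
$\sum_x 2^{-\delta(x)}$ equals 1 (validated against exhaustive enumeration
for $n \le 9$), and the integer form of the check is valid at any depth,
where the floating-point Kraft sum would underflow.

## Null models and their moments

Two classical null models for bifurcating phylogenetic trees on $n$ leaves
are implemented.  Under the **Yule** (Equal-Rate Markov) model a tree grows
by uniform random leaf replacement and then receives a uniform random
labeling; a labeled tree has probability
$P_Y(T) = \frac{2^{n-1}}{n!}\prod_v \frac{1}{\kappa_T(v)-1}$ over its
internal nodes' subtree leaf counts $\kappa$.  Under the **uniform** (PDA)
model all $(2n-3)!!$ labeled trees are equiprobable; the sampler inserts
leaf $k+1$ into one of $2k-1$ equiprobable positions (every arc, plus a
new-root position), which reproduces exactly that distribution and is
verified by a chi-square test over all 15 labeled 4-leaf trees.

Expectations are available through three independent routes, which the
tests require to agree:

1. **Closed forms** (`yule_moments()`, `uniform_moments()`,
   `uniform_covariances()`), e.g.
   $E_Y(V_n) = \frac{2(n+1)}{n}H_n + \frac{1}{n} - 5 \sim 2\ln n$ and
   $E_U(V_n) = \frac{(2n-1)(n-1)}{3n} - \frac{n-1}{2n}\,r_n \sim
   \frac{2}{3}n$, with $H_n$ the harmonic numbers and
   $r_n = (2n-2)!!/(2n-3)!! \sim \sqrt{\pi n}$.  The uniform-model
   variances of $S$ and $\Phi$ and their covariance give the limiting
   Pearson correlation
   $\rho_U(S_n,\Phi_n) \to \frac{(52-15\pi)/60}
   {\sqrt{\tfrac{10-3\pi}{3}\cdot\tfrac{56-15\pi}{240}}} \approx 0.965$.
2. **Exhaustive enumeration** (`expected_by_enumeration()`): every shape
   with $n \le 12$ leaves, generated once each via the unique unordered
   root decomposition, weighted by its labeled count $n!/2^q$ ($q$ =
   symmetric internal nodes) times the per-tree model probability, in
   exact rationals.
3. **Seeded samplers** (`sample_index_stats()`), checked to land within
   four standard errors of the enumeration values at $10^5$ draws.

The uniform-model moments all satisfy recurrences
$X_n = 2\sum_k C_{k,n-k}X_k + p(n) + q(n)\,r_n$ in the splitting weights
$C_{k,n-k}$, with polynomial forcing written in the binomial basis (no
constant term; `power_to_binomial()` converts via Stirling numbers).
`solve_recurrence()` implements the general closed-form solution of this
family and `iterate_recurrence()` runs the recurrence directly as an
independent check; the iteration multiplies through by $M\,(2n-3)!!$ (a
common denominator) so the whole computation stays in big integers and no
intermediate reduction is needed.  When the $r_n$ forcing part is absent
its coefficient list is padded with a single zero, which reproduces all
verified instances; the general $s = 0$ convention is not otherwise pinned
down by the solution formulas, so the padding is a documented choice.

## Numerical and design choices

* **Exact keys, no tolerances.**  Minima, ties, feasibility and
  realizability are integer decisions.  Floating point appears only in
  display columns and in the large-$n$ asymptotic helpers, where
  `digamma`/`trigamma`/`lgamma` give $H_n$, $H^{(2)}_n$ and $r_n$ to full
  double precision without overflow.
* **Edge cases.**  A single leaf has $S = V = \Phi = 0$ (empty pair sum);
  $n = 1, 2$ evaluate correctly through every closed form; rooted stars
  have $V = 0$, which is why $V$ (like $S$) cannot rank taxonomic trees
  whose leaves share one depth.
* **Seeds.**  Every stochastic routine takes an explicit seed and restores
  the session RNG state (`withr::with_seed`); the documented guarantee is
  reproducibility of a fixed `(n, model, seed, reps)` call, not
  cross-version stability of R's generator.
* **Unary nodes.**  Newick input containing out-degree-1 nodes is rejected
  by default, since the tree definition underlying all results excludes
  them; `collapse_unary = TRUE` (or `--collapse-unary` in the CLI)
  contracts them instead.
* **Problem sizes.**  The checked surfaces are sized for a desk run:
  exhaustive enumeration to $n = 20$ (293,547 shapes) for the
  minimum-oracle comparison and $n \le 12$ for model expectations; scans
  over $[4,200]$, $[2^9-30, 2^9]$ and $[2^{12}, 2^{13})$ for the boundary
  phenomena; $10^5$ draws per sampler check.  The search itself is exact
  and quasilinear, so scanning up to $2^{20}$ (the range behind the
  published minimum-$V$ tables) is a matter of minutes with
  `scan_min_variance()`, and nothing in the implementation caps it except
  a CLI guard.

## What the generators emulate — and what they do not

`random_tree()` is a fixture generator (seeded recursive splitting, 2–4
children per node in multifurcating mode); it targets structural coverage
of tree space for property tests, not any biological null model, and its
split-size distribution is not calibrated to real phylogenies.  The Yule
and uniform samplers are the models' defining growth processes and are
exact by construction.  None of the generators produce branch lengths,
extinction, or taxon-sampling effects, so passing tests say nothing about
how $V$ behaves on trees whose imbalance stems from those processes;
they certify the combinatorics and the moments, which is what this package
is for.

## Known limitations

* Indices beyond $V$, $S$, $\hat S$, $S^{(2)}$, $\Phi$ (Colless, rooted
  quartet index, cherry counts) are out of scope.
* No closed-form predictor of the optimal l-sequence as a function of $n$
  is known; `min_variance()` is inherently a (fast) search.
* `enumerate_shapes()` is capped at $n = 22$; labeled counts are exact
  doubles only through $n = 16$, where $(2n-3)!!$ last fits in $2^{53}$
  (the exact big-integer count is available via `n_labeled_trees(exact =
  TRUE)`).
* Yule-model variance of $\Phi$ and the Yule $S$–$\Phi$ covariance are not
  implemented; only the uniform-model second moments are.
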