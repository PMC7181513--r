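# depthvar

Tools for the **variance of leaf depths** of a rooted tree, `V`, as a
phylogenetic shape index — the statistic behind the earliest proposal of
measuring tree imbalance by the "variation" of leaf depths, implemented long
ago as a population variance and since largely displaced by the Sackin
index.  For systematists and method developers who want to use `V` (and the
Sackin index `S` and total cophenetic index `Phi`) in tree-shape tests, this
package provides:

* **Exact indices.**  For a tree with leaf depths `d(x)`:
  `S = sum d(x)`, `S2 = sum d(x)^2`, and
  `V = S2/n - (S/n)^2` — computed in exact arithmetic (`n^2 V` is always an
  integer), with a built-in big-integer/rational layer so no value is ever
  a floating-point approximation internally.  `Phi` is the sum over leaf
  pairs of their lowest common ancestor's depth.
* **Extremal trees.**  The maximum of `V` is closed-form,
  `V(K_n) = (n-1)(n-2)(n^2+3n-6)/(12n^2)` at the comb `K_n`.  The minimum
  over bifurcating trees is found by an exact `O(n log n)` search over
  candidate depth-equivalence types `T_{n; l1..lj}` (one leaf at depth
  `delta - l_i` each, all others at depths `delta` or `delta - 1`); the
  maximally balanced class is optimal for every `n <= 183` and almost never
  afterwards — `depthvar` reproduces the boundary `n = 184` and the dyadic
  windows `[2^m - 29, 2^m]` where balance returns.
* **Null-model moments.**  Exact closed forms for `E[V]` under the Yule and
  uniform (PDA) models, and for the uniform-model variances of `S` and
  `Phi` and their covariance (limiting `S`–`Phi` correlation ≈ 0.965) —
  the quantities needed to standardize these indices in tests; plus exact
  enumeration oracles and seeded samplers that cross-validate all of them.

## Worked example

```r
library(depthvar)

tree_indices(c("((((a,b),c),d),e);",   # 5-leaf comb
               "((a,b),(c,d));",       # balanced 4-leaf tree
               "(a,b,c,d,e);"))        # rooted star
#> # A tibble: 3 × 8
#>    tree     n depth     S  Shat    S2     V   Phi
#>   <int> <int> <int> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     1     5     4    14   2.8    46  1.36    10
#> 2     2     4     2     8   2      16  0        2
#> 3     3     5     1     5   1       5  0        0
```

The comb is the most imbalanced tree by every classical index: its `V` is
the maximum for 5 leaves (`max_variance(5)` = 1.36).  The balanced tree and
the star have constant leaf depths, hence `V = 0`.

The minimum-`V` search shows the index's surprise at `n = 184` — the most
"balanced" tree according to `V` is *not* the maximally balanced one:

```r
min_variance(184)
#> Minimum depth variance on bifurcating trees with n = 184 leaves
#>   min V = 8055/33856 = 0.237919
#>   attained at type(s): 6
#>   (maximally balanced class is NOT optimal)

scan_min_variance(180, 186)[, c("n", "min_V", "argmin_ls", "is_max_balanced")]
#> # A tibble: 7 × 4
#>       n min_V argmin_ls is_max_balanced
#>   <int> <dbl> <chr>     <lgl>
#> 1   180 0.244 -         TRUE
#> ...
#> 5   184 0.238 6         FALSE
```

Type `6` means the optimizer has one stray leaf 6 levels above the deepest
level: 174 leaves at depth 8, 9 at depth 7, one at depth 2, giving
`V = 8055/33856 ≈ 0.2379` versus `V(B_184) = 8064/33856 ≈ 0.2382`.
`autoplot(scan_min_variance(128, 1024))` draws the minimum-`V` landscape
with the balanced-optimal `n` highlighted.

Model moments, with exact values behind the printed doubles
(`yule_moments_exact()` etc. return `p/q` rationals):

```r
moment_table(3:8)
#> # A tibble: 6 × 6
#>       n    EY_V    EU_V  varU_S varU_Phi covU_SPhi
#>   <int>   <dbl>   <dbl>   <dbl>    <dbl>     <dbl>
#> 1     3 0.22222 0.22222 0         0         0
#> 2     4 0.45833 0.55000 0.16      0.64      0.32
#> 3     5 0.68    0.93714 0.77551   4.7755    1.9184
#> 4     6 0.88333 1.3624  2.2358   19.583     6.5805
#> 5     7 1.0694  1.8145  4.9991   58.975    17.044
#> 6     8 1.2402  2.2864  9.5765  146.23     37.090
```

`E_Y(V_n)` grows like `2 log n`, `E_U(V_n)` like `2n/3`.  A sampler
cross-check: `colMeans(sample_index_stats(8, "uniform", reps = 1e5,
seed = 1))` gives a mean `V` of 2.2892, within sampling error of the exact
2.2864.

A shell interface wraps the same functions
(`system.file("cli", "depthvar", package = "depthvar")`):

```sh
depthvar minvar -n 184 --exact
depthvar indices -i trees.nwk -o indices.tsv
depthvar expected --from 3 --to 8
depthvar sample -n 50 --model uniform --reps 100 --seed 7 -o sample.nwk
```

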