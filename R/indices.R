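#' Depth statistics: Sackin index, squared depths, and the variance V
#'
#' For a rooted tree with `n` leaves and leaf depths `d(x)`, computes the
#' Sackin index `S = sum d(x)`, the mean depth `Shat = S/n`, the sum of
#' squared depths `S2 = sum d(x)^2`, and the variance of the leaves' depths
#'
#'   `V = S2/n - (S/n)^2 = (n*S2 - S^2) / n^2`,
#'
#' the population variance of the depth multiset.  All quantities are exact:
#' `n^2 * V = n*S2 - S^2` is a non-negative integer, and `V` is returned both
#' as a double and as a reduced exact fraction (`V_num / V_den`).  Big-integer
#' arithmetic takes over transparently when the intermediate integers exceed
#' the double's exact range.
#'
#' These statistics depend on a tree only through its depth multiset, so any
#' depth-equivalent trees share them.
#'
#' @param x a `depth_multiset`, `tree_shape`, `phylo`, Newick string, or a
#'   vector of leaf depths.
#' @return A one-row tibble with columns `n`, `depth` (max leaf depth), `S`,
#'   `Shat`, `S2`, `V`, `V_num`, `V_den`.
#' @examples
#' depth_statistics(tree_comb(8))                        # V = 4.484375
#' depth_statistics(rep(c(8, 7, 2), c(174, 9, 1)))       # V = 8055/33856
#' @export
depth_statistics <- function(x) {
  d <- depth_multiset(x)
  n <- sum(d$count)
  delta <- max(d$depth)
  # sums of c*d and c*d^2 are exact in doubles only below 2^53; bound first
  small_sums <- n * delta ^ 2 < 2 ^ 53
  if (small_sums) {
    S <- as.double(sum(as.double(d$depth) * d$count))
    S2 <- as.double(sum(as.double(d$depth) ^ 2 * d$count))
  } else {
    S_bi <- bi_sum_terms(d$count * d$depth)
    S2_bi <- bi_sum_terms(d$count * d$depth ^ 2)
    S <- bi_to_num(S_bi)
    S2 <- bi_to_num(S2_bi)
  }
  if (small_sums && S ^ 2 < 2 ^ 53 && n * S2 < 2 ^ 53) {
    num <- n * S2 - S ^ 2
    den <- n ^ 2
    g <- gcd_num(num, den)
    V <- num / den
    V_num <- num / g
    V_den <- den / g
  } else {
    # exact big-integer path for very deep trees
    Sq <- new_rq(if (small_sums) bi_from_num(S) else S_bi, bi_one())
    S2q <- new_rq(if (small_sums) bi_from_num(S2) else S2_bi, bi_one())
    Vq <- (rq(n) * S2q - Sq ^ 2) / rq(n) ^ 2
    V <- as.numeric(Vq)
    V_num <- bi_to_num(Vq$num)
    V_den <- bi_to_num(Vq$den)
  }
  tibble(n = n, depth = delta, S = S, Shat = S / n, S2 = S2,
         V = V, V_num = V_num, V_den = V_den)
}

gcd_num <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  max(a, 1)
}

#' Total cophenetic index
#'
#' The total cophenetic index `Phi` of a rooted tree is the sum over all
#' unordered pairs of distinct leaves of the depth of their lowest common
#' ancestor.  Two routes are implemented: `"aggregate"` sums
#' `choose(kappa(v), 2)` over internal nodes `v` (where `kappa(v)` is the
#' number of descendant leaves) and subtracts `choose(n, 2)`, which is exact
#' and O(n); `"pairwise"` walks ancestor paths for every leaf pair, a direct
#' transcription of the definition used as a cross-check on small trees.
#'
#' @param x a `tree_shape`, `phylo`, or Newick string.
#' @param method `"aggregate"` (default) or `"pairwise"`.
#' @return `Phi` as a numeric (exact integer).
#' @examples
#' total_cophenetic(tree_star(8))   # 0: every LCA is the root
#' total_cophenetic(tree_comb(4))   # 4
#' @export
total_cophenetic <- function(x, method = c("aggregate", "pairwise")) {
  shape <- as_tree_shape(x)
  method <- match.arg(method)
  n <- shape$n
  if (n == 1L) return(0)
  if (method == "aggregate") {
    kappa <- subtree_leaf_counts(shape)
    internal <- !shape$is_leaf
    sum(choose(kappa[internal], 2)) - choose(n, 2)
  } else {
    sum(cophenetic_depths(shape)[upper.tri(diag(n))])
  }
}

#' @rdname total_cophenetic
#' @return `cophenetic_depths()` returns the `n x n` matrix of pairwise LCA
#'   depths (diagonal: the leaf's own depth).
#' @export
cophenetic_depths <- function(x) {
  shape <- as_tree_shape(x)
  leaves <- which(shape$is_leaf)
  n <- length(leaves)
  anc <- lapply(leaves, function(v) {
    path <- v
    while (shape$parent[v] > 0L) {
      v <- shape$parent[v]
      path <- c(path, v)
    }
    path
  })
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      lca <- intersect(anc[[i]], anc[[j]])[1]
      phi[i, j] <- shape$depth[lca]
    }
  }
  phi
}

#' Per-tree index table
#'
#' Computes all shape indices for a collection of trees and returns one tidy
#' row per tree: leaf count, depth, Sackin index `S`, mean depth `Shat`,
#' squared-depth sum `S2`, depth variance `V`, and total cophenetic index
#' `Phi`.
#'
#' @param trees a `phylo`, a list of `phylo`/`tree_shape`, a character vector
#'   of Newick strings, or a file path read with [read_newick()].
#' @param collapse_unary passed to the Newick reader when `trees` is a path
#'   or Newick text.
#' @return A tibble with columns `tree`, `n`, `depth`, `S`, `Shat`, `S2`,
#'   `V`, `Phi`.
#' @examples
#' tree_indices(c("((a,b),c);", "(a,b,c);"))
#' @export
tree_indices <- function(trees, collapse_unary = FALSE) {
  if (inherits(trees, "phylo") || inherits(trees, "tree_shape")) trees <- list(trees)
  if (is.character(trees)) {
    trees <- if (length(trees) == 1L && file.exists(trees)) {
      read_newick(trees, collapse_unary = collapse_unary)
    } else {
      lapply(trees, parse_newick, collapse_unary = collapse_unary)
    }
  }
  rows <- lapply(seq_along(trees), function(i) {
    shape <- as_tree_shape(trees[[i]])
    st <- depth_statistics(shape)
    tibble(tree = i, n = st$n, depth = st$depth, S = st$S, Shat = st$Shat,
           S2 = st$S2, V = st$V, Phi = total_cophenetic(shape))
  })
  dplyr::bind_rows(rows)
}
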