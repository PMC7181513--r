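#' Classic tree shapes
#'
#' Constructors for the named shapes used throughout the package:
#'
#' * `tree_comb(n)`: the comb (caterpillar) `K_n`, in which every internal
#'   node has a leaf child; the unique maximizer of the depth variance V.
#' * `tree_star(n)`: the rooted star `RS_n` of depth 1; `V = 0`.
#' * `tree_max_balanced(n)`: the unique maximally balanced bifurcating tree
#'   `B_n`, in which every internal node splits its descendant leaves
#'   `floor(k/2)` / `ceiling(k/2)`.
#' * `tree_fully_symmetric(n)`: the fully symmetric bifurcating tree (`n`
#'   must be a power of 2); equals `B_n` with all leaves at depth `log2(n)`.
#' * `tree_f_type(n)`: one representative of the minimal-Sackin class `F_n`
#'   (trees depth-equivalent to `B_n`): `B_{2^m}` with `k = n - 2^m` leaves
#'   replaced by cherries, so `2k` leaves at depth `m + 1` and `2^m - k` at
#'   depth `m`.
#'
#' @param n number of leaves (>= 1).
#' @return A `tree_shape`.
#' @examples
#' depth_multiset(tree_max_balanced(8))  # fully symmetric: all depths 3
#' depth_multiset(tree_f_type(6))        # 2 leaves at depth 2, 4 at depth 3
#' @export
tree_comb <- function(n) {
  n <- check_count(n)
  if (n == 1) return(tree_shape(0L))
  if (n == 2) return(tree_shape(c(0L, 1L, 1L)))
  # internal spine 1..n-1; node i has leaf child and next spine node
  parent <- integer(2L * n - 1L)
  spine <- seq_len(n - 1L)
  parent[spine] <- c(0L, spine[-(n - 1L)])
  leaves <- (n - 1L) + seq_len(n)
  parent[leaves[seq_len(n - 1L)]] <- spine
  parent[leaves[n]] <- n - 1L
  tree_shape(parent)
}

#' @rdname tree_comb
#' @export
tree_star <- function(n) {
  n <- check_count(n)
  if (n == 1) return(tree_shape(0L))
  tree_shape(c(0L, rep(1L, n)))
}

#' @rdname tree_comb
#' @export
tree_max_balanced <- function(n) {
  n <- check_count(n)
  parent <- integer(2 * n - 1)
  nxt <- 1L
  build <- function(k, par) {
    id <- nxt
    nxt <<- nxt + 1L
    parent[id] <<- par
    if (k > 1) {
      build(floor(k / 2), id)
      build(ceiling(k / 2), id)
    }
    id
  }
  build(n, 0L)
  tree_shape(parent)
}

#' @rdname tree_comb
#' @export
tree_fully_symmetric <- function(n) {
  n <- check_count(n)
  m <- log2(n)
  if (m != floor(m)) {
    stop_data("fully symmetric trees need a power of 2 for n, got n = %d", n)
  }
  tree_max_balanced(n)
}

#' @rdname tree_comb
#' @export
tree_f_type <- function(n) {
  n <- check_count(n)
  m <- floor(log2(n))
  k <- n - 2 ^ m
  tree_from_depths(dm_from_counts(c(m, m + 1), c(2 ^ m - k, 2 * k)))
}

#' @rdname tree_comb
#' @param kind one of `"comb"`, `"star"`, `"max_balanced"`,
#'   `"fully_symmetric"`, `"f_type"`.
#' @export
build_classic <- function(kind, n) {
  kind <- match.arg(kind, c("comb", "star", "max_balanced", "fully_symmetric", "f_type"))
  switch(kind,
    comb = tree_comb(n),
    star = tree_star(n),
    max_balanced = tree_max_balanced(n),
    fully_symmetric = tree_fully_symmetric(n),
    f_type = tree_f_type(n)
  )
}

#' Random tree shapes
#'
#' Generates a reproducible random tree shape by recursive splitting: the
#' leaf set is partitioned into 2 or more nonempty parts (always exactly 2 in
#' `"bifurcating"` mode; 2 to 4, so out-degree 3+ occurs with positive
#' probability, in `"multifurcating"` mode) and each part is split
#' recursively.  This is a property-test fixture generator, not a sampler of
#' either null model; use [sample_tree()] for the Yule and uniform models.
#'
#' @param n number of leaves.
#' @param mode `"bifurcating"` or `"multifurcating"`.
#' @param seed integer seed; the RNG state of the session is left untouched.
#' @return A `tree_shape`.
#' @examples
#' random_tree(10, "multifurcating", seed = 7)
#' @export
random_tree <- function(n, mode = c("bifurcating", "multifurcating"), seed = 1L) {
  n <- check_count(n)
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    parent <- integer(0)
    nxt <- 0L
    build <- function(k, par) {
      nxt <<- nxt + 1L
      id <- nxt
      parent[id] <<- par
      if (k > 1) {
        maxp <- if (mode == "bifurcating") 2L else min(k, 4L)
        p <- if (maxp == 2L) 2L else sample(2:maxp, 1L)
        cuts <- sort(sample.int(k - 1L, p - 1L))
        sizes <- diff(c(0L, cuts, k))
        for (s in sizes) build(s, id)
      }
      id
    }
    build(n, 0L)
    tree_shape(parent)
  })
}
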