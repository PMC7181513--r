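#' Tree probabilities under the Yule and uniform models
#'
#' `yule_probability()` computes the probability of a labeled bifurcating
#' phylogenetic tree under the Yule (Equal-Rate Markov) model,
#'
#'   `P_Y(T) = 2^(n-1) / n! * prod_v 1 / (kappa(v) - 1)`,
#'
#' the product running over internal nodes `v` with `kappa(v)` descendant
#' leaves.  `uniform_probability()` computes the probability of any labeled
#' bifurcating tree under the uniform (PDA) model, `1 / (2n-3)!!`, which
#' depends only on `n`.
#'
#' @param x a bifurcating `phylo`, `tree_shape`, or Newick string.
#' @param exact return an exact [rq()] rational.
#' @return A double or an `rq`.
#' @examples
#' yule_probability(parse_newick("(((a,b),c),d);"))  # 1/18
#' uniform_probability(4)                            # 1/15
#' @export
yule_probability <- function(x, exact = FALSE) {
  shape <- as_tree_shape(x)
  if (any(tabulate(shape$parent[shape$parent > 0L]) > 2L)) {
    stop_data("the Yule model is defined on bifurcating trees")
  }
  n <- shape$n
  kappa <- subtree_leaf_counts(shape)[!shape$is_leaf]
  if (exact) {
    den <- Reduce(function(acc, k) bi_mul_small(acc, k - 1), kappa, bi_fact(n))
    return(new_rq(bi_pow_small(2, n - 1), den))
  }
  exp((n - 1) * log(2) - lgamma(n + 1) - sum(log(pmax(kappa - 1, 1))))
}

#' @rdname yule_probability
#' @param n leaf count.
#' @export
uniform_probability <- function(n, exact = FALSE) {
  n <- check_count(n)
  if (exact) return(new_rq(bi_one(), bi_dfact_odd(n)))
  1 / n_labeled_trees(n)
}

# --- samplers -------------------------------------------------------------

# Yule growth: start from a single leaf; repeatedly replace a uniformly
# chosen leaf by a cherry.  Returns topologically ordered parent pointers.
yule_parent <- function(n) {
  if (n == 1) return(list(parent = 0L, leaves = 1L, root = 1L))
  parent <- integer(2L * n - 1L)
  leaves <- integer(n)
  leaves[1L] <- 1L
  nl <- 1L
  nxt <- 1L
  while (nl < n) {
    i <- sample.int(nl, 1L)
    v <- leaves[i]
    c1 <- nxt + 1L
    c2 <- nxt + 2L
    nxt <- nxt + 2L
    parent[c1] <- v
    parent[c2] <- v
    leaves[i] <- c1
    nl <- nl + 1L
    leaves[nl] <- c2
  }
  list(parent = parent[seq_len(nxt)], leaves = leaves[seq_len(n)], root = 1L)
}

# Uniform (PDA) growth: at step k the leaf labeled k+1 is attached either to
# a new root or onto one of the 2k-2 existing arcs, all 2k-1 slots
# equiprobable, which makes all (2n-3)!! labeled trees equiprobable.
uniform_parent <- function(n) {
  if (n == 1) return(list(parent = 0L, leaves = 1L, root = 1L))
  parent <- integer(2L * n - 1L)
  root <- 1L
  nn <- 1L
  leaves <- integer(n)
  leaves[1L] <- 1L
  for (k in seq_len(n - 1L)) {
    z <- nn + 1L  # the new leaf, labeled k+1
    w <- nn + 2L  # the new internal node
    r <- sample.int(2L * k - 1L, 1L)
    if (r == 2L * k - 1L) {
      parent[root] <- w
      parent[z] <- w
      root <- w
    } else {
      v <- r + (r >= root)  # r-th non-root node = arc from its parent
      parent[w] <- parent[v]
      parent[v] <- w
      parent[z] <- w
    }
    nn <- nn + 2L
    leaves[k + 1L] <- z
  }
  list(parent = parent[seq_len(nn)], leaves = leaves, root = root)
}

# depths for a parent-pointer forest rooted at `root` (pointers need not be
# topologically ordered)
parent_depths <- function(parent, root) {
  N <- length(parent)
  d <- rep(NA_integer_, N)
  d[root] <- 0L
  for (v in seq_len(N)) {
    if (!is.na(d[v])) next
    path <- v
    p <- parent[v]
    while (is.na(d[p])) {
      path <- c(path, p)
      p <- parent[p]
    }
    d[path] <- d[p] + rev(seq_along(path))
  }
  d
}

# build an ape phylo from parent pointers with given per-leaf labels
parent_to_phylo <- function(parent, leaves, root, labels) {
  N <- length(parent)
  n <- length(leaves)
  newid <- integer(N)
  newid[leaves] <- seq_len(n)
  internal <- c(root, setdiff(which(!(seq_len(N) %in% leaves)), root))
  newid[internal] <- n + seq_along(internal)
  has_par <- parent > 0L
  edge <- cbind(newid[parent[has_par]], newid[which(has_par)])
  phy <- list(edge = edge, tip.label = labels, Nnode = length(internal))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Sample phylogenetic trees from the Yule or uniform model
#'
#' `sample_tree()` draws one labeled bifurcating phylogenetic tree;
#' `sample_trees()` draws a list of them.  Under the Yule model the tree
#' grows by uniform leaf replacement and labels are then assigned by a
#' uniform random permutation; under the uniform model the leaf labeled
#' `k+1` is inserted into one of the `2k-1` equiprobable positions, so all
#' `(2n-3)!!` labeled trees are equiprobable.  Draws are reproducible for a
#' fixed `(n, model, seed)`; the session RNG state is untouched.
#'
#' @param n leaf count (>= 2 for a `phylo` result; `n = 1` returns the
#'   single-leaf `tree_shape`).
#' @param model `"yule"` or `"uniform"`.
#' @param seed integer seed.
#' @return `sample_tree()`: a `phylo` with tip labels `t1..tn`;
#'   `sample_trees()`: a list of `phylo`.
#' @examples
#' sample_tree(8, "yule", seed = 1)
#' @export
sample_tree <- function(n, model = c("yule", "uniform"), seed = 1L) {
  sample_trees(n, model, reps = 1L, seed = seed)[[1L]]
}

#' @rdname sample_tree
#' @param reps number of trees to draw.
#' @export
sample_trees <- function(n, model = c("yule", "uniform"), reps = 1L, seed = 1L) {
  n <- check_count(n)
  model <- match.arg(model)
  reps <- check_count(reps, "reps")
  if (n == 1) {
    return(withr::with_seed(seed, replicate(reps, tree_shape(0L), simplify = FALSE)))
  }
  withr::with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      rec <- if (model == "yule") yule_parent(n) else uniform_parent(n)
      labels <- if (model == "yule") {
        paste0("t", sample.int(n))
      } else {
        paste0("t", seq_len(n))
      }
      parent_to_phylo(rec$parent, rec$leaves, rec$root, labels)
    })
  })
}

#' Bulk index statistics of sampled trees
#'
#' Draws `reps` trees from the chosen model and returns the shape statistics
#' of each draw without materializing `phylo` objects, for sampler-vs-theory
#' checks.
#'
#' @inheritParams sample_trees
#' @return A tibble with `reps` rows and columns `S`, `S2`, `V`, `Phi`.
#' @examples
#' colMeans(sample_index_stats(5, "uniform", reps = 1000, seed = 1))
#' @export
sample_index_stats <- function(n, model = c("yule", "uniform"), reps = 1000L,
                               seed = 1L) {
  n <- check_count(n)
  model <- match.arg(model)
  reps <- check_count(reps, "reps")
  S <- numeric(reps); S2 <- numeric(reps); Phi <- numeric(reps)
  if (n == 1) {
    out <- tibble(S = S, S2 = S2, V = numeric(reps), Phi = Phi)
    return(out)
  }
  gen <- if (model == "yule") yule_parent else uniform_parent
  withr::with_seed(seed, {
    for (i in seq_len(reps)) {
      rec <- gen(n)
      d <- parent_depths(rec$parent, rec$root)
      ld <- d[rec$leaves]
      S[i] <- sum(ld)
      S2[i] <- sum(ld * ld)
      # Phi by kappa aggregation over internal nodes
      N <- length(rec$parent)
      kappa <- numeric(N)
      kappa[rec$leaves] <- 1
      for (v in order(d, decreasing = TRUE)) {
        p <- rec$parent[v]
        if (p > 0L) kappa[p] <- kappa[p] + kappa[v]
      }
      internal <- kappa >= 2
      Phi[i] <- sum(kappa[internal] * (kappa[internal] - 1) / 2) - n * (n - 1) / 2
    }
  })
  tibble(S = S, S2 = S2, V = S2 / n - (S / n) ^ 2, Phi = Phi)
}

#' Exact model expectations by exhaustive enumeration
#'
#' Computes `E[statistic]` under the Yule or uniform model by brute force:
#' every bifurcating shape with `n` leaves is enumerated, its statistic
#' evaluated, and the shape probabilities (labeled count times per-tree
#' probability) accumulated in exact rational arithmetic.  This is the
#' independent oracle against which the closed-form moments are verified.
#'
#' @param n leaf count (at most 12; the enumeration grows exponentially).
#' @param statistic one of `"V"`, `"S"`, `"S2"` (sum of squared depths),
#'   `"Ssq"` (the square of S), `"Phi"`, `"PhiSq"` (its square), `"SPhi"`
#'   (the product S * Phi).
#' @param model `"yule"` or `"uniform"`.
#' @param exact return an exact [rq()] rational instead of a double.
#' @return A double or an `rq`.
#' @examples
#' expected_by_enumeration(5, "V", "uniform")  # 0.9371...
#' @export
expected_by_enumeration <- function(n, statistic = c("V", "S", "S2", "Ssq", "Phi",
                                                     "PhiSq", "SPhi"),
                                    model = c("yule", "uniform"), exact = FALSE) {
  n <- check_count(n)
  statistic <- match.arg(statistic)
  model <- match.arg(model)
  if (n > 12) {
    stop_data("exhaustive expectation is limited to n <= 12 (got n = %d); use the closed forms instead",
              n)
  }
  tbl <- enumerate_shapes(n, materialize = TRUE)
  total <- as_rq(0)
  for (i in seq_len(nrow(tbl))) {
    shape <- tbl$shape[[i]]
    S <- tbl$S[i]
    S2 <- tbl$S2[i]
    needs_phi <- statistic %in% c("Phi", "PhiSq", "SPhi")
    Phi <- if (needs_phi) total_cophenetic(shape) else 0
    stat <- switch(statistic,
      V = rq(n * S2 - S ^ 2, n ^ 2),
      S = rq(S),
      S2 = rq(S2),
      Ssq = rq(S) ^ 2,
      Phi = rq(Phi),
      PhiSq = rq(Phi) ^ 2,
      SPhi = rq(S) * rq(Phi)
    )
    prob <- if (model == "yule") {
      kappa <- subtree_leaf_counts(shape)[!shape$is_leaf]
      rq(2 ^ (n - 1 - tbl$q[i]), prod(kappa - 1))
    } else {
      rq(factorial(n) / 2 ^ tbl$q[i]) * uniform_probability(n, exact = TRUE)
    }
    total <- total + stat * prob
  }
  if (exact) total else as.numeric(total)
}
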