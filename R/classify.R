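#' Candidate depth-equivalence types T_{n; l1..lj}
#'
#' A bifurcating tree with maximum leaf depth `delta` is of type
#' `T_{n; l1,...,lj}` (with `2 <= l1 < ... < lj <= delta - 2`) when it has a
#' single leaf of depth `delta - l_i` for each `i`, and all remaining leaves
#' at depths `delta` or `delta - 1`.  The empty sequence (`j = 0`) is the
#' minimal-Sackin class `F_n`, exactly the trees depth-equivalent to the
#' maximally balanced tree `B_n`.  These types are depth-equivalence classes:
#' the depth multiset of a type member depends only on `(n, l1..lj)`.
#'
#' `classify_type()` returns the type of a bifurcating tree, or `NULL` when
#' the tree is of no candidate type.
#'
#' @param x a bifurcating `tree_shape`, `phylo`, Newick string, or
#'   `depth_multiset`.
#' @return A list with elements `n` and `ls` (integer vector, possibly empty)
#'   of class `candidate_type`, or `NULL`.
#' @examples
#' classify_type(tree_max_balanced(6))             # F_6: empty l-sequence
#' classify_type(depth_multiset(rep(c(8, 7, 2), c(174, 9, 1))))  # (184; 6)
#' classify_type(tree_comb(8))                     # NULL
#' @export
classify_type <- function(x) {
  if (!inherits(x, "depth_multiset")) {
    shape <- as_tree_shape(x)
    if (any(tabulate(shape$parent[shape$parent > 0L]) > 2L)) {
      stop_data("classify_type expects a bifurcating tree")
    }
    d <- depth_multiset(shape)
  } else {
    d <- x
  }
  n <- sum(d$count)
  delta <- max(d$depth)
  low <- d$depth < delta - 1L
  if (any(d$count[low] != 1L)) return(NULL)
  ls <- sort(delta - d$depth[low])
  if (length(ls) > 0L && min(d$depth[low]) < 2L) return(NULL) # l_j <= delta - 2
  structure(list(n = n, ls = as.integer(ls)), class = "candidate_type")
}

#' @export
print.candidate_type <- function(x, ...) {
  ls <- if (length(x$ls) == 0L) "-" else paste(x$ls, collapse = ",")
  cat(sprintf("<candidate type T_{%d; %s}>\n", x$n, ls))
  invisible(x)
}

#' Four characterizations of the minimal-Sackin class F_n
#'
#' For a bifurcating tree the following are equivalent, and
#' `f_type_conditions()` evaluates each by an independent route:
#'
#' 1. `f_construction`: its depth multiset matches the F_n construction
#'    (`2k` leaves at depth `m + 1`, `2^m - k` at depth `m`, with
#'    `m = floor(log2 n)`, `k = n - 2^m`);
#' 2. `two_depths`: leaf depths take at most two values differing by 1;
#' 3. `near_mean`: every leaf depth is within 1 of the mean depth
#'    (strictly);
#' 4. `depth_equiv_balanced`: the depth multiset equals that of the
#'    maximally balanced tree `B_n`.
#'
#' @param x a bifurcating tree or `depth_multiset`.
#' @return A named logical vector of length 4.
#' @examples
#' f_type_conditions(tree_max_balanced(6))  # all TRUE
#' f_type_conditions(tree_comb(5))          # all FALSE
#' @export
f_type_conditions <- function(x) {
  d <- depth_multiset(x)
  n <- sum(d$count)
  m <- floor(log2(n))
  k <- n - 2 ^ m
  f_dm <- dm_from_counts(c(m, m + 1), c(2 ^ m - k, 2 * k))
  cond1 <- identical(d$depth, f_dm$depth) && identical(d$count, f_dm$count)
  cond2 <- max(d$depth) - min(d$depth) <= 1L
  mean_depth <- sum(d$depth * d$count) / n
  cond3 <- all(abs(d$depth - mean_depth) < 1)
  bd <- depth_multiset(tree_max_balanced(n))
  cond4 <- identical(d$depth, bd$depth) && identical(d$count, bd$count)
  c(f_construction = cond1, two_depths = cond2, near_mean = cond3,
    depth_equiv_balanced = cond4)
}

#' @rdname f_type_conditions
#' @export
is_f_type <- function(x) {
  unname(f_type_conditions(x)["two_depths"])
}
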