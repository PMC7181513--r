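# Exhaustive enumeration of bifurcating tree shapes (Wedderburn-Etherington
# enumeration).  Every shape with n leaves decomposes uniquely into an
# unordered pair {A, B} of root subtrees with |A| <= |B|, so generating pairs
# (with i <= j when |A| == |B|) yields each shape exactly once and no
# canonical-form deduplication is needed.  Per-shape records carry the leaf
# depth counts, S, S2, and the number q of symmetric internal nodes, from
# which the number of labeled trees with that shape is n!/2^q.

.ENUM_MAX <- 22L

enum_records <- function(n) {
  key <- as.character(n)
  cache <- .depthvar_env$enum
  if (is.null(cache)) {
    cache <- list()
  }
  if (!is.null(cache[[key]])) return(cache[[key]])
  if (n == 1) {
    rec <- list(S = 0, S2 = 0, q = 0L, dm = list(1L),
                ka = 0L, ia = 0L, ib = 0L)
  } else {
    S <- numeric(0); S2 <- numeric(0); q <- integer(0)
    ka <- integer(0); ia <- integer(0); ib <- integer(0)
    dm <- list()
    for (a in seq_len(n %/% 2)) {
      b <- n - a
      A <- enum_records(a)
      B <- enum_records(b)
      na <- length(A$S); nb <- length(B$S)
      if (a < b) {
        i_idx <- rep(seq_len(na), times = nb)
        j_idx <- rep(seq_len(nb), each = na)
      } else {
        pairs <- which(outer(seq_len(na), seq_len(nb), `<=`), arr.ind = TRUE)
        i_idx <- pairs[, 1]
        j_idx <- pairs[, 2]
      }
      # shifting a subtree down one level: S' = S + n_sub, S2' = S2 + 2S + n_sub
      S_new <- (A$S[i_idx] + a) + (B$S[j_idx] + b)
      S2_new <- (A$S2[i_idx] + 2 * A$S[i_idx] + a) + (B$S2[j_idx] + 2 * B$S[j_idx] + b)
      q_new <- A$q[i_idx] + B$q[j_idx] + if (a == b) as.integer(i_idx == j_idx) else 0L
      dm_new <- vector("list", length(i_idx))
      for (t in seq_along(i_idx)) {
        da <- A$dm[[i_idx[t]]]
        db <- B$dm[[j_idx[t]]]
        ld <- max(length(da), length(db)) + 1L
        v <- integer(ld)
        v[1L + seq_along(da)] <- da
        v[1L + seq_along(db)] <- v[1L + seq_along(db)] + db
        dm_new[[t]] <- v
      }
      S <- c(S, S_new); S2 <- c(S2, S2_new); q <- c(q, q_new)
      ka <- c(ka, rep(a, length(i_idx))); ia <- c(ia, i_idx); ib <- c(ib, j_idx)
      dm <- c(dm, dm_new)
    }
    rec <- list(S = S, S2 = S2, q = q, dm = dm, ka = ka, ia = ia, ib = ib)
  }
  cache[[key]] <- rec
  .depthvar_env$enum <- cache
  rec
}

# materialize the idx-th enumerated shape with n leaves as a tree_shape
enum_shape <- function(n, idx) {
  parent <- integer(2 * n - 1)
  nxt <- 0L
  build <- function(n, idx, par) {
    nxt <<- nxt + 1L
    id <- nxt
    parent[id] <<- par
    if (n > 1) {
      rec <- enum_records(n)
      a <- rec$ka[idx]
      build(a, rec$ia[idx], id)
      build(n - a, rec$ib[idx], id)
    }
    id
  }
  build(n, idx, 0L)
  tree_shape(parent)
}

#' Enumerate all bifurcating tree shapes with n leaves
#'
#' Generates every (unordered, unlabeled) bifurcating rooted tree shape with
#' `n` leaves exactly once, together with the number of labeled phylogenetic
#' trees having that shape, `n!/2^q` where `q` counts internal nodes whose
#' two child subtrees are isomorphic.  The labeled counts sum to
#' `(2n-3)!! = (2n-3)(2n-5)...3.1`, the number of bifurcating phylogenetic
#' trees on `n` leaves.  The number of distinct shapes is the n-th
#' Wedderburn-Etherington number (23 shapes at n = 8; 293,547 at n = 20).
#'
#' This enumeration is the package's independent verification oracle: exact
#' model expectations and exhaustive index minima are computed from it and
#' compared against closed formulas and the quasilinear minimum-V search.
#'
#' @param n leaf count (1 to 22; the shape count grows exponentially).
#' @param materialize also build each shape as a `tree_shape` object (list
#'   column `shape`) and its canonical key; default for `n <= 14`.
#' @return A tibble with one row per shape: `n_leaves`, `index`, `S`, `S2`,
#'   `V`, `q`, `labeled_trees`, list column `depths` (leaf counts by depth,
#'   starting at depth 0), and if materialized `shape` and `key`.
#'   `labeled_trees` is exact through `n = 16`, where `(2n-3)!!` still fits
#'   in a double's integer range.
#' @examples
#' enumerate_shapes(6)   # 6 shapes; labeled counts sum to 9!! = 945
#' @export
enumerate_shapes <- function(n, materialize = n <= 14) {
  n <- check_count(n)
  if (n > .ENUM_MAX) {
    stop_data("shape enumeration is limited to n <= %d (got n = %d)", .ENUM_MAX, n)
  }
  rec <- enum_records(n)
  k <- length(rec$S)
  out <- tibble(
    n_leaves = rep(n, k),
    index = seq_len(k),
    S = rec$S,
    S2 = rec$S2,
    V = rec$S2 / n - (rec$S / n) ^ 2,
    q = rec$q,
    labeled_trees = factorial(n) / 2 ^ rec$q,
    depths = rec$dm
  )
  if (materialize) {
    shapes <- lapply(seq_len(k), function(i) enum_shape(n, i))
    out$shape <- shapes
    out$key <- vapply(shapes, canonical_key, character(1))
  }
  out
}

#' Count of labeled bifurcating trees: the odd double factorial
#'
#' `(2n-3)!!` with the convention `(-1)!! = 1`, the number of bifurcating
#' phylogenetic trees on `n` labeled leaves.
#'
#' @param n leaf count.
#' @param exact return an exact [rq()] big integer instead of a double.
#' @return A double (exact up to `n = 16`) or an `rq`.
#' @examples
#' n_labeled_trees(4)  # 15
#' @export
n_labeled_trees <- function(n, exact = FALSE) {
  n <- check_count(n)
  if (exact) return(structure(list(num = bi_dfact_odd(n), den = bi_one()), class = "rq"))
  k <- 2 * n - 3
  if (k < 3) 1 else prod(seq(3, k, by = 2))
}
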