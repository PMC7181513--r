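#' Leaf depth multisets
#'
#' The multiset of leaf depths is the sufficient statistic for the Sackin
#' index, the mean depth, the sum of squared depths, and the variance of
#' depths: two trees with equal depth multisets ("depth-equivalent" trees)
#' share all of them.
#'
#' @param x a `tree_shape`, `phylo`, Newick string, or an integer vector of
#'   leaf depths (with repetitions).
#' @return A `depth_multiset`: a list with integer vectors `depth` and
#'   `count` (multiplicities, all >= 1), sorted by depth.
#' @examples
#' depth_multiset(tree_comb(8))
#' depth_multiset(c(2, 2, 3, 3, 3, 3))
#' @export
depth_multiset <- function(x) {
  UseMethod("depth_multiset")
}

#' @export
depth_multiset.depth_multiset <- function(x) x

#' @export
depth_multiset.tree_shape <- function(x) {
  new_depth_multiset(x$depth[x$is_leaf])
}

#' @export
depth_multiset.phylo <- function(x) depth_multiset(as_tree_shape(x))

#' @export
depth_multiset.character <- function(x) depth_multiset(as_tree_shape(x))

#' @export
depth_multiset.numeric <- function(x) new_depth_multiset(x)

new_depth_multiset <- function(depths) {
  if (length(depths) == 0L) stop_data("empty depth multiset")
  if (any(depths < 0) || any(depths != floor(depths))) {
    stop_data("depths must be non-negative integers")
  }
  tab <- table(depths)
  structure(
    list(depth = as.integer(names(tab)), count = as.integer(tab)),
    class = "depth_multiset"
  )
}

# construct from parallel (depth, count) vectors
dm_from_counts <- function(depth, count) {
  keep <- count > 0
  ord <- order(depth[keep])
  structure(
    list(depth = as.integer(depth[keep][ord]), count = as.integer(count[keep][ord])),
    class = "depth_multiset"
  )
}

#' @export
print.depth_multiset <- function(x, ...) {
  cat(sprintf("<depth_multiset: n = %d, depth = %d>\n", sum(x$count), max(x$depth)))
  cat(" ", paste(sprintf("%d:%d", x$depth, x$count), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.depth_multiset <- function(x, ...) {
  data.frame(depth = x$depth, count = x$count)
}

dm_expand <- function(d) rep(d$depth, d$count)

#' Kraft equality for bifurcating realizability
#'
#' A multiset of leaf depths is realizable by a bifurcating rooted tree
#' exactly when the Kraft sum over its leaves, `sum(2^(-depth))`, equals 1.
#' The check is done in exact integer arithmetic (bottom-up pairing), so it is
#' valid for arbitrarily deep trees.
#'
#' @param d a `depth_multiset` (or anything [depth_multiset()] accepts).
#' @return `TRUE` or `FALSE`.
#' @export
kraft_realizable <- function(d) {
  d <- depth_multiset(d)
  counts <- numeric(max(d$depth) + 1L)
  counts[d$depth + 1L] <- d$count
  # merge pairs of deepest nodes into one node a level up
  for (lev in rev(seq_along(counts))) {
    if (lev == 1L) break
    if (counts[lev] %% 2 != 0) return(FALSE)
    counts[lev - 1L] <- counts[lev - 1L] + counts[lev] / 2
  }
  counts[1L] == 1
}

# Kraft sum as a double (display/reporting only; inexact for very deep trees)
kraft_sum <- function(d) sum(d$count * 2 ^ (-d$depth))

#' Build a bifurcating tree with a prescribed depth multiset
#'
#' Materializes one bifurcating tree whose leaf depth multiset equals `d`, by
#' repeatedly merging two deepest available nodes into a parent one level up
#' (Huffman-style).  When more than two nodes share the maximum depth, the
#' choice of pair does not affect the resulting depth multiset.  The
#' representative returned is one of possibly many depth-equivalent trees.
#'
#' @param d a `depth_multiset` (or depths vector) satisfying the Kraft
#'   equality `sum(2^(-depth)) == 1`.
#' @return A `tree_shape` with `depth_multiset(result)` equal to `d`.
#' @examples
#' tree_from_depths(c(1, 2, 2))        # the 3-leaf comb
#' tree_from_depths(c(2, 2, 3, 3, 3, 3))
#' @export
tree_from_depths <- function(d) {
  d <- depth_multiset(d)
  if (!kraft_realizable(d)) {
    stop_data("depth multiset is not realizable by a bifurcating tree (Kraft sum %s != 1)",
              format(kraft_sum(d)))
  }
  n <- sum(d$count)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_depth <- integer(n_nodes)
  # create leaves
  leaf_depths <- dm_expand(d)
  node_depth[seq_len(n)] <- leaf_depths
  nxt <- n
  # pending node ids per depth level
  pending <- split(seq_len(n), factor(leaf_depths, levels = 0:max(d$depth)))
  for (lev in rev(seq_along(pending))) {
    if (lev == 1L) break
    ids <- pending[[lev]]
    k <- length(ids)
    if (k %% 2L != 0L) stop_data("internal error: unpaired node during Huffman build")
    if (k > 0L) {
      new_ids <- nxt + seq_len(k / 2L)
      nxt <- nxt + k / 2L
      parent[ids] <- rep(new_ids, each = 2L)
      node_depth[new_ids] <- lev - 2L
      pending[[lev - 1L]] <- c(pending[[lev - 1L]], new_ids)
    }
  }
  parent[nxt] <- 0L
  tree_shape(parent[seq_len(nxt)])
}
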