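#' Unlabeled rooted tree shapes
#'
#' A `tree_shape` is the label-free object underlying a phylogenetic tree:
#' a rooted tree with no out-degree-1 nodes, compared up to isomorphism of
#' unordered rooted trees.  All depth-based indices in this package (`V`, `S`,
#' `S2`) depend on a tree only through its shape, and in fact only through its
#' leaf depth multiset.
#'
#' @param parent integer vector; `parent[i]` is the parent node of node `i`,
#'   with `0` for the root.  Any node numbering is accepted.
#' @return `tree_shape()` returns a `tree_shape` object.
#' @examples
#' tree_shape(c(0, 1, 1, 2, 2))   # the 3-leaf comb
#' @export
tree_shape <- function(parent) {
  parent <- as.integer(parent)
  N <- length(parent)
  if (N < 1L) stop_data("a tree needs at least one node")
  root <- which(parent == 0L)
  if (length(root) != 1L) stop_data("tree must have exactly one root (parent 0)")
  if (any(parent < 0L | parent > N)) stop_data("parent indices out of range")
  nchild <- tabulate(parent[parent > 0L], nbins = N)
  if (any(nchild == 1L)) {
    stop_data("node %d has out-degree 1; rooted trees here exclude unary nodes",
              which(nchild == 1L)[1])
  }
  depth <- rep(NA_real_, N)
  depth[root] <- 0
  while (anyNA(depth)) {
    todo <- is.na(depth)
    newd <- depth[parent[todo]] + 1
    if (all(is.na(newd))) stop_data("parent vector contains a cycle or unreachable nodes")
    depth[todo] <- newd
  }
  is_leaf <- nchild == 0L
  structure(
    list(parent = parent, root = root, depth = as.integer(depth),
         is_leaf = is_leaf, n = sum(is_leaf)),
    class = "tree_shape"
  )
}

#' @export
print.tree_shape <- function(x, ...) {
  cat(sprintf("<tree_shape: %d leaves, depth %d>\n", x$n, max(x$depth[x$is_leaf])))
  if (x$n <= 16) cat(" ", canonical_key(x), "\n")
  invisible(x)
}

#' Number of leaves of a tree
#'
#' @param x a `tree_shape`, `phylo`, or `depth_multiset`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(x) {
  if (inherits(x, "tree_shape")) return(x$n)
  if (inherits(x, "phylo")) return(length(x$tip.label))
  if (inherits(x, "depth_multiset")) return(sum(x$count))
  stop_data("cannot count leaves of a %s", class(x)[1])
}

children_list <- function(shape) {
  N <- length(shape$parent)
  kids <- split(seq_len(N), factor(shape$parent, levels = 0:N))
  kids[-1L]
}

# per-node number of descendant leaves
subtree_leaf_counts <- function(shape) {
  N <- length(shape$parent)
  kappa <- as.numeric(shape$is_leaf)
  ord <- order(shape$depth, decreasing = TRUE)
  for (v in ord) {
    p <- shape$parent[v]
    if (p > 0L) kappa[p] <- kappa[p] + kappa[v]
  }
  kappa
}

#' Canonical form of a tree shape
#'
#' Computes a canonical string key for a shape by recursively sorting
#' children's keys, so two shapes are isomorphic as unordered rooted trees
#' exactly when their keys are equal.
#'
#' @param x a `tree_shape` (or anything [as_tree_shape()] accepts).
#' @return A character scalar; leaves print as `*`.
#' @examples
#' canonical_key(as_tree_shape("((a,b),c);"))
#' @export
canonical_key <- function(x) {
  shape <- as_tree_shape(x)
  N <- length(shape$parent)
  kids <- children_list(shape)
  key <- character(N)
  ord <- order(shape$depth, decreasing = TRUE)
  for (v in ord) {
    if (shape$is_leaf[v]) {
      key[v] <- "*"
    } else {
      key[v] <- paste0("(", paste(sort(key[kids[[v]]]), collapse = ","), ")")
    }
  }
  key[shape$root]
}

# rebuild a tree_shape from a canonical key string
shape_from_key <- function(key) {
  parent <- integer(0)
  cur <- 0L
  n_node <- 0L
  for (ch in strsplit(key, "", fixed = TRUE)[[1]]) {
    if (ch == "(") {
      n_node <- n_node + 1L
      parent[n_node] <- cur
      cur <- n_node
    } else if (ch == "*") {
      n_node <- n_node + 1L
      parent[n_node] <- cur
    } else if (ch == ")") {
      cur <- parent[cur]
    }
  }
  tree_shape(parent)
}

#' Test whether two trees have the same shape
#'
#' @param a,b trees in any representation accepted by [as_tree_shape()].
#' @return `TRUE` if the underlying unordered rooted trees are isomorphic.
#' @export
shapes_equal <- function(a, b) {
  a <- as_tree_shape(a)
  b <- as_tree_shape(b)
  if (a$n != b$n) return(FALSE)
  identical(canonical_key(a), canonical_key(b))
}

#' Forget labels: the shape of a phylogenetic tree
#'
#' The forgetful map from a leaf-labeled tree to its unlabeled shape.  Trees
#' differing only in their leaf labels map to equal (isomorphic) shapes.
#'
#' @param x a `phylo` object, a Newick string, or a `tree_shape`.
#' @return A `tree_shape`.
#' @examples
#' as_tree_shape(ape::read.tree(text = "((a,b),(c,d));"))
#' @export
as_tree_shape <- function(x) {
  UseMethod("as_tree_shape")
}

#' @export
as_tree_shape.tree_shape <- function(x) x

#' @export
as_tree_shape.phylo <- function(x) {
  n <- length(x$tip.label)
  N <- n + x$Nnode
  parent <- integer(N)
  parent[x$edge[, 2]] <- x$edge[, 1]
  tree_shape(parent)
}

#' @export
as_tree_shape.character <- function(x) {
  as_tree_shape(parse_newick(x))
}

#' @export
as_tree_shape.default <- function(x) {
  stop_data("cannot interpret a %s as a tree shape", class(x)[1])
}

#' @rdname as_tree_shape
#' @export
shape_of <- function(x) as_tree_shape(x)

# convert a tree_shape to an ape phylo with given (or fresh) tip labels
shape_to_phylo <- function(shape, tip_labels = NULL) {
  N <- length(shape$parent)
  n <- shape$n
  if (n == 1L) {
    # ape cannot represent a single-node tree; use a root edge artifact-free form
    stop_data("a single-leaf tree cannot be converted to phylo")
  }
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  if (length(tip_labels) != n) stop_data("need exactly %d tip labels", n)
  newid <- integer(N)
  newid[shape$is_leaf] <- seq_len(n)
  internal <- which(!shape$is_leaf)
  # root must get number n+1 in ape's convention
  internal <- c(shape$root, setdiff(internal, shape$root))
  newid[internal] <- n + seq_along(internal)
  has_par <- shape$parent > 0L
  edge <- cbind(newid[shape$parent[has_par]], newid[which(has_par)])
  phy <- list(edge = edge, tip.label = tip_labels, Nnode = length(internal))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}
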