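#' Read rooted trees from Newick text
#'
#' Parses standard Newick (parentheses, commas, optional `:length`, optional
#' internal labels, terminating semicolon).  Branch lengths and internal
#' labels are accepted and discarded: the indices in this package depend only
#' on the tree topology.  Out-degree-1 (unary) nodes are rejected, because the
#' tree definition used throughout excludes them; set `collapse_unary = TRUE`
#' to contract them instead.  Unlabeled leaves receive fresh labels `t1`,
#' `t2`, ...; duplicated leaf labels are an error, since leaves must be
#' bijectively labeled.
#'
#' @param text a Newick string (one tree).
#' @param collapse_unary contract out-degree-1 nodes instead of rejecting.
#' @return `parse_newick()` returns a single `phylo`; `read_newick()` returns
#'   a list of `phylo` (one per tree; `#`-prefixed and empty lines skipped).
#' @examples
#' parse_newick("((a:1,b:2)x:3,c:4);")
#' @export
parse_newick <- function(text, collapse_unary = FALSE) {
  if (!is.character(text) || length(text) != 1L) {
    stop_data("`text` must be a single Newick string")
  }
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop_data("malformed Newick: %s", conditionMessage(e)),
    warning = function(w) stop_data("malformed Newick: %s", conditionMessage(w))
  )
  if (is.null(phy)) stop_data("malformed Newick: no tree found in input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  sanitize_phylo(phy, collapse_unary = collapse_unary)
}

#' @rdname parse_newick
#' @param path path to a file with one Newick tree per line.
#' @export
read_newick <- function(path, collapse_unary = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_data("no trees found in %s", path)
  lapply(lines, parse_newick, collapse_unary = collapse_unary)
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_data("malformed Newick: unmatched ')' at position %d", i)
    }
  }
  if (depth != 0L) stop_data("malformed Newick: %d unclosed '(' at end of string", depth)
  if (!grepl(";", text, fixed = TRUE)) stop_data("malformed Newick: missing ';' terminator")
  invisible(TRUE)
}

sanitize_phylo <- function(phy, collapse_unary = FALSE) {
  phy$edge.length <- NULL
  phy$node.label <- NULL
  # unary nodes
  n <- length(phy$tip.label)
  nchild <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  unary <- which(nchild == 1L)
  if (length(unary) > 0L) {
    if (!collapse_unary) {
      stop_data("Newick contains an out-degree-1 node (internal node %d); use collapse_unary = TRUE to contract it",
                unary[1])
    }
    phy <- ape::collapse.singles(phy)
    n <- length(phy$tip.label)
  }
  # labels: fill unlabeled, require uniqueness
  lab <- phy$tip.label
  blank <- !nzchar(lab) | is.na(lab)
  if (any(blank)) {
    fresh <- setdiff(paste0("t", seq_len(n + sum(blank))), lab[!blank])
    lab[blank] <- fresh[seq_len(sum(blank))]
    phy$tip.label <- lab
  }
  if (anyDuplicated(lab)) {
    stop_data("duplicate leaf label '%s': leaves must be bijectively labeled",
              lab[duplicated(lab)][1])
  }
  phy
}

#' Write trees as Newick
#'
#' Emits labels only (no branch lengths), one tree per line.  Re-parsing the
#' output gives back the same labeled trees.
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param path output file; if `NULL`, the Newick strings are returned.
#' @param header optional `#`-prefixed metadata line written before the trees.
#' @return The Newick strings, invisibly when written to a file.
#' @export
write_newick <- function(trees, path = NULL, header = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- vapply(trees, function(phy) {
    phy$edge.length <- NULL
    ape::write.tree(phy)
  }, character(1))
  if (is.null(path)) return(out)
  lines <- c(if (!is.null(header)) paste0("# ", header), out)
  writeLines(lines, path)
  invisible(out)
}
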