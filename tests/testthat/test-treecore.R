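test_that("Newick parsing discards lengths/labels and validates structure", {
  expect_true(shapes_equal(parse_newick("((a,b),c);"), tree_comb(3)))
  expect_true(shapes_equal(parse_newick("(a,b,c,d);"), tree_star(4)))
  expect_true(shapes_equal(parse_newick("((a:1,b:2)x:3,c:4);"),
                           parse_newick("((a,b),c);")))
  expect_identical(dm_vec(parse_newick("(a,b,c,d);")), rep(1L, 4))
  # malformed input
  expect_error(parse_newick("((a,b),(c,d);"), "unclosed")
  expect_error(parse_newick("(a,b))c;"), "position")
  expect_error(parse_newick("(a,b)"), "terminator")
  # bijective labeling
  expect_error(parse_newick("((a,b),a);"), "duplicate leaf label")
  # out-degree-1 nodes rejected unless collapsed
  expect_error(parse_newick("((a),b);"), "out-degree-1")
  collapsed <- parse_newick("((a),b);", collapse_unary = TRUE)
  expect_identical(sort(collapsed$tip.label), c("a", "b"))
  # unlabeled leaves get fresh labels
  phy <- parse_newick("((,),c);")
  expect_false(anyDuplicated(phy$tip.label) > 0)
  expect_identical(length(phy$tip.label), 3L)
})

test_that("write_newick round-trips labeled trees up to isomorphism", {
  for (txt in c("((a,b),c);", "(a,b,c);", "((a,b),(c,d));", "(((a,b),c),d);")) {
    phy <- parse_newick(txt)
    back <- parse_newick(write_newick(phy))
    expect_setequal(back$tip.label, phy$tip.label)
    expect_true(shapes_equal(back, phy))
  }
  expect_identical(dm_vec(parse_newick(write_newick(tree_from_depths(rep(2, 4)) |>
                                                      depthvar:::shape_to_phylo()))),
                   rep(2L, 4))
})

test_that("the forgetful map ignores labels and separates shapes", {
  a <- parse_newick("(((a,b),c),d);")
  b <- parse_newick("(((d,c),b),a);")
  expect_true(shapes_equal(shape_of(a), shape_of(b)))
  expect_true(shapes_equal(shape_of(a), tree_comb(4)))
  expect_false(shapes_equal(parse_newick("((a,b),(c,d));"), tree_comb(4)))
})

test_that("classic constructors realize their defining depth multisets", {
  expect_identical(dm_vec(tree_comb(8)), c(1:6, 7L, 7L))
  expect_identical(dm_vec(tree_max_balanced(6)), rep(c(2L, 3L), c(2, 4)))
  expect_identical(dm_vec(tree_max_balanced(8)), rep(3L, 8))  # fully symmetric
  expect_identical(dm_vec(tree_f_type(6)), rep(c(2L, 3L), c(2, 4)))
  expect_identical(dm_vec(tree_star(9)), rep(1L, 9))
  expect_identical(depth_statistics(tree_comb(3))$S, 5)  # (n-1)(n+2)/2 at n = 3
  expect_error(tree_fully_symmetric(6), "power")
  expect_error(tree_comb(0), "positive integer")
  # B_n's internal nodes are all balanced
  bn <- tree_max_balanced(11)
  kappa <- depthvar:::subtree_leaf_counts(bn)
  kids <- depthvar:::children_list(bn)
  for (v in which(!bn$is_leaf)) {
    ks <- sort(kappa[kids[[v]]])
    expect_identical(ks, c(floor(kappa[v] / 2), ceiling(kappa[v] / 2)))
  }
})

test_that("tree_from_depths realizes exactly the Kraft-feasible multisets", {
  expect_true(shapes_equal(tree_from_depths(c(1, 2, 2)), tree_comb(3)))
  d6 <- tree_from_depths(rep(c(2, 3), c(2, 4)))
  expect_identical(dm_vec(d6), rep(c(2L, 3L), c(2, 4)))
  expect_error(tree_from_depths(c(1, 1, 2)), "Kraft sum 1.25")
  expect_error(tree_from_depths(c(2, 2)), "Kraft")
  # round trip on every realizable multiset with n <= 9 leaves, and
  # agreement of the Kraft criterion with brute-force realizability
  for (n in 2:9) {
    feasible <- realizable_multisets(n)
    ids <- vapply(feasible, paste, "", collapse = ",")
    enum <- enumerate_shapes(n, materialize = FALSE)
    enum_ids <- unique(vapply(enum$depths, function(cnt) {
      paste(rep(seq_along(cnt) - 1L, cnt), collapse = ",")
    }, ""))
    expect_setequal(enum_ids, ids)
    for (d in feasible) {
      expect_true(kraft_realizable(d))
      expect_identical(dm_vec(tree_from_depths(d)), d)
    }
  }
})

test_that("shape enumeration matches Wedderburn-Etherington and (2n-3)!!", {
  we <- wedderburn_counts(16)
  for (n in c(2, 4, 6, 10, 13, 16)) {
    tbl <- enumerate_shapes(n, materialize = FALSE)
    expect_identical(nrow(tbl), as.integer(we[n]))
    expect_identical(sum(tbl$labeled_trees), dfact_odd_oracle(n))
  }
  tbl4 <- enumerate_shapes(4)
  expect_setequal(tbl4$labeled_trees, c(12, 3))
  expect_identical(sum(tbl4$labeled_trees), 15)
  # keys are unique: each shape appears exactly once
  tbl8 <- enumerate_shapes(8)
  expect_identical(anyDuplicated(tbl8$key), 0L)
  # per-shape S/S2 agree with a direct computation on the materialized tree
  for (i in seq_len(nrow(tbl8))) {
    d <- dm_vec(tbl8$shape[[i]])
    expect_identical(as.double(sum(d)), tbl8$S[i])
    expect_identical(as.double(sum(d^2)), tbl8$S2[i])
  }
})

test_that("random trees are seed-reproducible and respect their mode", {
  expect_true(shapes_equal(random_tree(5, "bifurcating", seed = 1),
                           random_tree(5, "bifurcating", seed = 1)))
  expect_identical(random_tree(1, "multifurcating", seed = 3)$n, 1L)
  # multifurcating mode produces out-degree >= 3 somewhere
  found <- FALSE
  for (s in 1:20) {
    sh <- random_tree(30, "multifurcating", seed = s)
    if (any(tabulate(sh$parent[sh$parent > 0]) >= 3)) { found <- TRUE; break }
  }
  expect_true(found)
  # bifurcating mode never does
  for (s in 1:5) {
    sh <- random_tree(30, "bifurcating", seed = s)
    counts <- tabulate(sh$parent[sh$parent > 0], nbins = length(sh$parent))
    expect_true(all(counts[!sh$is_leaf] == 2))
  }
})

test_that("classify_type recovers l-sequences from depth multisets", {
  fig2 <- depth_multiset(rep(c(8L, 7L, 2L), c(174, 9, 1)))
  ct <- classify_type(fig2)
  expect_identical(ct$n, 184L)
  expect_identical(ct$ls, 6L)
  expect_identical(classify_type(tree_max_balanced(6))$ls, integer(0))
  expect_null(classify_type(tree_comb(8)))       # depth-1 leaf
  expect_null(classify_type(depth_multiset(c(3, 3, 3, 2, 2, 1))))
  expect_error(classify_type(tree_star(4)), "bifurcating")
})

test_that("the four F_n characterizations coincide on every shape, n <= 12", {
  for (n in 2:12) {
    tbl <- enumerate_shapes(n, materialize = FALSE)
    for (i in seq_len(nrow(tbl))) {
      d <- depth_multiset(rep(seq_along(tbl$depths[[i]]) - 1L,
                              tbl$depths[[i]]))
      conds <- f_type_conditions(d)
      expect_true(all(conds) || !any(conds))
      # F_n <=> classify_type gives the empty sequence
      ct <- classify_type(d)
      expect_identical(all(conds), !is.null(ct) && length(ct$ls) == 0L)
    }
  }
})

test_that("B_n is the unique shape with all internal nodes balanced, n <= 12", {
  for (n in c(5, 7, 9, 12)) {
    tbl <- enumerate_shapes(n, materialize = TRUE)
    balanced <- vapply(tbl$shape, function(sh) {
      kappa <- depthvar:::subtree_leaf_counts(sh)
      kids <- depthvar:::children_list(sh)
      all(vapply(which(!sh$is_leaf), function(v) {
        ks <- kappa[kids[[v]]]
        abs(ks[1] - ks[2]) <= 1
      }, TRUE))
    }, TRUE)
    expect_identical(sum(balanced), 1L)
    expect_true(shapes_equal(tbl$shape[[which(balanced)]], tree_max_balanced(n)))
  }
})
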