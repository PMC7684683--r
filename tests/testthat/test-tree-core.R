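test_that("parsing assigns canonical numbers: tips first, internals preorder", {
  tr <- col_fixture()
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$tip.label, paste0("sample", 1:4))
  expect_equal(convert_node(tr, c("All", "GroupA", "GroupB")), c(5L, 6L, 7L))

  small <- parse_newick("(a,b);")
  expect_equal(small$tip.label, c("a", "b"))
  expect_equal(count_node(small), 3)
  expect_null(small$node.label)

  rf <- row_fixture()
  expect_equal(convert_node(rf, c("t3", "t2", "t1", "t5", "t4")), 1:5)
})

test_that("newick round trip preserves topology, labels and lengths", {
  withr::local_seed(160)
  for (s in 1:60) {
    tr <- random_tree(sample(2:15, 1), seed = 1000 + s)
    txt <- write_newick(tr)
    back <- parse_newick(txt)
    expect_identical(write_newick(back), txt)
    expect_identical(back$tip.label, tr$tip.label)
    expect_identical(back$edge, tr$edge)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-11)
  }
  # labeled internals survive too
  tr <- col_fixture()
  expect_identical(parse_newick(write_newick(tr))$node.label, tr$node.label)
})

test_that("malformed newick is rejected with a character offset", {
  expect_error(parse_newick("((a,b);"), "offset 1")
  expect_error(parse_newick("(a,b));"), "offset 6")
  expect_error(parse_newick("(a,b)"), "offset 6")
  expect_error(parse_newick("((dup,x),dup);"), "duplicate")
})

test_that("convert_node translates labels and numbers both ways", {
  tr <- col_fixture()
  expect_equal(convert_node(tr, c("GroupA", "GroupB")), c(6L, 7L))
  expect_equal(convert_node(tr, c(6, 7)), c("GroupA", "GroupB"))
  expect_equal(convert_node(row_fixture(), "t3"), 1L)
  expect_equal(convert_node(tr, character(0)), integer(0))
  # unlabeled internals map to NA labels; number->label->number is
  # identity for labeled nodes
  rf <- row_fixture()
  expect_true(is.na(convert_node(rf, 7)))
  expect_equal(convert_node(tr, convert_node(tr, 6)), 6L)
  expect_error(convert_node(tr, "nope"), "nope")
  expect_error(convert_node(tr, 99), "99")
})

test_that("find_descendant matches brute-force reachability", {
  expect_equal(find_descendant(col_fixture(), 6, only_leaf = TRUE), c(1L, 2L))
  expect_equal(find_descendant(row_fixture(), 8), c(3L, 4L, 5L, 9L))
  expect_equal(find_descendant(col_fixture(), 1, only_leaf = TRUE,
                               self_include = TRUE), 1L)
  expect_equal(find_descendant(col_fixture(), 1, only_leaf = TRUE),
               integer(0))
  withr::local_seed(260)
  for (s in 1:25) {
    tr <- random_tree(sample(2:10, 1), seed = 2000 + s)
    n_tip <- length(tr$tip.label)
    for (v in seq_len(max(tr$edge))) {
      expect_equal(find_descendant(tr, v), oracle_descendants(tr, v))
      expect_equal(find_descendant(tr, v, only_leaf = TRUE),
                   intersect(oracle_descendants(tr, v), seq_len(n_tip)))
    }
  }
})

test_that("children, ancestors and siblings follow the edge set", {
  tr <- col_fixture()
  expect_equal(find_child(tr, 5), c(6L, 7L))
  expect_equal(find_ancestor(tr, 1, 1), 6L)
  expect_equal(find_ancestor(tr, 1, 2), 5L)
  expect_equal(find_sibling(tr, 1), 2L)
  expect_equal(find_sibling(tr, 5), integer(0))
  expect_error(find_ancestor(tr, 1, 3), "root")
  for (s in 1:10) {
    rt <- random_tree(8, seed = 3000 + s)
    for (v in 1:15) {
      expect_equal(find_child(rt, v), oracle_children(rt, v))
      p <- oracle_parent(rt, v)
      if (!is.na(p)) {
        expect_equal(find_ancestor(rt, v), p)
        expect_equal(sort(find_sibling(rt, v)),
                     sort(setdiff(oracle_children(rt, p), v)))
      }
    }
  }
})

test_that("share_node is the deepest common ancestor", {
  expect_equal(share_node(col_fixture(), c("sample1", "sample2")), 6L)
  expect_equal(share_node(row_fixture(), c("t1", "t4")), 8L)
  expect_equal(share_node(col_fixture(), "GroupA"), 6L)
  expect_error(share_node(col_fixture(), integer(0)), "non-empty")
  withr::local_seed(460)
  for (s in 1:15) {
    rt <- random_tree(sample(3:10, 1), seed = 4000 + s)
    nn <- max(rt$edge)
    picks <- sample(nn, sample(2:4, 1))
    expect_equal(share_node(rt, picks), oracle_lca(rt, picks))
    # associativity over list extension
    expect_equal(share_node(rt, c(share_node(rt, picks[-1]), picks[1])),
                 share_node(rt, picks))
  }
})

test_that("union_leaf unions descendant-or-self tips", {
  expect_equal(union_leaf(row_fixture(), c(7, 4)), c(1L, 2L, 4L))
  expect_equal(union_leaf(col_fixture(), 5), 1:4)
  tr <- col_fixture()
  expect_equal(union_leaf(tr, 1:4), 1:4)
  withr::local_seed(560)
  for (s in 1:15) {
    rt <- random_tree(sample(2:10, 1), seed = 5000 + s)
    nn <- max(rt$edge)
    picks <- sample(nn, sample(min(4, nn), 1))
    expect_equal(union_leaf(rt, picks), oracle_leaf_union(rt, picks))
  }
})

test_that("join_node reaches a minimal fixed point preserving leaf unions", {
  rf <- row_fixture()
  expect_equal(join_node(rf, c(3, 4, 5)), 8L)
  expect_equal(join_node(rf, c(1, 3)), c(1L, 3L))
  expect_equal(join_node(col_fixture(), 1:4), 5L)
  withr::local_seed(660)
  for (s in 1:20) {
    rt <- random_tree(sample(3:10, 1), seed = 6000 + s)
    picks <- sample(max(rt$edge), sample(1:5, 1))
    joined <- join_node(rt, picks)
    expect_equal(union_leaf(rt, joined), oracle_leaf_union(rt, picks))
    # minimality: no complete sibling set remains in the result
    for (v in seq(length(rt$tip.label) + 1, max(rt$edge))) {
      ch <- oracle_children(rt, v)
      expect_false(all(ch %in% joined))
    }
  }
})

test_that("dist_node sums branch lengths along the path", {
  tr <- col_fixture()  # no lengths -> unit lengths
  expect_equal(dist_node(tr, 1, 2), 2)
  expect_equal(dist_node(tr, 1, 3), 4)
  expect_equal(dist_node(tr, 6, 6), 0)
  withr::local_seed(760)
  for (s in 1:10) {
    rt <- random_tree(sample(3:8, 1), seed = 7000 + s)
    pair <- sample(max(rt$edge), 2)
    expect_equal(dist_node(rt, pair[1], pair[2]),
                 oracle_dist(rt, pair[1], pair[2]))
    expect_equal(dist_node(rt, pair[1], pair[2]),
                 dist_node(rt, pair[2], pair[1]))
  }
})

test_that("mat_tree lists the tip-to-root paths padded with NA", {
  m <- mat_tree(col_fixture())
  expect_equal(unname(m),
               matrix(c(1L, 6L, 5L, 2L, 6L, 5L, 3L, 7L, 5L, 4L, 7L, 5L),
                      nrow = 4, byrow = TRUE))
  m2 <- mat_tree(parse_newick("(a,b);"))
  expect_equal(unname(m2), matrix(c(1L, 3L, 2L, 3L), nrow = 2, byrow = TRUE))
  withr::local_seed(860)
  for (s in 1:15) {
    rt <- random_tree(sample(2:12, 1), seed = 8000 + s)
    mm <- mat_tree(rt)
    expect_equal(nrow(mm), length(rt$tip.label))
    for (k in seq_len(nrow(mm))) {
      p <- mm[k, !is.na(mm[k, ])]
      expect_equal(unname(p), oracle_root_path(rt, k))
    }
  }
})

test_that("leaf tests, node counts and listings are consistent", {
  tr <- col_fixture()
  expect_equal(count_node(tr), 7)
  expect_equal(is_leaf(tr, c(1, 6)), c(TRUE, FALSE))
  expect_equal(show_node(tr), 1:7)
  expect_equal(show_node(tr, only_leaf = TRUE), 1:4)
  expect_equal(length(show_node(taxonomy_fixture_tree())), 12)
  pn <- print_node(tr, "internal")
  expect_equal(pn$nodeLab, c("All", "GroupA", "GroupB"))
  expect_equal(pn$nodeNum, 5:7)
  expect_false(any(pn$isLeaf))
  # 2n-1 node count holds exactly for strictly bifurcating trees
  withr::local_seed(960)
  for (s in 1:10) {
    rt <- random_tree(sample(2:10, 1), seed = 9000 + s)
    expect_equal(count_node(rt), 2 * length(rt$tip.label) - 1)
  }
})

test_that("add_label fills only unlabeled nodes in scope", {
  rf <- row_fixture()
  lab <- add_label(rf, "internal")
  expect_equal(lab$node.label, paste0("Node_", 6:9))
  expect_equal(lab$tip.label, rf$tip.label)
  cf <- col_fixture()
  expect_identical(add_label(cf, "internal"), cf)  # fully labeled
  withr::local_seed(1060)
  for (s in 1:15) {
    rt <- add_label(random_tree(sample(2:10, 1), seed = 10000 + s), "all")
    labs <- c(rt$tip.label, rt$node.label)
    expect_false(anyDuplicated(labs) > 0)
  }
})

test_that("track_node aliases survive pruning and identify original nodes", {
  tr <- track_node(col_fixture())
  expect_equal(tr$node.label[2], "alias_6")
  expect_equal(convert_node(tr, tr$node.label), 5:7)
  pruned <- keep_tips(tr, c("alias_1", "alias_2"))
  # the old GroupA node (6) is the root of the pruned tree
  expect_equal(convert_node(pruned, "alias_6"),
               length(pruned$tip.label) + 1L)
  withr::local_seed(1160)
  for (s in 1:15) {
    rt <- random_tree(sample(4:10, 1), seed = 11000 + s)
    n_tip <- length(rt$tip.label)
    keep <- sort(sample(n_tip, sample(2:(n_tip - 1), 1)))
    tracked <- keep_tips(track_node(rt), keep)
    # every retained original node is recoverable by alias label:
    # brute-force search over the pruned tree's labels
    all_labs <- c(tracked$tip.label, tracked$node.label)
    for (old_tip in keep) {
      found <- which(all_labs == paste0("alias_", old_tip))
      expect_length(found, 1)
      expect_equal(tracked$tip.label[found], paste0("alias_", old_tip))
    }
  }
})

test_that("keep_tips prunes, keeps labels and renumbers canonically", {
  pruned <- keep_tips(row_fixture(), c("t2", "t3"))
  expect_equal(sort(pruned$tip.label), c("t2", "t3"))
  expect_equal(count_node(pruned), 3)
  full <- keep_tips(col_fixture(), 1:4)
  expect_identical(full$edge, col_fixture()$edge)
  expect_error(keep_tips(col_fixture(), integer(0)), "at least one")
  expect_error(keep_tips(col_fixture(), "GroupA"), "not a tip")
  withr::local_seed(1260)
  for (s in 1:15) {
    rt <- random_tree(sample(4:12, 1), seed = 12000 + s)
    n_tip <- length(rt$tip.label)
    keep <- sample(n_tip, sample(2:n_tip, 1))
    pr <- keep_tips(rt, keep)
    expect_setequal(pr$tip.label, rt$tip.label[keep])
  }
})

test_that("as_leaf collapses internal nodes into labeled tips", {
  tt <- taxonomy_fixture_tree()
  cut <- as_leaf(tt, "Class:C3")
  expect_equal(length(cut$tip.label), 5)
  expect_setequal(cut$tip.label, c("D1", "D2", "D3", "D4", "Class:C3"))
  expect_identical(write_newick(as_leaf(tt, character(0))),
                   write_newick(tt))
  expect_error(as_leaf(tt, "D1"), "already leaves")
  expect_error(as_leaf(tt, c("Phylum:B2", "Class:C3")), "ancestors")
  expect_error(as_leaf(row_fixture(), 8), "label them first")
  # collapsing disjoint branches of sizes (a,b,c) in a 49-leaf binary
  # tree leaves 49-a-b-c+3 tips
  big <- add_label(random_tree(49, seed = 77), "internal")
  n_tip <- 49L
  internals <- (n_tip + 1L):(2L * n_tip - 1L)
  sizes <- vapply(internals, function(v)
    length(find_descendant(big, v, only_leaf = TRUE)), integer(1))
  cand <- internals[sizes >= 2 & sizes <= 8]
  picked <- integer(0)
  for (v in cand) {
    below <- c(v, find_descendant(big, v))
    above <- oracle_root_path(big, v)
    if (!any(picked %in% c(below, above)))
      picked <- c(picked, v)
    if (length(picked) == 3)
      break
  }
  expect_length(picked, 3)
  a_b_c <- sum(sizes[match(picked, internals)])
  cut_big <- as_leaf(big, picked)
  expect_equal(length(cut_big$tip.label), 49 - a_b_c + 3)
})
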