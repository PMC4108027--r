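test_that("collapsing contracts exactly the strictly-sub-threshold edges", {
  tr <- read_gene_tree("((a,b)40,(c,d)90);")
  ct <- collapse_low_support(tr, 50)
  rep <- collapse_report(ct)
  expect_equal(rep$n_collapsed, 1)
  expect_equal(rep$collapsed_supports, 40)
  expect_identical(canon_bips(ct), canon_bips(read_gene_tree("(a,b,(c,d)90);")))
  # support exactly at the threshold survives ("less than 50%" is strict)
  at50 <- collapse_low_support(read_gene_tree("((a,b)50,(c,d)49.9);"), 50)
  expect_equal(collapse_report(at50)$collapsed_supports, 49.9)
  expect_identical(canon_bips(at50), "a,b") # {a,b} survives, {c,d} is gone
})

test_that("a tree with all supports at or above threshold is unchanged", {
  tr <- read_gene_tree("((a,b)50,((c,d)99,e)72);")
  ct <- collapse_low_support(tr, 50)
  expect_equal(collapse_report(ct)$n_collapsed, 0)
  expect_identical(canon_bips(tr), canon_bips(ct))
  expect_identical(node_supports(tr), node_supports(ct))
})

test_that("k weak supports on a random binary tree remove exactly k internal edges", {
  set.seed(101)
  for (i in 1:20) {
    tr <- ape::rtree(20)
    m <- tr$Nnode - 1 # internal non-root nodes
    k <- sample(0:m, 1)
    sup <- rep(100, tr$Nnode)
    weak <- if (k > 0) sample(seq_len(m), k) + 1 else integer(0)
    sup[weak] <- sample(0:49, k, replace = TRUE)
    tr$node.label <- c("", as.character(sup[-1]))
    tr <- as_gene_tree(tr)
    before <- n_internal_edges(tr)
    ct <- collapse_low_support(tr, 50)
    expect_equal(before - n_internal_edges(ct), k)
    expect_equal(collapse_report(ct)$n_collapsed, k)
    expect_setequal(ct$tip.label, tr$tip.label)
    sup_after <- node_supports(ct)
    expect_true(all(is.na(sup_after) | sup_after >= 50))
  }
})

test_that("collapsing preserves leaf annotations and path lengths", {
  tm <- taxon_map(c("a", "b", "c", "d"), c("s1", "s2", "s3", "s4"))
  tr <- assign_taxa(read_gene_tree("((a:1,b:2)30:0.5,(c:1,d:1)90:1);"), tm)
  ct <- collapse_low_support(tr, 50)
  expect_equal(tip_species(ct)[sort(names(tip_species(ct)))],
               tip_species(tr)[sort(names(tip_species(tr)))])
  d1 <- ape::node.depth.edgelength(tr)[1:4]
  d2 <- ape::node.depth.edgelength(ct)[match(tr$tip.label, ct$tip.label)]
  expect_equal(d2, d1)
})

test_that("collapsing is idempotent and threshold-monotone", {
  set.seed(77)
  for (i in 1:30) {
    tr <- ape::rtree(12)
    tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1, TRUE)))
    tr <- as_gene_tree(tr)
    c50 <- collapse_low_support(tr, 50)
    expect_identical(canon_bips(c50),
                     canon_bips(collapse_low_support(c50, 50)))
    # collapsing at t2 >= t1 after t1 equals collapsing the original at t2
    c80 <- collapse_low_support(tr, 80)
    c50_80 <- collapse_low_support(c50, 80)
    expect_identical(canon_bips(c80), canon_bips(c50_80))
    expect_identical(node_supports(c80)[order(names(node_supports(c80)))],
                     node_supports(c50_80)[order(names(node_supports(c50_80)))])
  }
})

test_that("full collapse degenerates to a valid star tree", {
  tr <- read_gene_tree("((a,b)10,((c,d)20,e)5);")
  ct <- collapse_low_support(tr, 50)
  expect_equal(ct$Nnode, 1)
  expect_setequal(ct$tip.label, c("a", "b", "c", "d", "e"))
})

test_that("invalid collapse thresholds are rejected", {
  tr <- read_gene_tree("((a,b)60,c);")
  expect_error(collapse_low_support(tr, 0))
  expect_error(collapse_low_support(tr, 150))
})

test_that("a single outgroup leaf roots the tree as sister to the ingroup", {
  tr <- read_gene_tree("(alga,(m1,(s1,a1)));")
  rt <- root_by_outgroup(tr, "alga")
  expect_true(attr(rt, "rooting")$clean)
  nd <- copymin:::tree_nodes(rt)
  root_kids <- nd$children[[nd$root]]
  expect_true(match("alga", rt$tip.label) %in% root_kids)
  expect_identical(canon_bips(tr), canon_bips(rt))
})

test_that("an outgroup leaf inside a root polytomy roots cleanly, keeping the polytomy", {
  tr <- read_gene_tree("(alga,(p1,p2)90,(s1,a1)80,m1,a2);")
  rt <- root_by_outgroup(tr, "alga")
  expect_true(attr(rt, "rooting")$clean)
  nd <- copymin:::tree_nodes(rt)
  kids <- nd$children[[nd$root]]
  expect_equal(length(kids), 2)
  other <- kids[kids != match("alga", rt$tip.label)]
  expect_equal(length(nd$children[[other]]), 4) # polytomy retained below root
  expect_identical(canon_bips(tr), canon_bips(rt))
})

test_that("a non-monophyletic outgroup roots at its MRCA edge and is flagged", {
  tr <- read_gene_tree("(((o1,(o2,x)70)80,y)60,(a,b)90);")
  rt <- root_by_outgroup(tr, c("o1", "o2"))
  expect_false(attr(rt, "rooting")$clean)
  nd <- copymin:::tree_nodes(rt)
  kids <- nd$children[[nd$root]]
  sets <- copymin:::node_leafsets(rt)
  kid_sets <- lapply(kids, function(k) sort(rt$tip.label[sets[[k]]]))
  expect_true(list(c("o1", "o2", "x")) %in% kid_sets)
  expect_identical(canon_bips(tr), canon_bips(rt))
})

test_that("rooting keeps supports attached to their bipartitions", {
  set.seed(202)
  for (i in 1:25) {
    # unrooted (trifurcating-root) trees, as bootstrap gene trees are:
    # a rooted binary root would write one unrooted edge as two labelled ones
    tr <- ape::unroot(ape::rtree(10))
    tr$node.label <- c("", as.character(sample(30:100, tr$Nnode - 1, TRUE)))
    tr <- as_gene_tree(tr)
    rt <- root_by_outgroup(tr, sample(tr$tip.label, 1))
    expect_identical(canon_bips(tr), canon_bips(rt))
    # map support -> bipartition in both trees and compare on shared bips
    bip_sup <- function(t) {
      n <- ape::Ntip(t)
      sets <- copymin:::node_leafsets(t)
      sup <- node_supports(t)
      labs <- t$tip.label
      out <- list()
      for (v in (n + 1):(n + t$Nnode)) {
        s <- sort(labs[sets[[v]]])
        o <- sort(setdiff(labs, s))
        if (length(s) <= 1 || length(o) <= 1) next
        key <- if (paste(s, collapse = ",") < paste(o, collapse = ","))
          paste(s, collapse = ",") else paste(o, collapse = ",")
        if (!is.na(sup[as.character(v)])) out[[key]] <- unname(sup[as.character(v)])
      }
      out
    }
    b1 <- bip_sup(tr); b2 <- bip_sup(rt)
    shared <- intersect(names(b1), names(b2))
    expect_equal(b1[shared], b2[shared])
  }
})

test_that("rooting errors are informative", {
  tr <- read_gene_tree("((a,b),(c,d));")
  expect_error(root_by_outgroup(tr, "zz"), "zz")
  expect_error(root_by_outgroup(tr, character(0)), "non-empty")
  expect_error(root_by_outgroup(tr, c("a", "b", "c", "d")), "entire leaf set")
})

test_that("mrca_node matches exhaustive search", {
  tr <- read_gene_tree("((a,b),(c,d));")
  expect_equal(mrca_node(tr, "a"), match("a", tr$tip.label))
  n <- length(tr$tip.label)
  expect_equal(mrca_node(tr, c("a", "b", "c", "d")), n + 1)
  # {a,c} only share the root
  expect_equal(mrca_node(tr, c("a", "c")), n + 1)
  # exhaustive check: MRCA is the smallest-leafset node containing the query
  set.seed(5)
  rtr <- as_gene_tree(ape::rtree(8))
  sets <- copymin:::node_leafsets(rtr)
  for (i in 1:10) {
    q <- sample(rtr$tip.label, sample(2:4, 1))
    qi <- match(q, rtr$tip.label)
    containing <- which(vapply(sets, function(s) all(qi %in% s), logical(1)))
    want <- containing[which.min(lengths(sets[containing]))]
    expect_equal(mrca_node(rtr, q), want)
  }
  expect_error(mrca_node(tr, c("a", "nope")), "nope")
})
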