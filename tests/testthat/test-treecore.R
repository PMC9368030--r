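test_that("newick parsing reads support triples and rejects malformed input", {
  tr <- parse_newick("((A:1,B:1)80/0.99/97:0.5,C:2);")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  s <- support_triples(tr)
  i <- which(!is.na(s$sh_alrt))
  expect_equal(unlist(s[i, ]), c(sh_alrt = 80, abayes = 0.99, ufboot = 97))

  tr2 <- parse_newick("(A,B);")
  expect_true(all(is.na(support_triples(tr2))))
  expect_null(tr2$edge.length)

  expect_error(parse_newick("((A,B;"), "parse error")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")

  # missing components are encoded as empty fields
  s3 <- support_triples("80//95")
  expect_equal(s3$sh_alrt, 80)
  expect_true(is.na(s3$abayes))
  expect_equal(s3$ufboot, 95)
})

test_that("serialize/parse round-trips topology, labels and lengths", {
  withr::with_seed(2, {
    for (i in 1:5) {
      tr <- ape::rtree(10)
      tr$node.label <- sprintf("%d/0.9%d/9%d", 70 + 1:tr$Nnode, 1:tr$Nnode %% 10,
                               1:tr$Nnode %% 10)
      txt <- serialize_newick(tr)
      expect_identical(serialize_newick(parse_newick(txt)), txt)
    }
  })
})

test_that("rerooting at a leaf splits the pendant edge and preserves paths", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  r <- reroot_at_leaf(tr, "A")
  kids <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1L, 2]
  expect_length(kids, 2L)
  expect_true(match("A", r$tip.label) %in% kids)

  expect_error(reroot_at_leaf(tr, "Z"), "unknown leaf")

  withr::with_seed(8, tr20 <- ape::rtree(20))
  before <- ape::cophenetic.phylo(tr20)
  after <- ape::cophenetic.phylo(reroot_at_leaf(tr20, "t5"))
  ord <- rownames(before)
  expect_equal(after[ord, ord], before, tolerance = 1e-9)
})

test_that("rerooting above a node keeps the leaf set and path lengths", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1,E:1);")
  nd <- mrca_leaves(tr, c("A", "B"))
  r <- reroot_at_node(tr, nd)
  expect_setequal(r$tip.label, tr$tip.label)
  kids <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1L, 2]
  expect_length(kids, 2L)
  # one root child subtends exactly {A,B}
  sides <- lapply(kids, function(k) tips_under(r, k))
  expect_true(any(vapply(sides, function(s) setequal(s, c("A", "B")),
                         logical(1))))
  before <- ape::cophenetic.phylo(tr)
  after <- ape::cophenetic.phylo(r)
  ord <- rownames(before)
  expect_equal(after[ord, ord], before, tolerance = 1e-9)

  expect_warning(r2 <- reroot_at_node(tr, ape::Ntip(tr) + 1L), "already the root")
  expect_identical(r2, tr)
})

test_that("marked-descendant counts sum up the tree", {
  tr <- parse_newick("((A,B),(C,D));")
  cnt <- count_marked_descendants(tr, c("A", "D"))
  expect_identical(cnt[ape::Ntip(tr) + 1L], 2L)             # root
  expect_identical(cnt[mrca_leaves(tr, c("A", "B"))], 1L)
  expect_identical(cnt[mrca_leaves(tr, c("C", "D"))], 1L)

  expect_true(all(count_marked_descendants(tr, character()) == 0L))
  expect_error(count_marked_descendants(tr, "Z"), "absent")

  # marked = all leaves: every node's count equals its subtree size
  # (oracle: ape::extract.clade)
  withr::with_seed(3, tr2 <- ape::rtree(12))
  cnt2 <- count_marked_descendants(tr2, tr2$tip.label)
  for (node in (ape::Ntip(tr2) + 1L):(ape::Ntip(tr2) + tr2$Nnode)) {
    expect_identical(cnt2[node],
                     length(ape::extract.clade(tr2, node)$tip.label))
  }
})

test_that("MRCA handles singletons, pairs and spanning sets", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_identical(mrca_leaves(tr, c("A", "B")), ape::getMRCA(tr, c("A", "B")))
  expect_identical(mrca_leaves(tr, c("A", "C")), ape::Ntip(tr) + 1L)
  expect_identical(mrca_leaves(tr, "A"), match("A", tr$tip.label))
  expect_error(mrca_leaves(tr, character()), "empty")
})

test_that("clade roots are the maximal single-definer subtrees", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_identical(clade_root(tr, "A", c("A", "C")),
                   mrca_leaves(tr, c("A", "B")))
  # a sibling definer forces the clade down to the leaf itself
  expect_identical(clade_root(tr, "A", c("A", "B")), match("A", tr$tip.label))
  expect_error(clade_root(tr, "Z", c("Z", "A")), "absent")

  # property: clades of distinct definers are pairwise disjoint, and each
  # root is confirmed by an exhaustive ancestor scan
  withr::with_seed(9, {
    for (rep in 1:10) {
      tr2 <- ape::rtree(15)
      defs <- sample(tr2$tip.label, 4)
      roots <- vapply(defs, function(d) clade_root(tr2, d, defs), integer(1))
      sets <- lapply(roots, function(nd) tips_under(tr2, nd))
      for (i in 1:3) for (j in (i + 1):4) {
        expect_length(intersect(sets[[i]], sets[[j]]), 0L)
      }
      cnt <- count_marked_descendants(tr2, defs)
      for (d in defs) {
        # exhaustive scan: highest ancestor of d with definer count 1
        anc <- match(d, tr2$tip.label)
        p <- tr2$edge[, 1][match(anc, tr2$edge[, 2])]
        while (!is.na(p) && cnt[p] == 1L) {
          anc <- p
          p <- tr2$edge[, 1][match(anc, tr2$edge[, 2])]
        }
        expect_identical(clade_root(tr2, d, defs), anc)
      }
    }
  })
})

test_that("clade assignment partitions leaves and flags conflicts", {
  tr <- parse_newick("((A,B),(C,D));")
  defs <- data.frame(name = c("one", "two"), color = c("red", "blue"),
                     sequence_id = c("A", "C"))
  asn <- assign_clades(tr, defs)
  expect_setequal(asn$clades$one$members, c("A", "B"))
  expect_setequal(asn$clades$two$members, c("C", "D"))
  expect_length(asn$outgroup, 0L)

  defs2 <- defs; defs2$sequence_id[1] <- "missing_leaf"
  expect_error(assign_clades(tr, defs2), "absent")
  # ...unless a substitute from a prior assignment steps in
  asn2 <- assign_clades(tr, defs2, substitutes = list(one = c("nope", "B")))
  expect_setequal(asn2$clades$one$members, c("A", "B"))
  expect_identical(asn2$clades$one$defining_leaf, "B")

  # synthetic truth: all clades recovered exactly on the true tree
  b <- simulate_family(small_sim_config(seed = 4))
  keep <- b$truth$id[b$truth$role %in% c("member", "fragment")]
  tru <- ape::keep.tip(b$tree, keep)
  cdefs <- b$clade_defs[b$clade_defs$name != "outgroup", ]
  asn3 <- assign_clades(reroot_at_node(tru, mrca_leaves(
    tru, b$truth$id[b$truth$clade %in% "gluopsin"])), cdefs)
  for (cl in asn3$clades) {
    expect_setequal(cl$members, b$truth$id[b$truth$clade %in% cl$name])
  }
})

test_that("bait-spanned clade extraction roots at the anchor", {
  tr <- parse_newick("(O:1,(b1:1,(x:1,b2:1):1):1);")
  expect_setequal(extract_bait_clade(tr, "O", c("b1", "b2")),
                  c("b1", "x", "b2"))

  expect_error(extract_bait_clade(tr, "O", c("b1", "zz")), "fewer than two")
  expect_error(extract_bait_clade(tr, "b1", c("b1", "b2")), "anchor")

  # baits on both sides of the anchor split the whole tree: classed error
  # with a per-bait influence report
  tr2 <- parse_newick("((b1:1,x:1):1,(O:1,(y:1,(b2:1,b3:1):1):1):1);")
  err <- tryCatch(extract_bait_clade(tr2, "O", c("b1", "b2", "b3")),
                  opsinpipe_baits_span_tree = function(e) e)
  expect_s3_class(err, "opsinpipe_baits_span_tree")
  expect_true("b1" %in% names(err$influence))
  expect_identical(unname(err$influence[["b1"]]), 2L)   # {b2,b3} without b1

  # generator truth: baits inside the ingroup retain exactly the ingroup
  b <- simulate_family(small_sim_config(seed = 6))
  m <- aln_matrix(b$records)
  ing <- b$truth$id[b$truth$role %in% c("member", "fragment")]
  dec <- b$truth$id[b$truth$role == "decoy"]
  baits <- ing[c(1, 20, 40, 60)]
  tr3 <- nj_tree(pdistance_matrix(m[c(ing, dec[1:8]), ]))
  got <- extract_bait_clade(tr3, dec[1], baits)
  expect_true(all(baits %in% got))
  expect_length(intersect(got, dec), 0L)
  expect_true(length(intersect(got, ing)) >= 0.95 * length(ing))
})

test_that("the three-support policy rejects, accepts, or abstains", {
  pol <- support_policy()
  expect_identical(branch_status(c(80, 0.95, 95), pol), "accepted")
  expect_identical(branch_status(c(0.05, 0.99, 99), pol), "rejected")
  expect_identical(branch_status(c(85, 0.90, 99), pol), "ambiguous")
  expect_identical(branch_status(c(NA, 0.99, 99), pol), "ambiguous")

  # monotonicity: raising any component never demotes a branch
  rank <- c(rejected = 1L, ambiguous = 2L, accepted = 3L)
  withr::with_seed(14, {
    for (i in 1:200) {
      s <- c(runif(1, 0, 100), runif(1), runif(1, 0, 100))
      up <- s + c(runif(1, 0, 100 - s[1]), runif(1, 0, 1 - s[2]),
                  runif(1, 0, 100 - s[3]))
      expect_gte(rank[branch_status(up, pol)], rank[branch_status(s, pol)])
    }
  })

  expect_error(support_policy(reject_sh_below = 90), "reject_sh_below")
})
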