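test_that("p-distances count mismatches over comparable sites", {
  d <- pdistance_matrix(c(a = "AAAA", b = "AATT"))
  expect_equal(d["a", "b"], 0.5)
  d2 <- pdistance_matrix(c(a = "AA--", b = "AAAA"))
  expect_equal(d2["a", "b"], 0)
  expect_error(pdistance_matrix(c(a = "AA--", b = "--AA")),
               "no comparable.*\\b(a and b|b and a)\\b")

  withr::with_seed(21, {
    seqs <- vapply(1:6, function(i)
      paste(sample(c(AAS, "-"), 80, replace = TRUE,
                   prob = c(rep(0.045, 20), 0.1)), collapse = ""),
      character(1))
  })
  names(seqs) <- paste0("s", 1:6)
  d3 <- pdistance_matrix(seqs)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d3[i, j], bf_pdist_pair(seqs[i], seqs[j]))
  }
  expect_true(isSymmetric(unname(d3)))
  expect_true(all(diag(d3) == 0))
})

test_that("neighbor joining is exact on additive matrices", {
  # the four-point example: distances generated by ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(ref)), 0)
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_equal(sum(tr$edge.length[internal]), 1)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d)

  # 3 taxa: closed-form pendant lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  pend <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "square|three")

  # topology recovery on random additive matrices
  withr::with_seed(33, {
    for (i in 1:20) {
      tr0 <- ape::rtree(8)
      dm <- ape::cophenetic.phylo(tr0)
      expect_equal(phangorn::RF.dist(ape::unroot(nj_tree(dm)),
                                     ape::unroot(tr0)), 0)
    }
  })
})

test_that("bootstrap replicates are deterministic under the seed", {
  b <- simulate_family(small_sim_config(seed = 2))
  m <- aln_matrix(b$records)[1:12, ]
  t1 <- bootstrap_trees(m, 3, seed = 99)
  t2 <- bootstrap_trees(m, 3, seed = 99)
  expect_identical(lapply(t1, serialize_newick), lapply(t2, serialize_newick))

  # identical sequences: all-zero distances still give a valid topology
  same <- setNames(rep(strrep("ACDE", 10), 5), paste0("s", 1:5))
  bt <- bootstrap_trees(same, 2, seed = 1)
  expect_setequal(bt[[1]]$tip.label, names(same))
})

test_that("majority consensus matches a brute-force bipartition tally", {
  withr::with_seed(17, tr <- ape::rtree(6))
  cons <- majority_consensus(list(tr, tr, tr))
  expect_length(cons$splits, 3L)           # 6 - 3 internal splits
  expect_true(all(cons$freq == 1))

  # a split in exactly half the trees is excluded (strict >)
  t1 <- parse_newick("((A,B),(C,D),E);")
  t2 <- parse_newick("((A,C),(B,D),E);")
  cons2 <- majority_consensus(list(t1, t2))
  expect_length(cons2$splits, 0L)

  withr::with_seed(27, {
    for (i in 1:10) {
      trees <- lapply(1:7, function(j) ape::rtree(8))
      got <- majority_consensus(trees)
      oracle <- bf_consensus(trees)
      keys <- vapply(got$splits, function(s) paste(sort(s), collapse = "|"),
                     character(1))
      expect_setequal(keys, names(oracle))
      expect_equal(sort(got$freq), sort(unname(oracle)))
    }
  })
  expect_error(majority_consensus(list(t1, ape::rtree(4))), "mismatched")
})

test_that("RBIC is 1 for identical resolved replicates and 0 for stars", {
  withr::with_seed(41, tr <- ape::rtree(7))
  trees <- list(tr, tr, tr, tr)
  expect_equal(rbic(trees), 1)

  star <- ape::read.tree(text = "(A,B,C,D,E,F);")
  expect_equal(rbic(list(star, star, star)), 0)

  # a planted rogue depresses the score; removing it recovers it
  reps <- random_replicate_set(8, B = 20, seed = 5)
  expect_gt(rbic(reps, "rg1"), rbic(reps))

  expect_error(rbic(trees, tr$tip.label[1:4]), "fewer than 4")

  # equality with the brute-force drop.tip + tally oracle
  withr::with_seed(55, {
    for (i in 1:8) {
      reps <- random_replicate_set(7, B = 9, seed = i * 7)
      expect_equal(rbic(reps), bf_rbic(reps))
      lv <- sort(reps[[1]]$tip.label)[1:2]
      expect_equal(rbic(reps, lv[1]), bf_rbic(reps, lv[1]))
      expect_equal(rbic(reps, lv), bf_rbic(reps, lv))
    }
  })
})

test_that("greedy rogue detection matches the exhaustive single-leaf oracle", {
  # identical replicates: nothing to remove
  withr::with_seed(61, tr <- ape::rtree(8))
  expect_identical(nrow(detect_rogues(list(tr, tr, tr))), 0L)

  # one planted rogue: found, and the first pick equals the exhaustive best
  cfg0 <- prune_config(min_gain = 0)
  withr::with_seed(62, {
    for (i in 1:15) {
      reps <- random_replicate_set(sample(6:8, 1), B = 11, seed = 1000 + i)
      got <- detect_rogues(reps, cfg0)
      oracle <- bf_best_single_removal(reps)
      if (nrow(got) > 0) {
        expect_true(got$id[1] %in% oracle$ids)
        expect_identical(got$id[1], sort(oracle$ids)[1])  # lexicographic tie
      }
      if (oracle$score > bf_rbic(reps) + 1e-12) {
        expect_gt(nrow(got), 0)
      }
    }
  })

  # two planted rogues are both recovered within two rounds
  reps2 <- random_replicate_set(10, B = 25, seed = 77, n_rogue = 2)
  got2 <- detect_rogues(reps2, cfg0)
  expect_true(all(c("rg1", "rg2") %in% got2$id[1:2]))
})

test_that("long-branch detection flags pendant outliers against the median", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_length(detect_long_branches(tr, 10), 0L)

  tr2 <- parse_newick("((A:100,B:1):1,(C:1,D:1):1);")
  expect_identical(detect_long_branches(tr2, 10), "A")

  withr::with_seed(71, {
    tr3 <- ape::rtree(12)
    pend <- tr3$edge[, 2] <= 12
    tr3$edge.length[pend] <- 1 + runif(sum(pend), 0, 5)   # all below 10x median
  })
  expect_length(detect_long_branches(tr3, 10), 0L)

  tr4 <- tr; tr4$edge.length <- NULL
  expect_error(detect_long_branches(tr4, 10), "branch lengths")
})

test_that("subset splitting is balanced, exhaustive, and seeded", {
  ids <- paste0("x", 1:10)
  got <- split_subsets(ids, 3, seed = 5)
  expect_identical(vapply(got, length, integer(1)),
                   setNames(c(3L, 3L, 2L, 2L), as.character(1:4)))
  expect_setequal(unlist(got), ids)

  one <- split_subsets(ids, 50, seed = 5)
  expect_length(one, 1L)
  expect_setequal(one[[1]], ids)

  expect_identical(split_subsets(ids, 3, seed = 5), split_subsets(ids, 3, seed = 5))
})

test_that("iterative pruning is conservative and deterministic", {
  b <- simulate_family(small_sim_config(seed = 12, n_rogues = 0,
                                        n_long_branches = 0))
  keep <- b$truth$id[b$truth$role %in% c("member", "fragment")]
  m <- aln_matrix(b$records)[keep[1:30], ]

  # a builder whose replicates are all identical gives the detectors
  # nothing to find: every input id survives and the audit is empty
  frozen_builder <- function(aln, B, seed) {
    tr <- nj_tree(pdistance_matrix(aln))
    tr$edge.length <- rep(1, nrow(tr$edge))
    list(main = tr, reps = rep(list(tr), B))
  }
  cfg <- prune_config(n_iterations = 3, full_from_iteration = 2,
                      bootstrap_replicates = 10, seed = 3)
  pr0 <- iterative_prune(m, builder = frozen_builder, cfg = cfg)
  expect_setequal(pr0$survivors, rownames(m))
  expect_identical(nrow(pr0$audit), 0L)

  # same seed, same audit, byte for byte; and no id is removed twice
  cfg2 <- prune_config(n_iterations = 2, full_from_iteration = 2,
                       bootstrap_replicates = 20, seed = 3)
  pr1 <- iterative_prune(m, cfg = cfg2)
  pr2 <- iterative_prune(m, cfg = cfg2)
  expect_identical(pr1$audit, pr2$audit)
  expect_identical(pr1$survivors, pr2$survivors)
  expect_false(anyDuplicated(pr1$audit$id) > 0)
})
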