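test_that("site composition counts gaps as their own category", {
  aln <- c(a = "AK", b = "AK", c = "AE", d = "A-")
  got <- composition_at(aln, c("a", "b", "c", "d"), 2)
  expect_equal(got$fractions[["K"]], 0.5)
  expect_equal(got$fractions[["E"]], 0.25)
  expect_equal(got$fractions[["-"]], 0.25)
  expect_equal(sum(got$fractions), 1)

  allk <- composition_at(aln, c("a", "b"), 2)
  expect_equal(allk$fractions, c(K = 1))
  expect_error(composition_at(aln, character(), 2), "empty member set")

  # generator truth: the planted E clade is pure E among full-length members
  b <- simulate_family(small_sim_config(seed = 5))
  glu <- b$truth$id[b$truth$clade %in% "gluopsin"]
  comp <- composition_at(b$records, glu, b$site_position)
  n_frag <- sum(b$truth$role[b$truth$id %in% glu] == "fragment")
  expect_equal(comp$fractions[["E"]], (length(glu) - n_frag) / length(glu))
  expect_equal(comp$fractions[["-"]], n_frag / length(glu))
})

test_that("motif strings are read through the residue map", {
  b <- simulate_family(small_sim_config(seed = 5))
  m <- aln_matrix(b$records)
  rmap <- build_residue_map(m, b$ref_id,
                            paste(m[b$ref_id, ], collapse = ""))
  # the reference is rhodopsin-like: conserved NPxxY
  pat <- motif_string(m, b$ref_id, rmap)
  expect_identical(as.character(pat), "NPxxY")
  expect_true(attr(pat, "conserved"))

  # the planted E clade carries its derived pattern
  glu <- b$truth$id[b$truth$clade %in% "gluopsin" & b$truth$role == "member"]
  expect_identical(as.character(motif_string(m, glu[1], rmap)), "PVxxY")

  # a gap at the proline anchor renders as '-'
  x <- m["REF_Bos_taurus_rhodopsin", , drop = FALSE]
  rownames(x) <- "gappy"
  x[1, 303] <- "-"
  pat2 <- motif_string(rbind(m, x), "gappy", rmap)
  expect_identical(as.character(pat2), "N-xxY")
  expect_false(attr(pat2, "conserved"))

  # motif agrees with direct residue lookup at the anchor columns
  mc <- motif_config()
  for (id in c(b$ref_id, glu[1:3])) {
    pat <- as.character(motif_string(m, id, rmap, mc))
    expect_identical(substr(pat, 1, 1), residue_at(m, id, mc$anchors[["7.49"]]))
    expect_identical(substr(pat, 2, 2), residue_at(m, id, mc$anchors[["7.50"]]))
    expect_identical(substr(pat, 5, 5), residue_at(m, id, mc$anchors[["7.53"]]))
  }

  # anchors trimmed away is an error, not a silent pattern
  trim <- list(alignment = m[, -(300:310)],
               kept_columns = setdiff(seq_len(ncol(m)), 300:310))
  rmap2 <- build_residue_map(trim$alignment, b$ref_id,
                             paste(m[b$ref_id, ], collapse = ""),
                             kept_columns = trim$kept_columns,
                             ref_row_full = paste(m[b$ref_id, ], collapse = ""))
  expect_error(motif_string(trim$alignment, b$ref_id, rmap2),
               "motif region trimmed")
})

test_that("logo matrices are row-normalized frequency tables", {
  b <- simulate_family(small_sim_config(seed = 5))
  m <- aln_matrix(b$records)
  rmap <- build_residue_map(m, b$ref_id, paste(m[b$ref_id, ], collapse = ""))

  lone <- logo_matrix(m, b$ref_id, rmap)
  expect_true(all(rowSums(lone) == 1))
  expect_true(all(apply(lone, 1, max) == 1))   # single member: one-hot rows

  # two members disagreeing at one position split 0.5/0.5 there
  glu <- b$truth$id[b$truth$clade %in% "gluopsin" & b$truth$role == "member"]
  pair <- m[glu[1:2], ]
  lm2 <- logo_matrix(pair, glu[1:2], rmap)
  win <- motif_config()$window
  for (i in seq_along(win)) {
    ch <- pair[, win[i]]
    if (ch[1] == ch[2]) {
      expect_equal(lm2[i, ch[1]], 1)
    } else {
      expect_equal(unname(lm2[i, ch]), c(0.5, 0.5))
    }
  }

  # full clade vs a direct column tally oracle
  lmat <- logo_matrix(m, glu, rmap)
  for (i in c(1, 10, 20, 38)) {
    tb <- table(m[glu, win[i]])
    for (ch in names(tb)) {
      expect_equal(lmat[i, ch], unname(tb[ch]) / length(glu))
    }
  }
  expect_equal(unname(rowSums(lmat)), rep(1, length(win)))
  expect_error(logo_matrix(m, character(), rmap), "empty member set")
})

test_that("the lysine-loss scan reports maximal clades and spares singletons", {
  b <- simulate_family(small_sim_config(seed = 5))
  m <- aln_matrix(b$records)
  rmap <- build_residue_map(m, b$ref_id, paste(m[b$ref_id, ], collapse = ""))
  keep <- b$truth$id[b$truth$role %in% c("member", "fragment")]
  tree <- ape::keep.tip(b$tree, keep)

  got <- scan_lysine_loss(tree, m, rmap)
  glu <- b$truth$id[b$truth$clade %in% "gluopsin"]
  glu_full <- b$truth$id[b$truth$clade %in% "gluopsin" &
                           b$truth$role == "member"]
  nem <- b$truth$id[b$truth$clade %in% "nemopsin"]
  expect_setequal(got$consensus_residue, c("E", "R"))
  erow <- got[got$consensus_residue == "E", ]
  expect_setequal(strsplit(erow$members, ",")[[1]], glu)
  expect_identical(erow$n_with_replacement, length(glu_full))
  rrow <- got[got$consensus_residue == "R", ]
  expect_setequal(strsplit(rrow$members, ",")[[1]], nem)

  # maximality: the parent of every reported root holds a K-bearing member
  for (nd in got$node) {
    par <- tree$edge[, 1][match(nd, tree$edge[, 2])]
    sibs <- setdiff(tips_under(tree, par),
                    strsplit(got$members[got$node == nd], ",")[[1]])
    res <- m[sibs, map_position(rmap, 296)]
    expect_true(any(res == "K"))
  }

  # an isolated lysine-less leaf inside a K clade is never called
  tr <- parse_newick("((a,b),(c,(d,e)));")
  aln <- c(a = strrep("K", 350), b = strrep("K", 350), c = strrep("K", 350),
           d = strrep("K", 350), e = strrep("K", 350))
  substr(aln["d"], 296, 296) <- "E"
  rmap2 <- build_residue_map(aln, "a", strrep("K", 350))
  expect_identical(nrow(scan_lysine_loss(tr, aln, rmap2)), 0L)

  # an all-K family yields nothing
  aln2 <- aln; substr(aln2["d"], 296, 296) <- "K"
  expect_identical(nrow(scan_lysine_loss(tr, aln2, rmap2)), 0L)
})
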