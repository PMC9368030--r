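# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own bipartition/consensus machinery: they go through
# ape::extract.clade / ape::drop.tip directly.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# small scaled-down family used where full default sizes would be slow
small_sim_config <- function(seed = 1L, ...) {
  cl <- sim_clades_default()
  cl$size <- c(15L, 15L, 10L, 9L, 8L, 12L, 5L)
  sim_config(clades = cl, n_decoys = 12L, seed = seed, ...)
}

# brute-force gap-column filter
bf_trim <- function(m, maxgap) {
  keep <- integer()
  for (j in seq_len(ncol(m))) {
    if (sum(m[, j] == "-") / nrow(m) <= maxgap) keep <- c(keep, j)
  }
  list(alignment = m[, keep, drop = FALSE], kept_columns = keep)
}

# brute-force p-distance of one pair
bf_pdist_pair <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  comp <- ca != "-" & cb != "-"
  sum(ca[comp] != cb[comp]) / sum(comp)
}

# canonical bipartition keys of one tree via ape::extract.clade
bf_bip_keys <- function(tree, labels = sort(tree$tip.label)) {
  nt <- ape::Ntip(tree)
  keys <- character()
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    cl <- ape::extract.clade(tree, node)$tip.label
    side <- if (labels[1] %in% cl) setdiff(labels, cl) else cl
    if (length(side) >= 2L && length(side) <= nt - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# brute-force majority-rule frequencies across trees
bf_consensus <- function(trees, cutoff = 0.5) {
  labels <- sort(trees[[1]]$tip.label)
  tab <- table(unlist(lapply(trees, bf_bip_keys, labels = labels)))
  fr <- as.numeric(tab) / length(trees)
  names(fr) <- names(tab)
  sort(fr[fr > cutoff], decreasing = TRUE)
}

# brute-force RBIC via drop.tip restriction
bf_rbic <- function(trees, remove = character()) {
  n0 <- ape::Ntip(trees[[1]])
  restricted <- lapply(trees, function(tr) {
    if (length(remove)) ape::drop.tip(tr, remove) else tr
  })
  sum(bf_consensus(restricted)) / (n0 - 3)
}

# replicate sets with one genuinely unstable leaf: a base topology plus the
# rogue regrafted onto a random edge per replicate
random_replicate_set <- function(n_leaves, B, seed, n_rogue = 1L) {
  withr::with_seed(seed, {
    base <- ape::rtree(n_leaves - n_rogue)
    rogues <- paste0("rg", seq_len(n_rogue))
    lapply(seq_len(B), function(b) {
      tr <- base
      for (rg in rogues) {
        e <- sample.int(nrow(tr$edge), 1L)
        tr <- phytools::bind.tip(tr, rg, edge.length = 0.1,
                                 where = tr$edge[e, 2],
                                 position = runif(1) * tr$edge.length[e])
      }
      tr
    })
  })
}

# exhaustive best single-leaf removal by brute-force RBIC
bf_best_single_removal <- function(trees) {
  labels <- sort(trees[[1]]$tip.label)
  sc <- vapply(labels, function(x) bf_rbic(trees, x), numeric(1))
  best <- max(sc)
  list(ids = labels[sc >= best - 1e-12], score = best)
}
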