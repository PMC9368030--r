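## Rogue and long-branch pruning. The internal tree builder is
## neighbor-joining on protein p-distances with column-resampling
## bootstraps; rogue detection is a greedy single-leaf dropset search over
## an RBIC-style consensus-stability score, and long-branch detection flags
## pendant-length outliers against the median. Both detectors are
## deliberately simple, fully specified replacements for the external tools
## usually wired into such pipelines, behind a pluggable builder interface.

#' Pruning configuration
#'
#' @param subset_size Size of the random subsets trees are built on during
#'   the early iterations (default 900 sequences).
#' @param n_iterations Total pruning iterations (default 20).
#' @param full_from_iteration Iteration from which detection runs on the
#'   full remaining set instead of random subsets (default 10).
#' @param bootstrap_replicates Bootstrap replicate count B (default 100).
#' @param max_drop_per_round Maximum rogues removed per greedy round
#'   (default 10).
#' @param min_gain Minimum RBIC gain required to remove a leaf (the gain
#'   must be strictly greater). The default `NULL` means three-quarters of
#'   a consensus split, `0.75 / (n0 - 3)`: a removal must recover most of
#'   one full majority bipartition. Calibrated on simulated families,
#'   where bootstrap-noise gains of stable leaves stay below about 0.4
#'   splits while genuinely unstable leaves recover one or more. Set to 0
#'   to accept any positive gain.
#' @param long_branch_factor Pendant branches longer than this multiple of
#'   the median pendant length are flagged (default 10).
#' @param seed Integer seed controlling subset shuffling and bootstraps.
#' @return Object of class `prune_config`.
#' @export
prune_config <- function(subset_size = 900L, n_iterations = 20L,
                         full_from_iteration = 10L,
                         bootstrap_replicates = 100L,
                         max_drop_per_round = 10L, min_gain = NULL,
                         long_branch_factor = 10, seed = 1L) {
  stopifnot(subset_size >= 2L, bootstrap_replicates >= 2L,
            full_from_iteration >= 1L,
            full_from_iteration <= n_iterations)
  structure(list(subset_size = as.integer(subset_size),
                 n_iterations = as.integer(n_iterations),
                 full_from_iteration = as.integer(full_from_iteration),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 max_drop_per_round = as.integer(max_drop_per_round),
                 min_gain = min_gain,
                 long_branch_factor = long_branch_factor,
                 seed = as.integer(seed)),
            class = "prune_config")
}

aln_codes <- function(m) {
  codes <- match(m, c(AA20, "X"))          # gap and anything else -> NA
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(m), dimnames = dimnames(m))
}

.pdist_codes <- function(codes) {
  d <- cpp_pdistance(codes)
  if (any(d < 0)) {
    bad <- which(d < 0, arr.ind = TRUE)[1L, ]
    stop("no comparable (ungapped-in-both) sites between ",
         rownames(codes)[bad[1]], " and ", rownames(codes)[bad[2]])
  }
  dimnames(d) <- list(rownames(codes), rownames(codes))
  d
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the fraction of mismatched residues among columns where
#' neither sequence is gapped. A pair sharing no comparable column is an
#' error (naming the pair).
#'
#' @param aln Alignment matrix (or named vector of aligned sequences) with
#'   at least two rows.
#' @return Symmetric numeric matrix with zero diagonal and dimnames = IDs.
#' @export
pdistance_matrix <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least two sequences")
  .pdist_codes(aln_codes(m))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining ([ape::nj()]) with negative branch lengths
#' clamped to zero. On an additive matrix the generating topology is
#' recovered.
#'
#' @param dm Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted phylo tree (rooted arbitrarily at the final join).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("dm must be square")
  if (nrow(dm) < 3L) stop("need at least three taxa")
  if (!isSymmetric(unname(dm), tol = 1e-9)) stop("asymmetric distance matrix")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap trees by column resampling
#'
#' Draws `B` column resamples (with replacement) of the alignment, computes
#' p-distances and builds a neighbor-joining tree from each. A resample in
#' which some pair has no comparable column is redrawn (up to 10 attempts).
#' Deterministic under `seed`.
#'
#' @param aln Alignment matrix (or named vector).
#' @param B Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return List of `B` phylo trees on the full leaf set.
#' @export
bootstrap_trees <- function(aln, B, seed = 1L) {
  stopifnot(B >= 1L)
  m <- aln_matrix(aln)
  codes <- aln_codes(m)
  L <- ncol(codes)
  withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      for (attempt in 1:10) {
        idx <- sample.int(L, L, replace = TRUE)
        d <- tryCatch(.pdist_codes(codes[, idx, drop = FALSE]),
                      error = function(e) NULL)
        if (!is.null(d)) return(nj_tree(d))
      }
      stop("bootstrap replicate ", b,
           " kept producing incomparable pairs after 10 redraws")
    })
  })
}

#' Nontrivial bipartitions of a tree
#'
#' @param tree A phylo tree.
#' @param labels Master leaf order (defaults to the tree's sorted tip
#'   labels).
#' @return 0/1 integer matrix, one row per distinct nontrivial bipartition
#'   (canonical: the side not containing `labels[1]`), columns = `labels`.
#' @export
tree_bipartitions <- function(tree, labels = sort(tree$tip.label)) {
  if (!setequal(tree$tip.label, labels)) {
    stop("tree leaf set does not match the master label set")
  }
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  M <- matrix(0L, nt + nn, length(labels))
  M[cbind(seq_len(nt), match(tree$tip.label, labels))] <- 1L
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    M[eo[k, 1], ] <- M[eo[k, 1], ] + M[eo[k, 2], ]
  }
  internal_children <- unique(tree$edge[, 2][tree$edge[, 2] > nt])
  B <- M[internal_children, , drop = FALSE]
  sz <- rowSums(B)
  B <- B[sz >= 2L & sz <= nt - 2L, , drop = FALSE]
  if (nrow(B) == 0L) {
    return(matrix(0L, 0L, length(labels), dimnames = list(NULL, labels)))
  }
  flip <- B[, 1] == 1L
  B[flip, ] <- 1L - B[flip, , drop = FALSE]
  B <- unique(B)
  colnames(B) <- labels
  B
}

bip_key <- function(B) {
  apply(B, 1L, function(r) paste(which(r == 1L), collapse = ","))
}

#' Majority-rule consensus bipartitions
#'
#' Tallies nontrivial bipartitions across replicate trees; entries are
#' bipartitions occurring in strictly more than `cutoff` of the trees, with
#' exact frequencies (rationals of B).
#'
#' @param trees List of phylo trees sharing one leaf set.
#' @param cutoff Frequency cutoff (strict; default 0.5).
#' @return Object of class `bipartition_table`: list with `leafset`,
#'   `splits` (list of label vectors, the canonical side of each split) and
#'   `freq` (numeric vector).
#' @export
majority_consensus <- function(trees, cutoff = 0.5) {
  stopifnot(length(trees) >= 1L)
  labels <- sort(trees[[1]]$tip.label)
  B <- length(trees)
  tal <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    if (!setequal(tr$tip.label, labels)) stop("trees have mismatched leaf sets")
    keys <- unique(bip_key(tree_bipartitions(tr, labels)))
    for (k in keys) assign(k, (get0(k, envir = tal) %||% 0L) + 1L, envir = tal)
  }
  keys <- ls(tal)
  cnt <- vapply(keys, get, integer(1), envir = tal)
  sel <- cnt / B > cutoff
  keys <- keys[sel]; cnt <- cnt[sel]
  splits <- lapply(strsplit(keys, ","), function(i) labels[as.integer(i)])
  structure(list(leafset = labels, splits = splits, freq = unname(cnt) / B),
            class = "bipartition_table")
}

#' @export
print.bipartition_table <- function(x, ...) {
  cat("<bipartition_table>", length(x$splits), "majority splits over",
      length(x$leafset), "leaves\n")
  invisible(x)
}

.bipmats <- function(trees, labels) {
  lapply(trees, function(tr) tree_bipartitions(tr, labels))
}

#' RBIC consensus-stability score after leaf removal
#'
#' Every replicate tree is restricted to the leaf set minus `remove`; the
#' frequencies of all majority-rule (> 1/2) bipartitions are summed and
#' divided by `n0 - 3`, where `n0` is the *original* leaf count (held fixed
#' so removals cannot inflate the score trivially). The score is 1 exactly
#' when all replicates are identical and fully resolved, and 0 for star
#' trees.
#'
#' @param trees List of replicate phylo trees on one leaf set.
#' @param remove Character vector of leaves to remove (at least 4 must
#'   remain).
#' @return Scalar in \[0, 1\].
#' @export
rbic <- function(trees, remove = character()) {
  labels <- sort(trees[[1]]$tip.label)
  if (!all(remove %in% labels)) stop("remove contains unknown leaves")
  n0 <- length(labels)
  if (n0 - length(remove) < 4L) stop("fewer than 4 leaves would remain")
  keep <- !(labels %in% remove)
  cpp_rbic_score(.bipmats(trees, labels), keep, n0)
}

#' Greedy rogue detection over replicate trees
#'
#' Repeatedly evaluates, for every remaining leaf, the RBIC gain of removing
#' it; removes the best leaf if its gain is strictly greater than
#' `min_gain` (ties broken by the lexicographically smallest label), up to
#' `max_drop_per_round` removals. Deterministic.
#'
#' @param trees List of replicate phylo trees (>= 5 leaves).
#' @param cfg A [prune_config()].
#' @return Data frame with columns `id` and `gain`, in removal order
#'   (zero rows when no removal qualifies).
#' @export
detect_rogues <- function(trees, cfg = prune_config()) {
  labels <- sort(trees[[1]]$tip.label)
  n0 <- length(labels)
  if (n0 < 5L) stop("need at least 5 leaves")
  min_gain <- cfg$min_gain %||% (0.75 / (n0 - 3))
  bips <- .bipmats(trees, labels)
  keep <- rep(TRUE, n0)
  base <- cpp_rbic_score(bips, keep, n0)
  out_id <- character(); out_gain <- numeric()
  while (length(out_id) < cfg$max_drop_per_round && sum(keep) - 1L >= 4L) {
    sc <- cpp_rbic_drop_scores(bips, keep, n0)
    gains <- sc - base
    best <- max(gains, na.rm = TRUE)
    ## the 1e-9 guard keeps floating-point dust from qualifying as a gain
    if (!(best > min_gain + 1e-9)) break
    cand <- which(!is.na(gains) & gains >= best - 1e-12)
    pick <- cand[order(labels[cand])][1]     # lexicographic tie-break
    keep[pick] <- FALSE
    out_id <- c(out_id, labels[pick])
    out_gain <- c(out_gain, gains[pick])
    base <- sc[pick]
  }
  data.frame(id = out_id, gain = out_gain, stringsAsFactors = FALSE)
}

#' Flag long pendant branches
#'
#' Flags leaves whose pendant branch length exceeds `factor` times the
#' median pendant length; an all-zero median disables flagging.
#'
#' @param tree A phylo tree with branch lengths (>= 4 leaves).
#' @param factor Multiple of the median (default 10).
#' @return Character vector of flagged tip labels (possibly empty).
#' @export
detect_long_branches <- function(tree, factor = 10) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (ape::Ntip(tree) < 4L) stop("need at least 4 leaves")
  tip_edges <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  pend <- tree$edge.length[tip_edges]
  med <- median(pend)
  if (med == 0) return(character())
  tree$tip.label[pend > factor * med]
}

#' Deterministically split IDs into random subsets
#'
#' @param ids Character vector.
#' @param subset_size Target subset size (>= 2).
#' @param seed Integer seed for the shuffle.
#' @return List of `ceiling(n / subset_size)` disjoint ID vectors whose
#'   sizes differ by at most one and whose union is `ids`.
#' @export
split_subsets <- function(ids, subset_size, seed = 1L) {
  stopifnot(subset_size >= 2L)
  n <- length(ids)
  if (n == 0L) return(list())
  shuffled <- withr::with_seed(seed, sample(ids))
  k <- ceiling(n / subset_size)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(shuffled, rep(seq_len(k), times = sizes))
}

#' Internal NJ + bootstrap tree builder
#'
#' Returns a builder closure mapping an alignment slice to a main
#' neighbor-joining tree plus `B` column-resampling bootstrap replicates.
#' External tree builders (e.g. maximum-likelihood tools) can be wired in by
#' supplying any function with the same contract:
#' `function(aln, B, seed) -> list(main = phylo, reps = list of phylo)`.
#'
#' @return A builder function.
#' @export
nj_boot_builder <- function() {
  function(aln, B, seed) {
    m <- aln_matrix(aln)
    list(main = nj_tree(pdistance_matrix(m)),
         reps = bootstrap_trees(m, B, seed))
  }
}

#' Iterative rogue and long-branch pruning
#'
#' Runs `n_iterations` rounds of detection and removal. Iterations before
#' `full_from_iteration` split the remaining IDs into random subsets of
#' about `subset_size` sequences, run both detectors per subset, and apply
#' the union of removals; from `full_from_iteration` onward detection runs
#' on the full remaining set. Deterministic under the configured seed.
#'
#' @param aln Alignment matrix (or named vector) of all candidate sequences.
#' @param builder Tree builder (default [nj_boot_builder()]).
#' @param cfg A [prune_config()].
#' @return List with `survivors` (character IDs) and `audit` (data frame:
#'   `iteration`, `subset`, `id`, `cause` in `{"rogue", "long_branch"}`,
#'   `score` — RBIC gain for rogues, pendant length for long branches).
#' @export
iterative_prune <- function(aln, builder = NULL, cfg = prune_config()) {
  builder <- builder %||% nj_boot_builder()
  m <- aln_matrix(aln)
  remaining <- rownames(m)
  audit <- list()
  for (it in seq_len(cfg$n_iterations)) {
    subsets <- if (it < cfg$full_from_iteration) {
      split_subsets(remaining, cfg$subset_size, seed = cfg$seed + 131L * it)
    } else {
      list(remaining)
    }
    removed <- character()
    for (j in seq_along(subsets)) {
      sub <- subsets[[j]]
      if (length(sub) < 5L) next
      res <- tryCatch(
        builder(m[sub, , drop = FALSE], cfg$bootstrap_replicates,
                cfg$seed + 131L * it + j),
        error = function(e) {
          stop("tree builder failed at iteration ", it, ", subset ", j, ": ",
               conditionMessage(e))
        })
      rog <- detect_rogues(res$reps, cfg)
      longs <- setdiff(detect_long_branches(res$main, cfg$long_branch_factor),
                       rog$id)
      if (nrow(rog)) {
        audit[[length(audit) + 1L]] <-
          data.frame(iteration = it, subset = j, id = rog$id,
                     cause = "rogue", score = rog$gain)
      }
      if (length(longs)) {
        tip_edges <- match(match(longs, res$main$tip.label), res$main$edge[, 2])
        audit[[length(audit) + 1L]] <-
          data.frame(iteration = it, subset = j, id = longs,
                     cause = "long_branch",
                     score = res$main$edge.length[tip_edges])
      }
      removed <- union(removed, c(rog$id, longs))
    }
    remaining <- setdiff(remaining, removed)
  }
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(iteration = integer(), subset = integer(), id = character(),
               cause = character(), score = numeric())
  list(survivors = remaining, audit = audit)
}

#' Write a pruning audit table as TSV
#'
#' @param audit The `audit` element of an [iterative_prune()] result.
#' @param path Output TSV path.
#' @export
write_prune_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
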