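## Bait-anchored target-family filter: split a large pool into subsets,
## inject bait sequences plus an outgroup anchor into each, build a tree per
## subset, extract the subtree spanned by the baits after rooting at the
## anchor, and union the retained leaves. Baits that make the spanned clade
## cover the whole tree are reported (candidate "rogue baits"), never
## deleted automatically.

#' Bait filter configuration
#'
#' @param subset_size Pool subset size (default 900).
#' @param add_back_random Number of random non-retained sequences to add
#'   back afterwards as a diverse outgroup (default 1000).
#' @param keep_patterns Character vector of ID substrings retained
#'   unconditionally by [add_back()] (e.g. a genus such as `"Trichoplax"`).
#' @param keep_baits Keep bait IDs in the retained output? Baits are probes,
#'   not data, so the default drops them.
#' @param seed Integer seed for subset shuffling and the add-back sample.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(subset_size = 900L, add_back_random = 1000L,
                          keep_patterns = character(), keep_baits = FALSE,
                          seed = 1L) {
  stopifnot(subset_size >= 2L, add_back_random >= 0L)
  structure(list(subset_size = as.integer(subset_size),
                 add_back_random = as.integer(add_back_random),
                 keep_patterns = keep_patterns, keep_baits = keep_baits,
                 seed = as.integer(seed)),
            class = "filter_config")
}

#' Filter a sequence pool down to the bait-spanned family
#'
#' The pool is split into random subsets; every subset receives the full
#' bait list and the anchor (IDs duplicating a pool member are suffixed
#' deterministically with `"_bait"`), a tree is built per subset, and
#' [extract_bait_clade()] collects the leaves spanned by the baits. The
#' retained set is the union over subsets, minus the baits themselves.
#'
#' @param pool Named character vector of aligned candidate sequences.
#' @param baits Named character vector of aligned bait sequences (>= 2).
#' @param anchor Single named aligned sequence used as the outgroup anchor
#'   (e.g. an olfactory receptor); must not be a bait.
#' @param builder Function mapping a named sequence vector to a phylo tree
#'   containing every input ID; defaults to neighbor joining on p-distances.
#' @param cfg A [filter_config()].
#' @return List with `retained` (character IDs from the pool) and `report`
#'   (data frame per subset: `subset_index`, `n_retained`, `failed`,
#'   `spanning_baits`).
#' @export
bait_filter <- function(pool, baits, anchor, builder = NULL,
                        cfg = filter_config()) {
  stopifnot(length(baits) >= 2L, length(anchor) == 1L,
            !is.null(names(anchor)))
  if (names(anchor) %in% names(baits)) stop("anchor must not be a bait")
  builder <- builder %||% function(seqs) nj_tree(pdistance_matrix(seqs))
  bait_ids <- names(baits)
  dup <- bait_ids %in% names(pool)
  bait_ids[dup] <- paste0(bait_ids[dup], "_bait")
  names(baits) <- bait_ids
  anchor_id <- names(anchor)
  if (anchor_id %in% names(pool)) {
    anchor_id <- paste0(anchor_id, "_anchor")
    names(anchor) <- anchor_id
  }

  subsets <- split_subsets(names(pool), cfg$subset_size, seed = cfg$seed)
  retained <- character()
  rep_rows <- vector("list", length(subsets))
  for (j in seq_along(subsets)) {
    seqs <- c(pool[subsets[[j]]], baits, anchor)
    tree <- builder(seqs)
    got <- tryCatch(
      extract_bait_clade(tree, anchor_id, bait_ids),
      opsinpipe_baits_span_tree = function(e) e)
    spanning <- character()
    if (inherits(got, "condition")) {
      ## a bait whose exclusion resolves the span to a proper clade is the
      ## one pulling the span across the root; retry once without the
      ## spanning baits so the subset can still contribute (the baits
      ## themselves are only reported, never deleted from the input)
      inf <- e_influence(got)
      spanning <- names(inf)[!is.na(inf)]
      rest <- setdiff(intersect(bait_ids, tree$tip.label), spanning)
      got <- if (length(rest) >= 2L) {
        tryCatch(extract_bait_clade(tree, anchor_id, rest),
                 opsinpipe_baits_span_tree = function(e) e,
                 error = function(e) e)
      } else {
        got
      }
    }
    if (inherits(got, "condition")) {
      rep_rows[[j]] <- data.frame(
        subset_index = j, n_retained = 0L, failed = TRUE,
        spanning_baits = paste(spanning, collapse = ","))
    } else {
      keep <- setdiff(got, bait_ids)
      retained <- union(retained, keep)
      rep_rows[[j]] <- data.frame(subset_index = j, n_retained = length(keep),
                                  failed = FALSE,
                                  spanning_baits = paste(spanning,
                                                         collapse = ","))
    }
  }
  report <- do.call(rbind, rep_rows)
  if (all(report$failed)) stop("bait-clade extraction failed on every subset")
  if (cfg$keep_baits) retained <- union(retained, intersect(bait_ids, names(pool)))
  list(retained = retained, report = report)
}

e_influence <- function(cond) cond$influence

#' Add back outgroup and keep-pattern sequences
#'
#' Augments a retained ID set with a deterministic seeded random sample of
#' the non-retained pool (a diverse outgroup) and with every pool ID
#' matching any of the configured keep patterns (substring match).
#'
#' @param retained Character IDs already retained.
#' @param pool_ids All pool IDs.
#' @param cfg A [filter_config()].
#' @return Character ID set (always a superset of `retained`).
#' @export
add_back <- function(retained, pool_ids, cfg = filter_config()) {
  avail <- setdiff(pool_ids, retained)
  k <- cfg$add_back_random
  if (k > length(avail)) {
    warning("add_back_random exceeds available sequences; clamping to ",
            length(avail))
    k <- length(avail)
  }
  extra <- if (k > 0L) withr::with_seed(cfg$seed, sample(avail, k)) else
    character()
  pat <- character()
  for (p in cfg$keep_patterns) {
    pat <- union(pat, pool_ids[grepl(p, pool_ids, fixed = TRUE)])
  }
  union(union(retained, extra), pat)
}

#' Write a bait-filter subset report as TSV
#'
#' @param report The `report` element of a [bait_filter()] result.
#' @param path Output TSV path.
#' @export
write_filter_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
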