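## Tree algorithms on ape "phylo" objects: newick I/O with per-branch
## support triples (SH-aLRT / aBayes / UFBoot encoded in internal-node
## labels as "sh/abayes/ufboot"), leaf and node rerooting, marked-descendant
## counting, clade-root identification from defining leaves, bait-spanned
## clade extraction, and the three-support branch acceptance policy.

#' Parse a newick string into a phylo tree
#'
#' Internal-node labels of the form `"x/y/z"` are interpreted downstream as
#' support triples (see [support_triples()]); other labels are kept verbatim.
#'
#' @param text Newick string.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) stop("newick parse error")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Serialize a phylo tree to newick
#'
#' @param tree An [ape::phylo] tree.
#' @return Newick string.
#' @export
serialize_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Parse support triples from internal-node labels
#'
#' Labels are expected as `"sh/abayes/ufboot"` with empty fields for absent
#' components (e.g. `"80//95"`). SH-aLRT and UFBoot are percentages in
#' \[0, 100\]; aBayes is a probability in \[0, 1\].
#'
#' @param tree A phylo tree (or a character vector of labels).
#' @return Data frame with columns `sh_alrt`, `abayes`, `ufboot`, one row per
#'   internal node (or per label).
#' @export
support_triples <- function(tree) {
  labs <- if (inherits(tree, "phylo")) tree$node.label else tree
  n <- if (inherits(tree, "phylo")) tree$Nnode else length(labs)
  out <- data.frame(sh_alrt = rep(NA_real_, n), abayes = NA_real_,
                    ufboot = NA_real_)
  if (is.null(labs) || length(labs) == 0L) return(out)
  parts <- strsplit(labs, "/", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) next                 # not a support label
    p <- c(p, rep("", 3L))[1:3]
    v <- suppressWarnings(as.numeric(p))
    out$sh_alrt[i] <- v[1]; out$abayes[i] <- v[2]; out$ufboot[i] <- v[3]
  }
  out
}

#' Branch support acceptance policy
#'
#' A branch is *rejected* outright when its SH-aLRT value is below
#' `reject_sh_below` regardless of the other supports; it is *accepted* when
#' all three supports are present and at or above their thresholds;
#' otherwise it is *ambiguous*. The rejection threshold is applied on the
#' 0-100 SH-aLRT scale exactly as configured.
#'
#' @param reject_sh_below Reject below this SH-aLRT value (default 0.1).
#' @param accept_sh Accept SH-aLRT at or above this value (default 80).
#' @param accept_abayes Accept aBayes at or above this value (default 0.95).
#' @param accept_ufboot Accept UFBoot at or above this value (default 95).
#' @return Object of class `support_policy`.
#' @export
support_policy <- function(reject_sh_below = 0.1, accept_sh = 80,
                           accept_abayes = 0.95, accept_ufboot = 95) {
  stopifnot(reject_sh_below < accept_sh)
  structure(list(reject_sh_below = reject_sh_below, accept_sh = accept_sh,
                 accept_abayes = accept_abayes, accept_ufboot = accept_ufboot),
            class = "support_policy")
}

#' Classify branches by their support triple
#'
#' @param s Numeric vector `c(sh_alrt, abayes, ufboot)` (NAs allowed) or a
#'   data frame as returned by [support_triples()].
#' @param policy A [support_policy()].
#' @return Character vector over `{"accepted", "rejected", "ambiguous"}`.
#' @export
branch_status <- function(s, policy = support_policy()) {
  stopifnot(inherits(policy, "support_policy"))
  if (is.data.frame(s)) {
    sh <- s$sh_alrt; ab <- s$abayes; uf <- s$ufboot
  } else {
    s <- as.numeric(s)
    stopifnot(length(s) == 3L)
    sh <- s[1]; ab <- s[2]; uf <- s[3]
  }
  rejected <- !is.na(sh) & sh < policy$reject_sh_below
  accepted <- !is.na(sh) & !is.na(ab) & !is.na(uf) &
    sh >= policy$accept_sh & ab >= policy$accept_abayes &
    uf >= policy$accept_ufboot
  out <- rep("ambiguous", length(rejected))
  out[accepted] <- "accepted"
  out[rejected] <- "rejected"              # rejection wins over acceptance
  out
}

## parent of every node (0 for the root)
parent_vec <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Tip labels descending from a node
#'
#' @param tree A phylo tree.
#' @param node Node id (tips are `1..Ntip`).
#' @return Character vector of tip labels under `node` (the label itself for
#'   a tip).
#' @export
tips_under <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  todo <- node
  tips <- integer()
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(todo)) {
    cur <- todo[[1]]; todo <- todo[-1]
    ch <- kids[[as.character(cur)]]
    istip <- ch <= nt
    tips <- c(tips, ch[istip])
    todo <- c(todo, ch[!istip])
  }
  tree$tip.label[sort(tips)]
}

#' Reroot a tree at a leaf
#'
#' The new root is placed on the leaf's pendant edge, splitting its length at
#' the midpoint, so the root has exactly two children: the leaf and the rest
#' of the tree. Leaf set and all pairwise leaf-to-leaf path lengths are
#' preserved.
#'
#' @param tree A phylo tree.
#' @param leaf_label Tip label to root at.
#' @return Rerooted phylo tree.
#' @export
reroot_at_leaf <- function(tree, leaf_label) {
  tip <- match(leaf_label, tree$tip.label)
  if (is.na(tip)) stop("unknown leaf: ", leaf_label)
  if (is.null(tree$edge.length)) {
    return(ape::root(tree, outgroup = leaf_label, resolve.root = TRUE))
  }
  el <- tree$edge.length[tree$edge[, 2] == tip]
  phytools::reroot(tree, tip, position = el / 2)
}

#' Reroot a tree on the edge above an internal node
#'
#' The new root is placed on the edge above `node` with a zero-length split
#' toward the node, so the root's two children are the node's subtree (the
#' ingroup side) and the remainder of the tree.
#'
#' @param tree A phylo tree.
#' @param node Internal node id.
#' @return Rerooted phylo tree (identity, with a warning, if `node` is
#'   already the root).
#' @export
reroot_at_node <- function(tree, node) {
  if (node == root_node(tree)) {
    warning("node is already the root; returning tree unchanged")
    return(tree)
  }
  if (node <= ape::Ntip(tree)) stop("node must be internal; got a tip")
  if (is.null(tree$edge.length)) {
    tr <- tree
    tr$edge.length <- rep(1, nrow(tr$edge))
    out <- phytools::reroot(tr, node,
                            position = tr$edge.length[tr$edge[, 2] == node])
    out$edge.length <- NULL
    return(out)
  }
  el <- tree$edge.length[tree$edge[, 2] == node]
  phytools::reroot(tree, node, position = el)
}

#' Count marked leaves below every node
#'
#' @param tree A phylo tree.
#' @param marked Character vector of tip labels (subset of the leaf set).
#' @return Integer vector indexed by node id (`1..Ntip+Nnode`): number of
#'   marked leaves in the subtree of each node.
#' @export
count_marked_descendants <- function(tree, marked) {
  bad <- setdiff(marked, tree$tip.label)
  if (length(bad)) stop("marked labels absent from tree: ",
                        paste(bad, collapse = ", "))
  nt <- ape::Ntip(tree)
  cnt <- integer(nt + tree$Nnode)
  cnt[match(marked, tree$tip.label)] <- 1L
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    cnt[eo[k, 1]] <- cnt[eo[k, 1]] + cnt[eo[k, 2]]
  }
  cnt
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A phylo tree.
#' @param labels Non-empty character vector of tip labels.
#' @return Node id (the tip itself for a single label).
#' @export
mrca_leaves <- function(tree, labels) {
  if (length(labels) == 0L) stop("empty leaf set")
  bad <- setdiff(labels, tree$tip.label)
  if (length(bad)) stop("labels absent from tree: ", paste(bad, collapse = ", "))
  if (length(labels) == 1L) return(match(labels, tree$tip.label))
  ape::getMRCA(tree, labels)
}

#' Root node of the clade defined by one defining leaf
#'
#' The clade root is the highest ancestor of `defining_leaf` whose subtree
#' contains exactly one defining leaf, i.e. the maximal subtree containing
#' this defining leaf and no other.
#'
#' @param tree A rooted phylo tree.
#' @param defining_leaf Tip label of this clade's defining leaf.
#' @param all_defining Tip labels of all defining leaves (including
#'   `defining_leaf`).
#' @return Node id of the clade root (the defining leaf itself when a second
#'   defining leaf is its sibling).
#' @export
clade_root <- function(tree, defining_leaf, all_defining) {
  if (!defining_leaf %in% all_defining) {
    stop("defining_leaf must be among all_defining")
  }
  tip <- match(defining_leaf, tree$tip.label)
  if (is.na(tip)) stop("defining leaf absent from tree: ", defining_leaf)
  cnt <- count_marked_descendants(tree, all_defining)
  par <- parent_vec(tree)
  node <- tip
  while (par[node] != 0L && cnt[par[node]] == 1L) node <- par[node]
  node
}

#' Read clade definitions from CSV
#'
#' Expected columns: `name`, `color`, `sequence_id` (with header). The last
#' row conventionally names the outgroup anchor leaf used to root the tree.
#'
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_clade_definitions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "color", "sequence_id")
  if (!all(need %in% names(df))) {
    stop("clade definition CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$name)) stop("duplicate clade names")
  if (anyDuplicated(df$sequence_id)) stop("duplicate defining sequence IDs")
  df[need]
}

#' Assign leaves to clades from defining leaves
#'
#' Each clade definition contributes one defining leaf; the clade is the
#' maximal subtree containing that leaf and no other defining leaf (see
#' [clade_root()]). Leaves in no clade form the residual outgroup. When a
#' defining leaf is absent from the tree (e.g. a pruned reduced tree), an
#' ordered fallback list of member leaves from a prior full-tree assignment
#' may be supplied via `substitutes`; the first present leaf wins.
#'
#' @param tree A rooted phylo tree.
#' @param defs Data frame of clade definitions (`name`, `color`,
#'   `sequence_id`), e.g. from [read_clade_definitions()].
#' @param substitutes Optional named list: clade name -> ordered character
#'   vector of substitute defining leaves.
#' @return Object of class `clade_assignment`: list with `clades` (named list
#'   of `list(name, color, defining_leaf, root, members)`) and `outgroup`
#'   (character vector of residual leaves).
#' @export
assign_clades <- function(tree, defs, substitutes = NULL) {
  leaves <- character(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    cand <- c(defs$sequence_id[i], substitutes[[defs$name[i]]])
    hit <- cand[cand %in% tree$tip.label]
    if (length(hit) == 0L) {
      stop("defining leaf absent from tree (and no substitute present) for ",
           "clade ", defs$name[i])
    }
    leaves[i] <- hit[1]
  }
  if (anyDuplicated(leaves)) stop("two clades resolve to the same defining leaf")
  roots <- vapply(leaves, function(lf) clade_root(tree, lf, leaves), integer(1))
  if (anyDuplicated(roots)) {
    d <- which(duplicated(roots) | duplicated(roots, fromLast = TRUE))
    stop("clade definitions resolve to the same clade root: ",
         paste(defs$name[d], collapse = " and "))
  }
  clades <- vector("list", nrow(defs))
  names(clades) <- defs$name
  used <- character()
  for (i in seq_len(nrow(defs))) {
    mem <- tips_under(tree, roots[i])
    if (length(intersect(mem, used))) {
      stop("clade member sets are not disjoint (overlap at clade ",
           defs$name[i], ")")
    }
    used <- c(used, mem)
    clades[[i]] <- list(name = defs$name[i], color = defs$color[i],
                        defining_leaf = leaves[i], root = roots[i],
                        members = mem)
  }
  structure(list(clades = clades,
                 outgroup = setdiff(tree$tip.label, used)),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat("<clade_assignment>", length(x$clades), "clades,",
      length(x$outgroup), "outgroup leaves\n")
  for (cl in x$clades) {
    cat(sprintf("  %-20s %5d leaves (defining: %s)\n",
                cl$name, length(cl$members), cl$defining_leaf))
  }
  invisible(x)
}

#' Export a clade assignment as TSV
#'
#' Columns: `leaf_id`, `clade_name` (`"outgroup"` for residual leaves).
#'
#' @param asn A [assign_clades()] result.
#' @param path Output TSV path.
#' @export
write_clade_assignment <- function(asn, path) {
  rows <- do.call(rbind, c(
    lapply(asn$clades, function(cl) {
      data.frame(leaf_id = cl$members, clade_name = cl$name)
    }),
    list(if (length(asn$outgroup))
      data.frame(leaf_id = asn$outgroup, clade_name = "outgroup"))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the leaf set spanned by bait sequences
#'
#' The tree is rerooted at the non-member anchor leaf (e.g. an olfactory
#' receptor among opsins), with the anchor kept as a direct child of the
#' root; the returned set is every leaf under the MRCA of the bait labels
#' present in the tree. If that MRCA is the root itself, the baits sit on
#' both sides of the anchor and span the entire tree: a classed error
#' (`opsinpipe_baits_span_tree`) is signalled carrying a per-bait influence
#' report, the size of the clade spanned when that bait is left out.
#'
#' @param tree A phylo tree.
#' @param anchor_leaf Outgroup anchor tip label (not a bait).
#' @param bait_labels Bait tip labels (at least two present in the tree).
#' @return Character vector of spanned leaf labels (excluding the anchor).
#' @export
extract_bait_clade <- function(tree, anchor_leaf, bait_labels) {
  if (anchor_leaf %in% bait_labels) stop("anchor must not be a bait")
  if (!anchor_leaf %in% tree$tip.label) {
    stop("unknown leaf: ", anchor_leaf)
  }
  ## root at the anchor's attachment node, anchor as a direct root child
  ## (unresolved), so "MRCA of the baits = root" means the baits surround
  ## the anchor and span the whole tree
  tr <- ape::root(tree, outgroup = anchor_leaf, resolve.root = FALSE)
  present <- intersect(bait_labels, tr$tip.label)
  if (length(present) < 2L) {
    stop("fewer than two bait labels present in the tree")
  }
  node <- mrca_leaves(tr, present)
  if (node == root_node(tr)) {
    influence <- vapply(present, function(b) {
      rest <- setdiff(present, b)
      if (length(rest) < 2L) return(NA_integer_)
      nd <- mrca_leaves(tr, rest)
      if (nd == root_node(tr)) return(NA_integer_)
      length(tips_under(tr, nd))
    }, integer(1))
    cond <- structure(
      class = c("opsinpipe_baits_span_tree", "error", "condition"),
      list(message = paste0(
        "baits span entire tree; per-bait spanned-clade size when excluded: ",
        paste(sprintf("%s=%s", present, influence), collapse = ", ")),
        call = sys.call(-1), influence = influence))
    stop(cond)
  }
  setdiff(tips_under(tr, node), anchor_leaf)
}
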