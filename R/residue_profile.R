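## The biological payload: residue composition at the mapped retinal-binding
## site (bovine rhodopsin K296, Ballesteros-Weinstein 7.43), NPxxY (7.53)
## motif calling, sequence-logo frequency matrices over the helix-7 window,
## and the scan for clades that have lost the lysine, with the
## singleton-exclusion rule (an isolated lysine-less sequence inside an
## otherwise lysine-bearing clade is never called).

#' Motif and logo window configuration
#'
#' Anchors follow helix-7 arithmetic from the 7.43 lysine at reference
#' position 296: position = 296 + (k - 43) for Ballesteros-Weinstein label
#' 7.k, so 7.49 -> 302, 7.50 -> 303, 7.53 -> 306. The logo window covers
#' reference positions 287 (7.34) through 324 (7.71) inclusive; its span is
#' reported as end - start. Highlighted positions are the retinal-binding
#' site, the NPxxY anchors and the conserved 292 (7.39) and 314 (7.64).
#'
#' @param site Reference position of the retinal-binding lysine (default
#'   296).
#' @param window Inclusive reference-position window for logos (default
#'   `287:324`).
#' @return Object of class `motif_config`.
#' @export
motif_config <- function(site = 296L, window = 287:324) {
  stopifnot(length(window) >= 2L, window[1] < window[length(window)])
  anchors <- c("7.43" = site, "7.49" = site + 6L, "7.50" = site + 7L,
               "7.53" = site + 10L)
  structure(list(site = as.integer(site),
                 anchors = anchors,
                 window = as.integer(window),
                 window_span = window[length(window)] - window[1],
                 highlighted = as.integer(c(site - 4L, site, anchors[-1],
                                            site + 18L))),
            class = "motif_config")
}

#' Residue composition of a member set at one column
#'
#' Counts every residue character over exactly `member_ids`, with the gap
#' character `'-'` as its own category (incomplete sequences).
#'
#' @param aln Alignment matrix (or named vector).
#' @param member_ids Non-empty character vector of member IDs.
#' @param column 1-based alignment column.
#' @return List with `counts` and `fractions` (named numeric vectors summing
#'   to 1 over the members).
#' @export
composition_at <- function(aln, member_ids, column) {
  if (length(member_ids) == 0L) stop("empty member set")
  m <- aln_matrix(aln)
  missing <- setdiff(member_ids, rownames(m))
  if (length(missing)) stop("unknown member IDs: ", paste(missing, collapse = ", "))
  if (column < 1L || column > ncol(m)) stop("column out of range")
  ch <- m[member_ids, column]
  counts <- table(ch)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, fractions = counts / length(member_ids))
}

#' Helix-7 motif pattern of one sequence
#'
#' Builds the 5-character pattern `residue@7.49 + residue@7.50 + "xx" +
#' residue@7.53` through the residue map; gaps render as `'-'`. The motif
#' is conserved iff the pattern equals `"NPxxY"`.
#'
#' @param aln Alignment matrix (or named vector).
#' @param seq_id Sequence ID.
#' @param rmap A [build_residue_map()] result.
#' @param mcfg A [motif_config()].
#' @return Character scalar such as `"NPxxY"` or `"PVxxY"`, with attribute
#'   `"conserved"` (logical).
#' @export
motif_string <- function(aln, seq_id, rmap, mcfg = motif_config()) {
  cols <- map_position(rmap, mcfg$anchors[c("7.49", "7.50", "7.53")])
  if (anyNA(cols)) stop("motif region trimmed: anchor residue(s) unmapped")
  ch <- vapply(cols, function(co) residue_at(aln, seq_id, co), character(1))
  pat <- paste0(ch[1], ch[2], "xx", ch[3])
  attr(pat, "conserved") <- identical(pat, "NPxxY")
  pat
}

#' Sequence-logo frequency matrix over the helix-7 window
#'
#' One row per reference position of the window, one column per character
#' (20 residues, `X`, gap); cells are frequencies over the member set and
#' each mapped row sums to 1. Positions whose residue was trimmed away are
#' emitted as all-gap rows and flagged in the `"unmapped"` attribute.
#'
#' @param aln Alignment matrix (or named vector).
#' @param member_ids Non-empty character vector of member IDs.
#' @param rmap A [build_residue_map()] result.
#' @param mcfg A [motif_config()].
#' @return Numeric matrix (positions x characters) with attribute
#'   `"unmapped"` (logical vector per row).
#' @export
logo_matrix <- function(aln, member_ids, rmap, mcfg = motif_config()) {
  if (length(member_ids) == 0L) stop("empty member set")
  m <- aln_matrix(aln)
  cols <- map_position(rmap, mcfg$window)
  if (all(is.na(cols))) stop("no window position is mapped")
  out <- matrix(0, length(mcfg$window), length(ALN_CHARS),
                dimnames = list(mcfg$window, ALN_CHARS))
  for (i in seq_along(cols)) {
    if (is.na(cols[i])) {
      out[i, "-"] <- 1
    } else {
      ch <- m[member_ids, cols[i]]
      tb <- table(factor(ch, levels = ALN_CHARS))
      out[i, ] <- as.numeric(tb) / length(member_ids)
    }
  }
  attr(out, "unmapped") <- is.na(cols)
  out
}

#' Write a logo or composition matrix as TSV
#'
#' @param mat Matrix with dimnames.
#' @param path Output TSV path.
#' @export
write_profile_tsv <- function(mat, path) {
  df <- data.frame(position = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scan a tree for clades that lost the retinal-binding lysine
#'
#' Reports every *maximal* subtree in which all members that cover the
#' mapped site column carry a non-lysine residue, provided at least
#' `min_members` such members exist. Gapped (`'-'`) and unknown (`'X'`)
#' characters at the site are non-informative: fragments neither support nor
#' veto a candidate clade. Isolated singletons are excluded by
#' `min_members` (default 2), since a single lysine-less sequence inside a
#' clade may be missequenced, misassembled, or a pseudogene.
#'
#' @param tree A rooted phylo tree whose tips are alignment rows.
#' @param aln Alignment matrix (or named vector).
#' @param rmap A [build_residue_map()] result with the site position mapped.
#' @param clades Optional [assign_clades()] result used to label candidates
#'   with the clade of their members.
#' @param min_members Minimum informative non-lysine members (default 2).
#' @param mcfg A [motif_config()].
#' @return Data frame, one row per candidate clade: `node`, `clade_name`,
#'   `n_members`, `n_full_length`, `n_with_replacement`,
#'   `consensus_residue`, `members` (comma-joined), `residues`
#'   (comma-joined, aligned with `members`). Zero rows when nothing
#'   qualifies.
#' @export
scan_lysine_loss <- function(tree, aln, rmap, clades = NULL, min_members = 2L,
                             mcfg = motif_config()) {
  col <- map_position(rmap, mcfg$site)
  if (is.na(col)) stop("site position is not mapped in this alignment")
  m <- aln_matrix(aln)
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(m))
  if (length(missing)) stop("tree tips absent from alignment: ",
                            paste(missing, collapse = ", "))
  ch <- m[tips, col]
  informative <- !(ch %in% c("-", "X"))
  isK <- informative & ch == "K"
  nonK <- informative & ch != "K"

  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  nK <- integer(nt + nn); nR <- integer(nt + nn)
  nK[seq_len(nt)] <- as.integer(isK)
  nR[seq_len(nt)] <- as.integer(nonK)
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    nK[eo[k, 1]] <- nK[eo[k, 1]] + nK[eo[k, 2]]
    nR[eo[k, 1]] <- nR[eo[k, 1]] + nR[eo[k, 2]]
  }
  par <- parent_vec(tree)
  cand <- which(nK == 0L & nR >= min_members &
                  (par == 0L | nK[ifelse(par == 0L, 1L, par)] > 0L))
  if (length(cand) == 0L) {
    return(data.frame(node = integer(), clade_name = character(),
                      n_members = integer(), n_full_length = integer(),
                      n_with_replacement = integer(),
                      consensus_residue = character(), members = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  clade_of <- NULL
  if (!is.null(clades)) {
    clade_of <- unlist(unname(lapply(clades$clades, function(cl)
      setNames(rep(cl$name, length(cl$members)), cl$members))))
  }
  rows <- lapply(cand, function(nd) {
    mem <- tips_under(tree, nd)
    res <- m[mem, col]
    inf <- !(res %in% c("-", "X"))
    tb <- sort(table(res[inf]), decreasing = TRUE)
    cons <- names(tb)[order(-tb, names(tb))][1]   # ties: lexicographic
    nm <- if (is.null(clade_of)) NA_character_ else {
      hits <- unique(clade_of[mem]); hits <- hits[!is.na(hits)]
      if (length(hits)) paste(hits, collapse = "+") else "outgroup"
    }
    data.frame(node = nd, clade_name = nm, n_members = length(mem),
               n_full_length = sum(inf),
               n_with_replacement = sum(res[inf] == cons),
               consensus_residue = cons,
               members = paste(mem, collapse = ","),
               residues = paste(res, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
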