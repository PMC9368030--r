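## Alignment and sequence handling: FASTA I/O, exact-duplicate removal,
## gap-column trimming with column provenance, and mapping of reference
## residue positions (bovine rhodopsin numbering) into trimmed alignments.
##
## Sequence sets are named character vectors (names = unique IDs, values =
## upper-case residue strings over the 20 amino acids, 'X' and '-').
## Alignments are character matrices (one row per sequence, one column per
## alignment column, rownames = IDs). All column indices are 1-based, both
## internally and in every file or report; reference residue positions are
## 1-based throughout (so the retinal-binding lysine of bovine rhodopsin is
## position 296).

#' Read protein sequences from a FASTA file
#'
#' IDs are the first whitespace-delimited token of each header; the remainder
#' of the header line is preserved in the `"desc"` attribute. Sequences are
#' upper-cased and `'.'` gap characters are normalized to `'-'`.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of sequences; names are IDs.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr(".", "-", toupper(as.character(x)))
  names(seqs) <- ids
  attr(seqs, "desc") <- setNames(desc, ids)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  desc <- attr(seqs, "desc")
  nm <- names(seqs)
  if (!is.null(desc)) {
    has <- nzchar(desc[nm]) & !is.na(desc[nm])
    nm[has] <- paste(nm[has], desc[nm][has])
  }
  x <- Biostrings::AAStringSet(setNames(as.character(seqs), nm))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Remove exact duplicate sequences
#'
#' Keeps, for each distinct sequence string, the first-occurring record;
#' all later records with an identical string are dropped. Input order is
#' otherwise preserved.
#'
#' @param seqs Named character vector of sequences.
#' @return List with `records` (deduplicated named vector) and `dropped`
#'   (character vector of dropped IDs, possibly empty).
#' @export
dedup_exact <- function(seqs) {
  if (length(seqs) == 0L) {
    return(list(records = seqs, dropped = character()))
  }
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  dup <- duplicated(unname(seqs))
  list(records = seqs[!dup], dropped = names(seqs)[dup])
}

#' Convert a sequence set to an alignment matrix
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Character matrix with rownames = IDs.
#' @export
aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have unequal lengths; not an alignment")
  if (L < 1L) stop("empty sequences")
  m <- matrix(unlist(strsplit(unname(seqs), ""), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

#' Convert an alignment matrix back to a named sequence vector
#'
#' @param m Character matrix with rownames.
#' @return Named character vector.
#' @export
aln_records <- function(m) {
  if (!is.matrix(m)) return(m)
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Trim gap-rich alignment columns
#'
#' Removes every column whose gap fraction is strictly greater than
#' `max_gap_fraction` (a column at exactly the threshold is kept). Row count
#' and row order are unchanged.
#'
#' @param aln Alignment matrix (or named vector of aligned sequences).
#' @param max_gap_fraction Maximum tolerated gap fraction, default 0.9.
#' @return List with `alignment` (trimmed matrix), `kept_columns` (strictly
#'   increasing 1-based original column indices) and `gap_fraction` (per
#'   original column).
#' @export
trim_gap_columns <- function(aln, max_gap_fraction = 0.9) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- aln_matrix(aln)
  gf <- colMeans(m == "-")
  keep <- which(gf <= max_gap_fraction)
  if (length(keep) == 0L) stop("empty alignment after trimming")
  list(alignment = m[, keep, drop = FALSE],
       kept_columns = keep,
       gap_fraction = unname(gf))
}

#' Write a column-trimming audit table
#'
#' One row per original column: `original_column` (1-based), `kept`
#' (TRUE/FALSE) and `gap_fraction`.
#'
#' @param trim Result of [trim_gap_columns()].
#' @param path Output TSV path.
#' @export
write_trim_audit <- function(trim, path) {
  n <- length(trim$gap_fraction)
  df <- data.frame(original_column = seq_len(n),
                   kept = seq_len(n) %in% trim$kept_columns,
                   gap_fraction = trim$gap_fraction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map reference residue positions to alignment columns
#'
#' Builds the mapping from 1-based residue positions of an untrimmed
#' reference sequence (the bovine rhodopsin role) to columns of a trimmed
#' alignment. Positions whose residue was removed by column trimming map to
#' `NA` (unmapped).
#'
#' Two routes are available. If both `kept_columns` (from
#' [trim_gap_columns()]) and `ref_row_full` (the reference row of the
#' *untrimmed* alignment) are supplied, the mapping is exact: the untrimmed
#' reference row is walked to pair each ungapped residue with its original
#' column, which is then translated through `kept_columns`. Otherwise a
#' fallback subsequence alignment is used: the degapped trimmed reference row
#' is embedded left-most into `ref_seq_full` (trimming can only delete
#' reference residues, never substitute them, so mismatches are forbidden).
#'
#' @param aln_trimmed Trimmed alignment matrix (or named vector).
#' @param ref_id ID of the reference sequence, present in `aln_trimmed`.
#' @param ref_seq_full Untrimmed, ungapped reference sequence string.
#' @param kept_columns Optional 1-based original column indices kept by
#'   trimming (for the exact route).
#' @param ref_row_full Optional reference row of the untrimmed alignment
#'   (with gaps), required for the exact route.
#' @return Object of class `residue_map`: list with `ref_id`, `ref_seq_full`,
#'   `pos_to_column` (integer vector, one entry per reference position, `NA`
#'   where unmapped) and `anchor_note` (records that reference position 296
#'   carries Ballesteros-Weinstein label 7.43).
#' @export
build_residue_map <- function(aln_trimmed, ref_id, ref_seq_full,
                              kept_columns = NULL, ref_row_full = NULL) {
  m <- aln_matrix(aln_trimmed)
  if (!ref_id %in% rownames(m)) stop("reference ID not in alignment: ", ref_id)
  ref_seq_full <- toupper(ref_seq_full)
  refchars <- strsplit(ref_seq_full, "")[[1]]
  np <- length(refchars)
  row <- m[ref_id, ]
  pos_to_column <- rep(NA_integer_, np)

  if (!is.null(kept_columns) && !is.null(ref_row_full)) {
    ## Exact provenance: walk the untrimmed reference row.
    full <- strsplit(chartr(".", "-", toupper(ref_row_full)), "")[[1]]
    res_cols <- which(full != "-")           # original column of residue i
    if (length(res_cols) != np ||
        !identical(full[res_cols], refchars)) {
      stop("reference mismatch: untrimmed reference row does not spell ",
           "ref_seq_full")
    }
    trans <- match(res_cols, kept_columns)   # original column -> trimmed column
    pos_to_column <- as.integer(trans)
  } else {
    ## Fallback: left-most embedding of the degapped trimmed row into the
    ## full reference (no mismatches allowed).
    nz <- which(row != "-")
    tchars <- row[nz]
    p <- 1L
    for (j in seq_along(tchars)) {
      while (p <= np && refchars[p] != tchars[j]) p <- p + 1L
      if (p > np) stop("reference mismatch: trimmed reference row is not a ",
                       "subsequence of ref_seq_full")
      pos_to_column[p] <- nz[j]
      p <- p + 1L
    }
  }

  ## Invariant: a mapped column's reference-row character equals the
  ## reference residue at that position.
  ok <- !is.na(pos_to_column)
  if (any(ok) && !identical(unname(row[pos_to_column[ok]]), refchars[ok])) {
    stop("reference mismatch: mapped columns do not spell the reference")
  }
  if (any(ok) && is.unsorted(pos_to_column[ok], strictly = TRUE)) {
    stop("internal error: mapped columns not strictly increasing")
  }
  structure(list(ref_id = ref_id,
                 ref_seq_full = ref_seq_full,
                 pos_to_column = pos_to_column,
                 anchor_note = "reference position 296 = Ballesteros-Weinstein 7.43"),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  n <- length(x$pos_to_column)
  cat("<residue_map> reference", x$ref_id, "with", n, "positions;",
      sum(!is.na(x$pos_to_column)), "mapped\n")
  cat(" ", x$anchor_note, "\n")
  invisible(x)
}

#' Column of a reference residue position
#'
#' @param rmap A [build_residue_map()] result.
#' @param position 1-based reference residue position(s).
#' @return Integer column index (`NA` if the residue was trimmed away).
#' @export
map_position <- function(rmap, position) {
  stopifnot(inherits(rmap, "residue_map"))
  if (any(position < 1L | position > length(rmap$pos_to_column))) {
    stop("reference position out of range")
  }
  rmap$pos_to_column[position]
}

#' Residue of one sequence at one alignment column
#'
#' @param aln Alignment matrix (or named vector).
#' @param seq_id Sequence ID.
#' @param column 1-based column index.
#' @return Single character; `'-'` when gapped.
#' @export
residue_at <- function(aln, seq_id, column) {
  m <- aln_matrix(aln)
  if (!seq_id %in% rownames(m)) stop("unknown sequence ID: ", seq_id)
  if (length(column) != 1L || is.na(column) ||
      column < 1L || column > ncol(m)) {
    stop("column out of range: ", column)
  }
  unname(m[seq_id, column])
}
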