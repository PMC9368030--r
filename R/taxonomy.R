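## Genus-string taxonomy annotation. Sequence IDs are tokenized and matched
## against a genus index built either from the NCBI taxdump dialect
## (names.dmp / nodes.dmp, fields separated by "\t|\t") or from a simple
## two-column genus -> higher-taxon TSV. Matching is by whole token, not raw
## substring, to avoid false hits inside accession strings.

#' Load a genus taxonomy index
#'
#' Accepts either a two-column TSV (`genus<TAB>higher_taxon`, no header) or
#' the NCBI taxdump dialect: supply `nodes` alongside `source` =
#' `names.dmp`, where rows are `tax_id\t|\tname\t|\t...` and
#' `tax_id\t|\tparent_id\t|\trank\t|...` respectively. Every node of rank
#' `genus` is indexed with its lineage of scientific names, ordered from the
#' immediate parent upward.
#'
#' @param source TSV path, or `names.dmp` path when `nodes` is given.
#' @param nodes Optional `nodes.dmp` path (taxdump dialect).
#' @param interest Optional ordered character vector of higher taxa of
#'   interest; [assign_taxon()] reports the first lineage member on this
#'   list.
#' @return Object of class `taxonomy_index`: list with `genera` (named list
#'   genus -> lineage character vector) and `interest`.
#' @export
load_taxonomy <- function(source, nodes = NULL, interest = NULL) {
  if (is.null(nodes)) {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty taxonomy file: ", source)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 2L)
    if (length(bad)) stop("malformed taxonomy row at line ", bad[1])
    genera <- lapply(parts, function(p) p[-1])
    names(genera) <- vapply(parts, `[[`, character(1), 1L)
  } else {
    nm <- read_dmp(source, c("tax_id", "name", "unique_name", "name_class"))
    nd <- read_dmp(nodes, c("tax_id", "parent_id", "rank"))
    sci <- nm[nm$name_class == "scientific name" | is.na(nm$name_class), ]
    name_of <- setNames(sci$name, sci$tax_id)
    parent_of <- setNames(nd$parent_id, nd$tax_id)
    rank_of <- setNames(nd$rank, nd$tax_id)
    gids <- nd$tax_id[nd$rank == "genus"]
    if (length(gids) == 0L) stop("no genus-rank nodes in ", nodes)
    genera <- lapply(gids, function(id) {
      lin <- character()
      cur <- parent_of[[id]]
      for (step in 1:100) {                 # guard against cycles
        if (is.null(name_of[[cur]]) || is.na(name_of[[cur]])) break
        if (!identical(rank_of[[cur]], "no rank")) {
          lin <- c(lin, name_of[[cur]])
        }
        nxt <- parent_of[[cur]]
        if (is.null(nxt) || identical(nxt, cur)) break
        cur <- nxt
      }
      lin
    })
    names(genera) <- name_of[gids]
  }
  if (anyDuplicated(names(genera))) {
    genera <- genera[!duplicated(names(genera))]
  }
  structure(list(genera = genera, interest = interest),
            class = "taxonomy_index")
}

read_dmp <- function(path, cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty taxdump file: ", path)
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t|\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stop("malformed taxdump row at line ", bad[1], " of ", path)
  df <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- length(cols)
    p
  })), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Assign a higher taxon to sequence IDs by genus token
#'
#' IDs are split on non-alphanumeric separators; tokens are matched
#' (case-preserving) against the genus index. On a match the first lineage
#' member present on the interest list is returned (the immediate higher
#' taxon when no interest list is configured); when several distinct genus
#' tokens match, the longest token wins, then the lexicographically
#' smallest. IDs with no genus token yield `"unidentified"` — never an
#' error.
#'
#' @param seq_ids Character vector of sequence IDs.
#' @param idx A [load_taxonomy()] index.
#' @return Character vector of higher-taxon names (or `"unidentified"`).
#' @export
assign_taxon <- function(seq_ids, idx) {
  stopifnot(inherits(idx, "taxonomy_index"))
  vapply(seq_ids, function(id) {
    toks <- strsplit(id, "[^A-Za-z0-9]+")[[1]]
    toks <- unique(toks[toks %in% names(idx$genera)])
    if (length(toks) == 0L) return("unidentified")
    toks <- toks[order(-nchar(toks), toks)]
    lin <- idx$genera[[toks[1]]]
    if (is.null(idx$interest)) {
      if (length(lin)) lin[1] else "unidentified"
    } else {
      hit <- lin[lin %in% idx$interest]
      if (length(hit)) hit[1] else "unidentified"
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Higher-taxon composition of a member set
#'
#' @param member_ids Non-empty character vector of sequence IDs.
#' @param idx A [load_taxonomy()] index.
#' @return Named numeric vector of fractions (including `"unidentified"`),
#'   summing to 1.
#' @export
taxon_composition <- function(member_ids, idx) {
  if (length(member_ids) == 0L) stop("empty member set")
  tx <- assign_taxon(member_ids, idx)
  tb <- table(tx)
  setNames(as.numeric(tb), names(tb)) / length(member_ids)
}

#' Write per-leaf taxonomy annotation as TSV
#'
#' Columns: `leaf_id`, `higher_taxon`.
#'
#' @param seq_ids Character vector of IDs.
#' @param idx A [load_taxonomy()] index.
#' @param path Output TSV path.
#' @export
write_taxon_annotation <- function(seq_ids, idx, path) {
  df <- data.frame(leaf_id = seq_ids, higher_taxon = assign_taxon(seq_ids, idx))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
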