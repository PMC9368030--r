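## Pipeline assembly: rooting and clade annotation of a master tree from a
## clade-definition table, per-clade summary records (the data behind
## collapsed-tree pie charts: residue composition at the mapped site, taxon
## composition, support-triple pass flags), and the end-to-end run:
## dedup -> bait filter -> add-back -> iterative pruning -> gap trimming ->
## residue mapping -> clade assignment -> lysine-loss scan -> summaries.

#' Root and annotate a master tree from clade definitions
#'
#' Implements the descendant-counting annotation flow: the tree is rooted at
#' the outgroup anchor leaf (the definition row named `"outgroup"`,
#' conventionally last), the MRCA of all clade defining leaves (the ingroup)
#' is found and the tree rerooted on the edge above it, and every clade is
#' assigned as the maximal subtree containing its defining leaf and no
#' other.
#'
#' @param tree A phylo tree.
#' @param defs Clade definition table (`name`, `color`, `sequence_id`); a
#'   row named `"outgroup"` is the anchor, not a clade.
#' @param substitutes Optional named list of fallback defining leaves per
#'   clade (see [assign_clades()]).
#' @param outgroup_substitute_pattern Optional ID substring used to pick a
#'   replacement anchor leaf when the configured one is absent.
#' @return List with `tree` (rerooted), `assignment`
#'   (a [assign_clades()] result) and `defs` (clade rows actually used).
#' @export
annotate_tree <- function(tree, defs, substitutes = NULL,
                          outgroup_substitute_pattern = NULL) {
  is_out <- defs$name == "outgroup"
  anchor <- if (any(is_out)) defs$sequence_id[which(is_out)[1]] else NULL
  cdefs <- defs[!is_out, , drop = FALSE]
  if (nrow(cdefs) == 0L) stop("no clade rows in the definition table")

  if (!is.null(anchor)) {
    if (!anchor %in% tree$tip.label && !is.null(outgroup_substitute_pattern)) {
      hit <- grep(outgroup_substitute_pattern, tree$tip.label,
                  fixed = TRUE, value = TRUE)
      if (length(hit)) anchor <- hit[1]
    }
    if (anchor %in% tree$tip.label) {
      tree <- reroot_at_leaf(tree, anchor)
    } else {
      warning("outgroup anchor absent from tree; keeping current rooting")
    }
  }

  ## resolve defining leaves (with substitutes), dropping absent clades
  present <- logical(nrow(cdefs))
  for (i in seq_len(nrow(cdefs))) {
    cand <- c(cdefs$sequence_id[i], substitutes[[cdefs$name[i]]])
    hit <- cand[cand %in% tree$tip.label]
    if (length(hit)) {
      cdefs$sequence_id[i] <- hit[1]
      present[i] <- TRUE
    } else {
      warning("dropping clade ", cdefs$name[i],
              ": defining leaf absent and no substitute present")
    }
  }
  cdefs <- cdefs[present, , drop = FALSE]
  if (nrow(cdefs) == 0L) stop("no defining leaf present in the tree")

  ing <- mrca_leaves(tree, cdefs$sequence_id)
  if (ing > ape::Ntip(tree) && ing != root_node(tree)) {
    tree <- reroot_at_node(tree, ing)
  }
  list(tree = tree, assignment = assign_clades(tree, cdefs), defs = cdefs)
}

frac_string <- function(fr) {
  fr <- fr[order(-fr, names(fr))]
  paste(sprintf("%s:%.4g", names(fr), fr), collapse = ",")
}

#' Per-clade summary records
#'
#' One record per clade plus one residual outgroup record: leaf count,
#' residue composition at the mapped site column, taxon composition, and
#' the clade root's support triple with per-component pass flags under the
#' given policy. This is the machine-readable form of a collapsed annotated
#' tree.
#'
#' @param tree A rooted, annotated phylo tree (see [annotate_tree()]).
#' @param asn A [assign_clades()] result for `tree`.
#' @param aln Alignment matrix (or named vector) covering the tree's tips.
#' @param rmap A [build_residue_map()] result with the site mapped.
#' @param taxonomy_idx Optional [load_taxonomy()] index.
#' @param policy A [support_policy()].
#' @param mcfg A [motif_config()].
#' @return Data frame ordered by clade root position in the tree, with an
#'   `"outgroup"` row last.
#' @export
clade_summary <- function(tree, asn, aln, rmap, taxonomy_idx = NULL,
                          policy = support_policy(), mcfg = motif_config()) {
  col <- map_position(rmap, mcfg$site)
  if (is.na(col)) stop("site position is not mapped")
  sup <- support_triples(tree)
  nt <- ape::Ntip(tree)

  one <- function(name, members, root) {
    comp <- composition_at(aln, members, col)$fractions
    tax <- if (is.null(taxonomy_idx)) NULL else
      taxon_composition(members, taxonomy_idx)
    s <- if (!is.null(root) && root > nt) {
      as.numeric(sup[root - nt, ])
    } else {
      c(NA_real_, NA_real_, NA_real_)
    }
    data.frame(
      clade = name, n_leaves = length(members),
      residue_composition = frac_string(comp),
      frac_site_K = if (is.na(comp["K"])) 0 else unname(comp["K"]),
      taxon_composition = if (is.null(tax)) NA_character_ else
        frac_string(tax),
      sh_alrt = s[1], abayes = s[2], ufboot = s[3],
      pass_sh = !is.na(s[1]) & s[1] >= policy$accept_sh,
      pass_abayes = !is.na(s[2]) & s[2] >= policy$accept_abayes,
      pass_ufboot = !is.na(s[3]) & s[3] >= policy$accept_ufboot,
      status = branch_status(s, policy),
      stringsAsFactors = FALSE)
  }

  ord <- order(vapply(asn$clades, `[[`, integer(1), "root"))
  rows <- lapply(asn$clades[ord], function(cl) one(cl$name, cl$members,
                                                  cl$root))
  if (length(asn$outgroup)) {
    rows <- c(rows, list(one("outgroup", asn$outgroup, NULL)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfgfile <- config
    config <- yaml::read_yaml(config)
    config$.file <- cfgfile
  }
  stopifnot(is.list(config))
  config
}

#' Run the full pipeline from a configuration
#'
#' Executes dedup -> bait filter -> add-back -> iterative pruning -> gap
#' trimming -> residue mapping -> tree building -> clade assignment ->
#' lysine-loss scan -> summaries, writing every intermediate artifact plus a
#' run log (seed, config checksum, package versions, stage boundaries,
#' removal counts) into the output directory. With `resume: true`, stages
#' whose artifact already exists are reloaded instead of recomputed. All
#' inputs are validated before any stage runs.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#'   Required keys: `pool_fasta`, `baits_fasta`, `anchor_fasta`,
#'   `clade_definitions`, `reference_id`, `out_dir`. Optional keys:
#'   `taxonomy_tsv`, `interest_taxa`, `seed`, `subset_size`,
#'   `add_back_random`, `keep_patterns`, `bootstrap_replicates`,
#'   `n_iterations`, `full_from_iteration`, `max_drop_per_round`,
#'   `long_branch_factor`, `max_gap_fraction`, `min_members`,
#'   `outgroup_substitute_pattern`, `skip_filter`, `resume`.
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (named file paths), and the key in-memory results (`survivors`,
#'   `candidates`, `summary`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  need <- c("pool_fasta", "baits_fasta", "anchor_fasta", "clade_definitions",
            "reference_id", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing required keys: ",
                         paste(miss, collapse = ", "))
  infiles <- unlist(cfg[c("pool_fasta", "baits_fasta", "anchor_fasta",
                          "clade_definitions", "taxonomy_tsv")])
  absent <- infiles[!file.exists(infiles)]
  if (length(absent)) stop("input file(s) not found: ",
                           paste(absent, collapse = ", "))

  seed <- as.integer(cfg$seed %||% 1L)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  resume <- isTRUE(cfg$resume)
  art <- function(f) file.path(out, f)
  logfile <- art("run_log.txt")
  logit <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
        file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  logit("pipeline start; seed =", seed,
        "; opsinpipe", as.character(utils::packageVersion("opsinpipe")),
        "; R", paste(R.version$major, R.version$minor, sep = "."))
  if (!is.null(cfg$.file)) {
    logit("config:", cfg$.file, "md5 =", unname(tools::md5sum(cfg$.file)))
  }

  pool <- read_fasta(cfg$pool_fasta)
  baits <- read_fasta(cfg$baits_fasta)
  anchor <- read_fasta(cfg$anchor_fasta)[1]
  defs <- read_clade_definitions(cfg$clade_definitions)
  ref_id <- cfg$reference_id
  if (!ref_id %in% names(pool)) stop("reference_id not in pool: ", ref_id)

  ## stage: dedup
  dd <- dedup_exact(pool)
  pool <- dd$records
  writeLines(dd$dropped, art("duplicates_removed.txt"))
  logit("dedup:", length(dd$dropped), "duplicates removed;",
        length(pool), "sequences remain")

  fcfg <- filter_config(
    subset_size = cfg$subset_size %||% 900L,
    add_back_random = cfg$add_back_random %||% 1000L,
    keep_patterns = unlist(cfg$keep_patterns) %||% character(),
    seed = seed)

  ## stage: bait filter
  if (isTRUE(cfg$skip_filter)) {
    retained <- names(pool)
    logit("bait filter skipped by config")
  } else if (resume && file.exists(art("retained.txt"))) {
    retained <- readLines(art("retained.txt"))
    logit("bait filter resumed from artifact:", length(retained), "retained")
  } else {
    bf <- bait_filter(pool, baits, anchor, cfg = fcfg)
    retained <- bf$retained
    writeLines(retained, art("retained.txt"))
    write_filter_report(bf$report, art("filter_report.tsv"))
    logit("bait filter:", length(retained), "retained over",
          nrow(bf$report), "subset(s);", sum(bf$report$failed),
          "subset extraction failure(s)")
  }

  ## stage: add-back (outgroup sample + keep patterns + the reference)
  dataset <- add_back(retained, names(pool), fcfg)
  dataset <- union(dataset, ref_id)
  writeLines(dataset, art("dataset.txt"))
  logit("add-back: dataset of", length(dataset), "sequences")

  ## stage: iterative rogue / long-branch pruning
  pcfg <- prune_config(
    subset_size = cfg$subset_size %||% 900L,
    n_iterations = cfg$n_iterations %||% 20L,
    full_from_iteration = cfg$full_from_iteration %||% 10L,
    bootstrap_replicates = cfg$bootstrap_replicates %||% 100L,
    max_drop_per_round = cfg$max_drop_per_round %||% 10L,
    long_branch_factor = cfg$long_branch_factor %||% 10,
    seed = seed)
  if (resume && file.exists(art("survivors.txt"))) {
    survivors <- readLines(art("survivors.txt"))
    logit("pruning resumed from artifact:", length(survivors), "survivors")
  } else {
    pr <- iterative_prune(pool[dataset], cfg = pcfg)
    survivors <- pr$survivors
    if (!ref_id %in% survivors) {
      logit("note: reference was pruned; re-adding for residue mapping")
      survivors <- c(survivors, ref_id)
    }
    writeLines(survivors, art("survivors.txt"))
    write_prune_audit(pr$audit, art("prune_audit.tsv"))
    logit("pruning:", nrow(pr$audit), "removals over", pcfg$n_iterations,
          "iterations;", length(survivors), "survivors")
  }

  ## stage: gap-column trimming
  aln <- aln_matrix(pool[survivors])
  trim <- trim_gap_columns(aln, cfg$max_gap_fraction %||% 0.9)
  write_fasta(aln_records(trim$alignment), art("trimmed.fasta"))
  write_trim_audit(trim, art("trim_audit.tsv"))
  logit("trimming:", ncol(aln) - length(trim$kept_columns),
        "columns removed,", length(trim$kept_columns), "kept")

  ## stage: residue map (reference position -> trimmed column)
  ref_row <- pool[[ref_id]]
  rmap <- build_residue_map(trim$alignment, ref_id,
                            gsub("-", "", ref_row, fixed = TRUE),
                            kept_columns = trim$kept_columns,
                            ref_row_full = ref_row)
  write.table(
    data.frame(reference_position = seq_along(rmap$pos_to_column),
               trimmed_column = rmap$pos_to_column),
    art("residue_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  mcfg <- motif_config()
  sitecol <- map_position(rmap, mcfg$site)
  logit("residue map: site position", mcfg$site, "->",
        if (is.na(sitecol)) "UNMAPPED" else paste("column", sitecol))

  ## stage: master tree of the survivors
  tree <- nj_tree(pdistance_matrix(trim$alignment))
  ape::write.tree(tree, art("final_tree.nwk"))
  logit("tree:", ape::Ntip(tree), "leaves")

  ## stage: clade assignment
  ann <- annotate_tree(tree, defs,
                       outgroup_substitute_pattern =
                         cfg$outgroup_substitute_pattern)
  write_clade_assignment(ann$assignment, art("clade_assignment.tsv"))
  ape::write.tree(ann$tree, art("annotated_tree.nwk"))
  logit("clades:", length(ann$assignment$clades), "assigned;",
        length(ann$assignment$outgroup), "outgroup leaves")

  ## stage: lysine-loss scan
  cands <- scan_lysine_loss(ann$tree, trim$alignment, rmap,
                            clades = ann$assignment,
                            min_members = cfg$min_members %||% 2L,
                            mcfg = mcfg)
  write.table(cands, art("lysine_loss_candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logit("lysine-loss scan:", nrow(cands), "candidate clade(s)")

  ## stage: taxonomy + summaries
  idx <- NULL
  if (!is.null(cfg$taxonomy_tsv)) {
    idx <- load_taxonomy(cfg$taxonomy_tsv,
                         interest = unlist(cfg$interest_taxa))
    write_taxon_annotation(ann$tree$tip.label, idx, art("taxon_annotation.tsv"))
  }
  summ <- clade_summary(ann$tree, ann$assignment, trim$alignment, rmap,
                        taxonomy_idx = idx, mcfg = mcfg)
  write.table(summ, art("clade_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dir.create(art("logos"), showWarnings = FALSE)
  for (cl in ann$assignment$clades) {
    lm <- logo_matrix(trim$alignment, cl$members, rmap, mcfg)
    write_profile_tsv(lm, art(file.path("logos", paste0(cl$name, ".tsv"))))
  }
  logit("pipeline done")

  invisible(list(status = 0L,
                 artifacts = setNames(
                   file.path(out, c("retained.txt", "dataset.txt",
                                    "survivors.txt", "trimmed.fasta",
                                    "residue_map.tsv", "final_tree.nwk",
                                    "clade_assignment.tsv",
                                    "lysine_loss_candidates.tsv",
                                    "clade_summary.tsv", "run_log.txt")),
                   c("retained", "dataset", "survivors", "trimmed",
                     "residue_map", "tree", "clades", "candidates",
                     "summary", "log")),
                 survivors = survivors, candidates = cands, summary = summ,
                 rmap = rmap, tree = ann$tree,
                 assignment = ann$assignment))
}
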