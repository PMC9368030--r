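## Deterministic generator of clade-structured protein families with a
## planted lysine-loss clade (glutamic acid at the 296-analog site), an
## arginine clade, clade-specific helix-7 motif variants, unstable chimeric
## rogues, long-branch sequences, fragments lacking the site, and unrelated
## decoys. Sequences are emitted pre-aligned (gapless except fragment
## tails), so the site column equals the reference position and every
## downstream stage has exact ground truth.

#' Default clade table for the synthetic generator
#'
#' Emulates the statistical structure of a chromopsin-bearing opsin family:
#' several lysine (K) clades with conserved or derived motifs, one planted
#' glutamic-acid (E) clade with a PVxxY motif, and one small arginine (R)
#' clade.
#'
#' @return Data frame with columns `name`, `size`, `site_residue`, `motif`,
#'   `taxon`, `genus`.
#' @export
sim_clades_default <- function() {
  data.frame(
    name = c("cilopsin", "rhabopsin", "peropsin", "rgropsin",
             "retinochrome", "gluopsin", "nemopsin"),
    size = c(60L, 60L, 40L, 35L, 30L, 12L, 5L),
    site_residue = c("K", "K", "K", "K", "K", "E", "R"),
    motif = c("NPxxY", "NPxxY", "NPxxY", "NAxxY", "VPxxY", "PVxxY", "NPxxY"),
    taxon = c("Chordata", "Arthropoda", "Chordata", "Chordata",
              "Mollusca", "Arthropoda", "Nematoda"),
    genus = c("Danio", "Drosophila", "Homo", "Gallus",
              "Todarodes", "Sympetrum", "Caenorhabditis"),
    stringsAsFactors = FALSE)
}

#' Synthetic family configuration
#'
#' @param clades Clade table as in [sim_clades_default()].
#' @param seq_length Alignment length (default 350, so the site analog sits
#'   at reference position 296 like the bovine rhodopsin lysine).
#' @param sub_prob Per-branch, per-site substitution probability within
#'   clades (default 0.05).
#' @param backbone_sub_prob Per-branch substitution probability on the
#'   between-clade backbone (default 0.15).
#' @param n_rogues Number of planted 50/50 chimeric rogues (default 3).
#' @param n_long_branches Number of planted long-branch sequences
#'   (default 1).
#' @param n_fragments Fragments with terminal gap runs covering the site,
#'   planted in the first non-K clade (default 2).
#' @param n_decoys Unrelated i.i.d.-uniform decoy sequences (default 40).
#' @param seed Integer seed; everything is deterministic under it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(clades = sim_clades_default(), seq_length = 350L,
                       sub_prob = 0.05, backbone_sub_prob = 0.15,
                       n_rogues = 3L, n_long_branches = 1L,
                       n_fragments = 2L, n_decoys = 40L, seed = 1L) {
  stopifnot(nrow(clades) >= 1L, all(clades$size >= 1L),
            sub_prob >= 0, sub_prob <= 1, seq_length >= 330L,
            sum(clades$size) >= 4L)
  target <- which(clades$site_residue != "K")[1]
  if (is.na(target)) target <- 1L
  if (n_fragments > clades$size[target]) {
    stop("fragment count exceeds the size of the target clade")
  }
  structure(list(clades = clades, seq_length = as.integer(seq_length),
                 sub_prob = sub_prob, backbone_sub_prob = backbone_sub_prob,
                 n_rogues = as.integer(n_rogues),
                 n_long_branches = as.integer(n_long_branches),
                 n_fragments = as.integer(n_fragments),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 target_clade = target),
            class = "sim_config")
}

## Evolve a clade along a balanced random topology: labels are shuffled,
## the set is split into halves recursively, and every edge applies one
## round of substitutions. Shallow balanced trees keep every internal edge
## strongly marked relative to homoplasy, so simulated clade members are
## stable under resampling.
evolve_balanced <- function(ids, root_seq, prob, frozen, bl) {
  env <- new.env(parent = emptyenv())
  rec <- function(v, seq_here) {
    if (length(v) == 1L) {
      assign(v, seq_here, envir = env)
      return(sprintf("%s:%g", v, bl))
    }
    h <- length(v) %/% 2L
    left <- rec(v[seq_len(h)], mutate_seq(seq_here, prob, frozen))
    right <- rec(v[(h + 1L):length(v)], mutate_seq(seq_here, prob, frozen))
    sprintf("(%s,%s):%g", left, right, bl)
  }
  nwk <- rec(sample(ids), root_seq)
  list(newick = nwk, seqs = mget(ids, envir = env))
}

mutate_seq <- function(chars, prob, frozen = integer()) {
  hit <- which(runif(length(chars)) < prob)
  hit <- setdiff(hit, frozen)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

apply_clade_state <- function(chars, site, anchors, site_residue, motif) {
  chars[site] <- site_residue
  chars[anchors] <- strsplit(motif, "")[[1]][c(1L, 2L, 5L)]
  chars
}

#' Simulate a clade-structured protein family
#'
#' Builds a random clade backbone and within-clade topologies, evolves a
#' root consensus along the branches at the configured substitution
#' probabilities (the site column and the three motif anchor columns are
#' frozen to each clade's specification, so downstream recovery tests have
#' exact ground truth), then plants rogues, long branches, fragments and
#' decoys. Fully deterministic under the configured seed.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_bundle`: list with `tree` (true phylo over
#'   members, rogues and long branches), `records` (named character vector,
#'   the aligned family incl. reference and decoys), `truth` (data frame:
#'   `id`, `clade`, `role`, `site_residue`, `motif`, `taxon`, `genus`),
#'   `site_position` (296), `anchor_positions`, `ref_id`, `clade_defs`
#'   (clade definition table with an outgroup anchor as last row),
#'   `taxonomy` (genus -> taxon table) and `config`.
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  site <- 296L
  anchors <- c(302L, 303L, 306L)
  frozen <- c(site, anchors)
  L <- cfg$seq_length
  cl <- cfg$clades
  k <- nrow(cl)

  withr::with_seed(cfg$seed, {
    root_cons <- sample(AA20, L, replace = TRUE)
    root_cons <- apply_clade_state(root_cons, site, anchors, "K", "NPxxY")

    ## clade consensuses evolve along a random backbone
    cons <- vector("list", k)
    names(cons) <- cl$name
    if (k == 1L) {
      cons[[1]] <- root_cons
      backbone <- NULL
    } else {
      backbone <- ape::rtree(k, tip.label = paste0("CLADETIP", seq_len(k)))
      backbone$edge.length <- rep(cfg$backbone_sub_prob, nrow(backbone$edge))
      nseq <- vector("list", k + backbone$Nnode)
      nseq[[k + 1L]] <- root_cons
      pre <- ape::reorder.phylo(backbone, "cladewise")$edge
      for (e in seq_len(nrow(pre))) {
        nseq[[pre[e, 2]]] <- mutate_seq(nseq[[pre[e, 1]]],
                                        cfg$backbone_sub_prob, frozen)
      }
      ord <- as.integer(sub("CLADETIP", "", backbone$tip.label))
      for (i in seq_len(k)) cons[[ord[i]]] <- nseq[[i]]
    }
    for (i in seq_len(k)) {
      cons[[i]] <- apply_clade_state(cons[[i]], site, anchors,
                                     cl$site_residue[i], cl$motif[i])
    }

    ## within-clade topologies and sequences
    member_ids <- vector("list", k)
    seqs <- list()
    clade_nwk <- character(k)
    for (i in seq_len(k)) {
      ids <- sprintf("%s_%03d_%s_sp", cl$name[i], seq_len(cl$size[i]),
                     cl$genus[i])
      member_ids[[i]] <- ids
      if (cl$size[i] == 1L) {
        seqs[[ids]] <- cons[[i]]
        clade_nwk[i] <- sprintf("%s:%g", ids, cfg$sub_prob)
      } else {
        ev <- evolve_balanced(ids, cons[[i]], cfg$sub_prob, frozen,
                              cfg$sub_prob)
        for (id in ids) seqs[[id]] <- ev$seqs[[id]]
        clade_nwk[i] <- ev$newick
      }
    }

    ## stitch the full true tree: substitute clade subtrees into the backbone
    if (k == 1L) {
      full_nwk <- paste0("(", clade_nwk[1], ");")
    } else {
      full_nwk <- ape::write.tree(backbone)
      for (i in seq_len(k)) {
        sub_nwk <- sub(":[0-9.eE+-]+$", "", clade_nwk[i])
        full_nwk <- sub(paste0("CLADETIP", i, ":"),
                        paste0(sub_nwk, ":"), full_nwk, fixed = TRUE)
      }
    }
    tree <- parse_newick(full_nwk)

    truth <- data.frame(
      id = unlist(member_ids),
      clade = rep(cl$name, cl$size),
      role = "member",
      taxon = rep(cl$taxon, cl$size),
      genus = rep(cl$genus, cl$size),
      stringsAsFactors = FALSE)

    ## rogues: fragmentary chimeras of members of two different clades.
    ## Only a small site subset is retained (the rest is gapped), half
    ## following each donor: with so few informative sites and a
    ## conflicting cross-clade signal, column-resampling replicates
    ## scatter the leaf across the tree -- the behaviour that makes a
    ## taxon rogue. Attached at the first donor clade's root.
    if (cfg$n_rogues > 0L) {
      if (k < 2L) stop("rogues require at least two clades")
      core <- 171:176        # shared core so every pair stays comparable
      ## donors come from large, phylogenetically distant clades: a
      ## chimera of small or sister clades settles on a stable compromise
      ## placement (it is not rogue), whereas conflicting signal between
      ## two distant large clades scatters it along a long path
      eligible <- which(cl$size >= 8L)
      if (length(eligible) < 2L) {
        eligible <- order(cl$size, decreasing = TRUE)[1:2]
      }
      ## distinct host (first-donor) clades across rogues, so their damage
      ## regions differ and one rogue cannot mask another
      hosts <- rep(sample(eligible), length.out = cfg$n_rogues)
      for (r in seq_len(cfg$n_rogues)) {
        ab <- c(hosts[r], sample(setdiff(eligible, hosts[r]), 1L))
        donor_a <- seqs[[sample(member_ids[[ab[1]]], 1L)]]
        donor_b <- seqs[[sample(member_ids[[ab[2]]], 1L)]]
        keep_sites <- sort(union(core, sample(setdiff(seq_len(L), core), 6L)))
        half <- keep_sites[seq_len(length(keep_sites) %/% 2L)]
        rest <- setdiff(keep_sites, half)
        chim <- rep("-", L)
        chim[half] <- donor_a[half]
        chim[rest] <- donor_b[rest]
        id <- sprintf("ROGUE_%02d_%s_sp", r, cl$genus[ab[1]])
        seqs[[id]] <- chim
        at <- mrca_leaves(tree, intersect(member_ids[[ab[1]]],
                                          tree$tip.label))
        tree <- phytools::bind.tip(tree, id, edge.length = cfg$sub_prob,
                                   where = at)
        truth <- rbind(truth, data.frame(
          id = id, clade = NA_character_, role = "rogue",
          taxon = cl$taxon[ab[1]], genus = cl$genus[ab[1]]))
      }
    }

    ## long branches: heavily mutated copies of a random clade consensus
    if (cfg$n_long_branches > 0L) {
      for (r in seq_len(cfg$n_long_branches)) {
        src <- sample(k, 1L)
        id <- sprintf("LONGBRANCH_%02d_%s_sp", r, cl$genus[src])
        seqs[[id]] <- mutate_seq(cons[[src]], min(0.9, 20 * cfg$sub_prob))
        at <- sample(ape::Ntip(tree) + seq_len(tree$Nnode), 1L)
        tree <- phytools::bind.tip(tree, id, edge.length = 1.0, where = at)
        truth <- rbind(truth, data.frame(
          id = id, clade = NA_character_, role = "long_branch",
          taxon = cl$taxon[src], genus = cl$genus[src]))
      }
    }

    ## fragments: terminal gap runs covering the site, planted in the
    ## target (first non-K) clade
    if (cfg$n_fragments > 0L) {
      tgt <- cfg$target_clade
      frag_ids <- utils::tail(member_ids[[tgt]], cfg$n_fragments)
      for (id in frag_ids) {
        gap_from <- sample(260:285, 1L)
        seqs[[id]][gap_from:L] <- "-"
        truth$role[truth$id == id] <- "fragment"
      }
    }

    ## reference (bovine rhodopsin role): the unmutated root consensus
    ref_id <- "REF_Bos_taurus_rhodopsin"
    seqs[[ref_id]] <- root_cons
    truth <- rbind(truth, data.frame(
      id = ref_id, clade = NA_character_, role = "reference",
      taxon = "Chordata", genus = "Bos"))

    ## decoys: i.i.d. uniform residues; half carry a Trichoplax genus
    ## token, half look like bare accessions (unidentifiable)
    if (cfg$n_decoys > 0L) {
      for (i in seq_len(cfg$n_decoys)) {
        id <- if (i %% 2L == 1L) {
          sprintf("DECOY_%03d_Trichoplax_adhaerens", i)
        } else {
          sprintf("XP_%07d", 1500000L + i)
        }
        seqs[[id]] <- sample(AA20, L, replace = TRUE)
        truth <- rbind(truth, data.frame(
          id = id, clade = NA_character_, role = "decoy",
          taxon = if (i %% 2L == 1L) "Placozoa" else NA_character_,
          genus = if (i %% 2L == 1L) "Trichoplax" else NA_character_))
      }
    }

    records <- vapply(seqs, paste, character(1), collapse = "")
    truth <- truth[match(names(records), truth$id), ]
    rownames(truth) <- NULL
    truth$site_residue <- substr(records[truth$id], site, site)
    truth$motif <- paste0(substr(records[truth$id], anchors[1], anchors[1]),
                          substr(records[truth$id], anchors[2], anchors[2]),
                          "xx",
                          substr(records[truth$id], anchors[3], anchors[3]))

    palette <- rep(c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                     "#a65628", "#f781bf", "#999999"), length.out = k)
    clade_defs <- data.frame(name = cl$name, color = palette,
                             sequence_id = vapply(member_ids, `[[`,
                                                  character(1), 1L),
                             stringsAsFactors = FALSE)
    decoy_ids <- truth$id[truth$role == "decoy"]
    if (length(decoy_ids)) {
      clade_defs <- rbind(clade_defs, data.frame(
        name = "outgroup", color = "#bbbbbb", sequence_id = decoy_ids[1]))
    }
    taxonomy <- unique(truth[!is.na(truth$genus), c("genus", "taxon")])
    rownames(taxonomy) <- NULL

    structure(list(tree = tree, records = records, truth = truth,
                   site_position = site, anchor_positions = anchors,
                   ref_id = ref_id, clade_defs = clade_defs,
                   taxonomy = taxonomy, config = cfg),
              class = "sim_bundle")
  })
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle>", length(x$records), "sequences,",
      ape::Ntip(x$tree), "true-tree leaves,",
      nrow(x$config$clades), "clades\n")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits `family.fasta` (aligned), `true_tree.nwk`, `truth.tsv`,
#' `clades.csv` and `taxonomy.tsv` into `dir`.
#'
#' @param bundle A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$records, file.path(dir, "family.fasta"))
  ape::write.tree(bundle$tree, file.path(dir, "true_tree.nwk"))
  write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$clade_defs, file.path(dir, "clades.csv"),
                   row.names = FALSE, quote = FALSE)
  write.table(bundle$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Replicate trees with rogues regrafted at random
#'
#' Produces `B` copies of the true tree in which every planted rogue leaf is
#' pruned and re-grafted onto an independently chosen random edge per
#' replicate, isolating rogue-detector testing from any tree builder.
#' Non-rogue bipartitions are identical across replicates by construction.
#'
#' @param bundle A [simulate_family()] result with at least one rogue.
#' @param B Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return List of `B` phylo trees on the true tree's full leaf set.
#' @export
make_rogue_replicates <- function(bundle, B, seed = 1L) {
  if (B < 2L) stop("need at least 2 replicates")
  rogues <- bundle$truth$id[bundle$truth$role == "rogue"]
  rogues <- intersect(rogues, bundle$tree$tip.label)
  if (length(rogues) == 0L) stop("bundle has no rogue sequences")
  withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      tr <- bundle$tree
      for (rg in rogues) {
        tr <- ape::drop.tip(tr, rg)
        e <- sample.int(nrow(tr$edge), 1L)
        pos <- runif(1L) * tr$edge.length[e]
        tr <- phytools::bind.tip(tr, rg, edge.length = 0.05,
                                 where = tr$edge[e, 2], position = pos)
      }
      tr
    })
  })
}
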