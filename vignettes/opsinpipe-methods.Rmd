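---
title: "Methods: clade filtering, rogue pruning and retinal-binding-site profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade filtering, rogue pruning and retinal-binding-site profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large opsin (and general GPCR) phylogenies are built from tens of thousands
of database hits, most of which are not members of the target family. The
biologically interesting signal — here, clades of opsins that have *lost*
the retinal-binding lysine K296 (Ballesteros–Weinstein 7.43 of bovine
rhodopsin) — only becomes visible after several bespoke computational
stages: filtering a mixed sequence pool down to the family spanned by known
bait sequences, removing rogue taxa and long branches that destabilize the
reconstruction, trimming gap-rich alignment columns, mapping reference
residue numbering through the trimmed alignment, and summarising residue
and taxon composition per clade. `opsinpipe` implements those stages as a
tested library with a thin command-line wrapper, together with a synthetic
family generator so that every stage can be exercised, end to end, with
exact ground truth and no external downloads.

## Bait-anchored clade extraction

A pool of candidate sequences is split into random subsets (about 900
sequences each by default, mirroring the scale at which per-subset trees
are practical). Every subset receives the full bait list plus one
non-family *anchor* sequence (an olfactory receptor plays this role for
opsins). A tree is built per subset and rooted at the anchor's attachment
node, keeping the anchor as a direct child of the root; every leaf under
the most recent common ancestor of the baits is then retained. When that
MRCA is the root itself, the baits sit on both sides of the anchor — the
span would cover the entire tree and filter nothing — and the offending
bait, the one whose exclusion shrinks the span back to a proper clade, is
reported per subset. Such baits are best handled by a human, so they are
only reported, never deleted; the subset result is recomputed once without
them so a single bad bait does not void a subset.

After filtering, a seeded random sample of the *non*-retained pool is added
back as a diverse outgroup (default 1000), together with every sequence
matching a configurable keep pattern (e.g. the genus *Trichoplax*, whose
placopsin-like GPCRs are deliberately retained even though they fail the
bait filter).

## Rogue and long-branch pruning

Rogue taxa jump between positions across replicate trees and erode
consensus support. The package's detector is a deliberately simple,
fully-specified stand-in for the dedicated tools usually wired into such
pipelines (which are described in their own publications), behind a
pluggable builder interface: any function mapping an alignment slice to a
main tree plus replicate trees can be substituted, so external
maximum-likelihood builders can be wired in without code changes. The
internal builder is neighbor joining on protein p-distances with
column-resampling bootstrap replicates.

The stability score is an RBIC-style quantity: restrict every replicate
tree to the kept leaf set, tally nontrivial bipartitions, and sum the
frequencies of all majority-rule (> 1/2) splits, divided by `n0 − 3` where
`n0` is the *original* leaf count. Keeping the denominator fixed means leaf
removals cannot inflate the score trivially; the score is 1 exactly when
all replicates are identical and fully resolved. Detection is a greedy
single-leaf dropset search: evaluate the score gain of every remaining
leaf's removal, remove the best one if its gain clears a minimum, and
repeat (ties go to the lexicographically smallest label, so runs are
deterministic).

The minimum gain deserves a note. With honest bootstrap replicates many
splits sit near the majority boundary, so almost every leaf shows a tiny
positive gain in some draw; accepting *any* positive gain would slowly eat
stable members over the twenty iterations of the protocol. The default
minimum is therefore three-quarters of a consensus split,
`0.75 / (n0 − 3)`: a removal must recover most of one full majority
bipartition. In our calibration runs on simulated families, member-noise
gains stay below about 0.4 splits at 50–100 replicates while genuinely
unstable leaves recover one to four splits, so this default separates the
two populations; it can be set to 0 (accept any gain) for oracle-style
analyses on noise-free replicate sets.

Long branches are flagged on the main tree by a robust pendant-length rule:
a leaf is removed when its pendant branch exceeds `long_branch_factor`
(default 10) times the median pendant length. A zero median disables the
rule.

The orchestration follows a twenty-iteration removal protocol:
iterations 1–9 run both detectors on random subsets and apply the union of
removals; from iteration 10 onward detection runs on the full remaining
set. Every removal is recorded in an audit table (iteration, id, cause,
score). The wording of the original protocol leaves open whether the
subset trees of the later iterations contributed removals independently;
the simpler full-set reading is implemented.

## Gap trimming and residue mapping

Alignment columns are removed when *more than* `max_gap_fraction` (default
0.9) of sequences carry a gap — the inequality is strict, so a column at
exactly the threshold is kept. The trim result carries the kept original
column indices, giving exact provenance. All column indices are 1-based,
internally and in every report, matching both R convention and biological
residue numbering (so the retinal-binding lysine is simply position 296).

Mapping reference residue positions into the trimmed alignment has an
exact route and a fallback. When the kept-column list and the untrimmed
reference row are available, each ungapped reference residue is paired
with its original column and translated through the kept columns. The
fallback embeds the degapped trimmed reference row into the full reference
sequence left-most with no mismatches allowed — trimming can only delete
reference residues, never substitute them — and the two routes agree
whenever the embedding is unambiguous. Positions lost to trimming map to
`NA` and downstream consumers treat them explicitly ("motif region
trimmed" is an error, not a silent default).

Helix-7 anchors are derived arithmetically from the 7.43 site at reference
position 296: 7.49 → 302, 7.50 → 303, 7.53 → 306. The logo window spans
reference positions 287 (7.34) to 324 (7.71); its span is reported as
`end − start` = 37, the field's customary difference arithmetic, although
the window inclusively contains 38 positions — the constructor exposes
both numbers rather than resolving the discrepancy.

## The lysine-loss scan

Given a tree, a trimmed alignment and the residue map, the scan reports
every *maximal* subtree in which all members covering the site column
carry a non-lysine residue, with at least `min_members` (default 2) such
members. Gaps and `X` at the site are non-informative: fragments neither
support nor veto a candidate. The singleton rule is deliberate: one
isolated lysine-less sequence inside a lysine-bearing clade may be
missequenced, misassembled or a pseudogene, and is never called. Maximality
is enforced structurally — the parent of every reported subtree contains a
lysine-bearing covered member.

## Taxonomy annotation

Sequence IDs are tokenized on non-alphanumeric separators and tokens are
matched case-preservingly against a genus index built from either the NCBI
taxdump dialect (`names.dmp`/`nodes.dmp`) or a simple two-column TSV.
Token matching is a deliberate tightening of "the ID contains a genus
string": raw substring matching produces false hits inside accession
strings (a two-letter genus such as *Io* would match almost anything).
When several genus tokens match, the longest wins, then the
lexicographically smallest; unmatched IDs are reported as
`"unidentified"`, never as an error. The interest list (which higher taxa
to report) is an input, since such lists are grown iteratively by the
analyst.

## The synthetic family generator

The generator emits a clade-structured, pre-aligned protein family with
exact truth labels, emulating the statistical shape of a chromopsin-bearing
opsin data set: several lysine clades with conserved or derived helix-7
motifs, one planted glutamic-acid clade (12 members, two of them fragments
whose terminal gap runs cover the site column — mirroring the observation
that a few members of a real lysine-loss clade are fragments), and one
small arginine clade. Site and motif anchor columns are frozen during
simulation, so recovery tests have exact ground truth. Sequences evolve
from a root consensus along random backbone and within-clade topologies
with per-branch, per-site substitution probability 0.05 within clades and
0.15 on the backbone — enough divergence that neighbor joining recovers
the clades as monophyletic, without saturating p-distances.

Planted artifacts:

* **Rogues** are fragmentary chimeras of members of two different large
  clades (12 informative sites, half following each donor, including a
  shared core window so all pairs stay comparable; the rest gapped).
  Full-length chimeras of two clade consensuses turned out *not* to be
  rogue under distance methods — they find a stable compromise placement
  on the path between the donor clades — whereas weak, conflicting signal
  over a handful of sites demonstrably scatters the leaf across
  replicates. Donors are drawn from clades of at least eight members (a
  chimera of small clades has too few neighbouring splits to disturb) and
  each rogue gets a different host clade, so rogues do not mask one
  another.
* **Long branches** are heavily mutated copies of a clade consensus
  (substitution probability capped at 0.9) attached with pendant length 1.
* **Decoys** are i.i.d. uniform sequences; half carry a *Trichoplax* genus
  token (exercising keep patterns and taxonomy), half look like bare
  accessions (exercising `"unidentified"`).
* A **reference** record (the unmutated root consensus, lysine at 296,
  NPxxY motif) plays the bovine-rhodopsin role for residue mapping.

What the generator does *not* emulate: indel evolution beyond terminal
fragment gaps, empirical substitution matrices, rate heterogeneity,
alignment error, and database-scale redundancy. Passing recovery tests on
this substrate shows the machinery is correct and well-calibrated on
clade-structured data with exact truth; it does not show that the
simplified detectors match dedicated rogue-detection tools on real,
messy alignments.

## Problem sizes and numerical choices

The test suite runs the full pipeline on the generator's default family
(about 290 sequences, 50 bootstrap replicates) once, and the parameter
recovery suites on a scaled family (about 75 members plus planted
artifacts, clade sizes 15/15/10/9/8/12/5) across many seeds — sizes chosen
so that a complete run of the suite stays comfortable on a single CPU
while keeping every structural property of the full-size family. The
methods themselves have no size-dependent constants except the RBIC
denominator, which is explicit.

Other numerical choices: p-distances error out (naming the pair) when two
sequences share no comparable column, and bootstrap resamples that produce
such a pair are redrawn (at most 10 times); negative neighbor-joining
branch lengths are clamped to zero; consensus frequencies are exact
rationals of the replicate count; all randomness flows through explicit
integer seeds (subset shuffling, bootstraps, add-back sampling, the
generator), so every run is byte-reproducible; rerooting at a leaf splits
the pendant edge at its midpoint (the placement is otherwise unspecified
and the midpoint is symmetric and preserves path lengths); rerooting above
a node uses a zero-length split toward the node.

The SH-aLRT rejection threshold (0.1) is applied on the 0–100 scale
exactly as printed in the sources that recommend it; because the intended
scale is genuinely ambiguous (0.1% versus 10%), the threshold is a
configuration field rather than a constant.

## Known limitations

* The internal builder is distance-based; likelihood-grade topologies
  require wiring an external builder through the builder interface.
* The greedy single-leaf dropset search can in principle miss rogue
  *sets* whose members mask each other perfectly; the twenty-iteration
  protocol with fresh replicates mitigates, but does not eliminate, this.
* Clade assignment requires at least two defining leaves to be
  meaningful — with a single definition the maximal single-definer subtree
  is the whole tree.
* Taxonomy matching is genus-token based and cannot identify IDs that
  carry no genus token (reported as `"unidentified"`).
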