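---
title: "Active-site fingerprinting and subfamily delineation with cladefp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site fingerprinting and subfamily delineation with cladefp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladefp)
```

## The problem

Enzyme families often diverge most informatively at a handful of first-shell
active-site residues, while a phylogeny built from whole sequences tracks
overall relatedness. Comparing the two views — *which clades carry which
active-site constitution* — is how new subfamilies with altered substrate
scope are found. `cladefp` implements this comparison for protein families
such as the fungal vanillyl alcohol oxidases (VAOs), FAD-dependent
4-phenol oxidoreductases whose active site can be described by five named
residue clusters:

| cluster | positions (reference numbering) | proposed role |
|---|---|---|
| A | 316, 413, 469, 470 | coordination of the *p*-substituent of phenolic substrates |
| H | 61, 422, 423 | covalent binding of the FAD cofactor |
| P | 108, 424, 468, 503, 504 | phenolate binding pocket |
| T | 184, 185, 459 | gate between substrate tunnel and active site |
| W | 170, 188, 312, 409, 410, 457 | catalysis; binding/activation of water |

Positions are 1-based residue indices on the ungapped **reference** sequence
(PsVAO numbering for the packaged default config), the same convention used
when residues are written `L316` or `H61`. The pipeline carries these
indices through a multiple sequence alignment to every homolog, producing a
per-sequence **fingerprint**: the ordered list of symbols presented at the
21 mapped positions (a gap where the homolog has a deletion).

## Pipeline

```{r pipeline, eval = FALSE}
fam <- simulate_family(default_vao_scenario(seed = 1))
res <- run_pipeline(list(
  records      = fam$records,
  ref_id       = "C4_leaf01",
  loop         = c(220, 240),
  outgroup_ids = grep("^BO", fam$records$id, value = TRUE),
  k_clades     = 7,
  out_dir      = "vao_run"))
res$subfamilies
```

The stages, each available as a standalone function and as a subcommand of
`inst/scripts/cladefp.R`:

1. **Assembly and deduplication** (`read_fasta`, `merge_and_deduplicate`).
   A *duplicate* is exact residue-string identity; near-duplicates are kept,
   because a similarity threshold would silently change the family
   composition. The first occurrence wins, so input order is meaningful and
   the operation is idempotent.
2. **Alignment** (`progressive_msa`, or import with `read_alignment`). A
   built-in progressive aligner: UPGMA guide tree on 3-mer distances, then
   profile–profile merges scored by average-of-pairs BLOSUM62 with affine
   gaps (open −10, extend −1, a length-*k* gap costing
   `open + (k−1)·extend`). These are the conventional protein defaults; no
   attempt is made to reproduce any particular external aligner's output,
   and externally computed alignments (aligned FASTA or Clustal) can be
   swapped in at this stage — both paths flow through identical downstream
   code.
3. **Coordinate mapping and fingerprinting** (`build_position_map`,
   `fingerprint_matrix`). The *k*-th non-gap character of the reference row
   defines the column of reference position *k*. A gap in a homolog at a
   mapped column is reported as `-` rather than imputed: deletions at
   active-site positions are informative, and the loop analysis depends on
   this convention.
4. **Phylogeny** (`p_distance_matrix`, `neighbor_joining`,
   `root_with_outgroup`). Distances are p-distances over mutually ungapped,
   non-`X` columns; the tree is neighbor joining (exact on additive inputs;
   negative branch-length estimates clamped to 0), rooted on the designated
   outgroup, which must be monophyletic. Maximum-likelihood inference is
   deliberately out of scope — the downstream analysis needs only a
   topology with branch lengths, and an external ML tree can be imported as
   Newick.
5. **Clades** (`extract_clades`). Either an explicit membership table (the
   faithful option when clade boundaries were drawn by expert inspection) or
   an automatic *k*-cut: the *k*−1 longest internal ingroup branches are
   cut and the components define the clades. The automatic mode assumes
   inter-clade branches are clearly longer than intra-clade ones.
6. **Loop detection and subfamilies** (`detect_loop`,
   `assign_subfamilies`). The oligomerization loop is specified as a
   reference residue span (a required configuration item — spans differ per
   family and per reference). Occupancy is the non-gap fraction over the
   mapped loop columns; a sequence carries the loop at occupancy ≥ 0.5, a
   clade is loop-present at ≥ 90% carriers, loop-absent at ≤ 10%, and
   *mixed* (reported, unassigned) otherwise. Subfamilies are the maximal
   clade groups sharing a non-mixed state. The thresholds exist to make an
   otherwise by-inspection binary call testable; at the default simulation
   settings every clade is unanimously present or absent, so results are
   insensitive to their exact values.
7. **Candidate ranking** (`rank_candidates`). Members of chosen clades are
   ordered by decreasing fingerprint Hamming distance to the reference.
   `-` and `X` mismatch everything, including themselves — conservative
   divergence scoring. The distance is deliberately unweighted: candidate
   selection in family surveys is qualitative, and weights would suggest
   spurious precision.

## Cluster configuration

Cluster definitions live in a JSON config (`read_cluster_config()`), so the
machinery applies beyond VAOs. The packaged default also carries an
`expected_reference_residues` block (L316, W413, …): when present, the
pipeline warns if the chosen reference disagrees — the usual symptom of an
off-by-one numbering error or the wrong reference sequence.

Two numbering ambiguities in the VAO literature are worth knowing about: the
W-cluster is listed with D409/E410 while several clade descriptions discuss
"D408", and the P-cluster lists I468 while one clade description calls the
same site "L468". The packaged config stores 409/410 and 468 as listed and
does not attempt to resolve the discrepancy; users anchoring on a different
reference should verify against the expected-residue warning.

## The simulator and what it does (not) show

`default_vao_scenario()` generates families with the structure the analysis
assumes, plus machine-readable truth for every stage:

* a rooted tree of 7 star-shaped ingroup clades (6 leaves each, pendant
  branches 0.02) on stems of 0.10 (the 5× inter/intra contrast the
  automatic clade cut relies on), and a 3-leaf outgroup on a 0.20 stem;
* a root sequence of 560 residues (the scale of the reference protein),
  drawn uniformly, with the 21 canonical reference states fixed at the
  cluster positions so a C4 leaf is a numbering-faithful reference;
* background substitutions as Poisson draws (rate 1.0 per site per unit
  branch length over unprotected sites, uniform over the 19 alternatives),
  never at the 21 protected positions;
* per-clade planted active-site states applied at the leaves
  (C1: 61F/459V/409T; C2: 459V; C6: 424A/470E/61F/468V/409E;
  C7: 316Q/470E/61M/424G/459C/409R; outgroup: 424G/459V; C3–C5 canonical).
  "Mostly replaced" observations are simplified to "always"
  (an application probability parameter exists, default 1.0);
* a loop at root positions 220–240, deleted from C7 and outgroup leaves.
  The span was chosen inside the largest cluster-free stretch of the
  reference numbering (positions 189–311), because deleting active-site
  positions would make planted fingerprints undefined; real loop
  coordinates are family-specific configuration. The loop is modelled as a
  deletion from a loop-bearing root rather than an insertion, so reference
  numbering over the span stays well-defined.

Substitutions are uniform (no empirical rate matrix, no rate heterogeneity,
no within-clade indels), so simulated distances should not be
over-interpreted: passing the pipeline on this generator demonstrates that
coordinate mapping, tree building, clade cutting, loop calling and
subfamily logic are correct *given* clade-structured data — not that the
aligner or NJ would resolve a real family with rate variation, domain
shuffling or fragmentary sequences. For real data, import a production MSA
and ML tree and let `cladefp` do the comparative layer.

## Numerical and design notes

* The alignment DP (Gotoh three-state, compiled) is shared between
  pairwise and profile–profile alignment; profile columns score
  average-of-pairs, with profile-internal gaps scoring `gap_extend` against
  residues and 0 against gaps. Columns that would become all-gap are
  dropped so the coordinate map stays minimal.
* Determinism everywhere: guide-tree and NJ tie handling follow the
  deterministic behaviour of `stats::hclust` and `ape::nj`; consensus ties
  break alphabetically with the gap last; candidate ties break by id; all
  simulator randomness flows from one seed. Rerunning a pipeline config
  reproduces byte-identical artifacts.
* Degenerate inputs: a single sequence "aligns" to a 1-row alignment;
  a pair with no comparable columns gets p-distance 1; an all-gap
  fingerprint is maximally distant from everything (21 with the default
  clusters); clade extraction refuses a *k* larger than the number of
  internal ingroup branches allows.
* Problem sizes in the test-suite and acceptance script (45-sequence
  families, 10 seeds, 200 brute-force aligner pairs at length ≤ 8, 500
  position-map alignments) were chosen as the smallest sizes at which every
  structural claim is exercised; all complete in well under a minute each.

## Known limitations

* The progressive aligner is desk-scale: adequate for tens of sequences of
  moderate divergence, not a substitute for MAFFT/ClustalW on large or
  highly divergent families.
* Automatic clade extraction requires the inter/intra branch-length
  contrast; families with gradual divergence need explicit membership.
* Subfamily assignment keys on a single indel; families with multiple
  informative indels need one run per segment.
* Fingerprint distances say nothing about activity: ranking candidates by
  active-site divergence is a hypothesis generator for wet-lab
  characterization, not a predictor of catalytic behaviour.
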