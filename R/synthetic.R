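#' Build a clade-structured tree for simulation
#'
#' Rooted tree with `n_clades` star-shaped ingroup clades hanging off a
#' common stem and a monophyletic outgroup on the other side of the root.
#' Leaf labels encode the planted group (`C3_leaf07`, `BO_leaf01`), which is
#' what the downstream truth tables key on. The topology is a deterministic
#' function of the counts and lengths; `seed` is accepted for interface
#' symmetry with the simulator.
#'
#' @param n_clades number of ingroup clades (>= 1).
#' @param leaves_per_clade leaves in each clade (>= 1).
#' @param intra_len pendant branch length inside clades (> 0).
#' @param inter_len clade stem length (> 0); the ingroup stem gets
#'   `inter_len` and the outgroup stem `2 * inter_len`.
#' @param outgroup_size leaves in the outgroup (>= 1).
#' @param seed unused; the tree is deterministic.
#' @return a rooted `phylo` tree.
#' @export
build_clade_tree <- function(n_clades, leaves_per_clade, intra_len, inter_len,
                             outgroup_size, seed = NULL) {
  stopifnot(n_clades >= 1L, leaves_per_clade >= 1L, outgroup_size >= 1L,
            intra_len > 0, inter_len > 0)
  star <- function(label, n, leaf_len, stem_len) {
    tips <- sprintf("%s_leaf%02d:%g", label, seq_len(n), leaf_len)
    if (n == 1L) sprintf("%s_leaf01:%g", label, leaf_len + stem_len)
    else sprintf("(%s):%g", paste(tips, collapse = ","), stem_len)
  }
  clades <- vapply(seq_len(n_clades), function(i)
    star(paste0("C", i), leaves_per_clade, intra_len, inter_len), "")
  ingroup <- if (n_clades == 1L) clades
             else sprintf("(%s):%g", paste(clades, collapse = ","), inter_len)
  outgroup <- star("BO", outgroup_size, intra_len, 2 * inter_len)
  ape::read.tree(text = sprintf("(%s,%s);", ingroup, outgroup))
}

#' Simulation specification
#'
#' Bundles everything [simulate_family()] needs: the true tree, the root
#' sequence model, the background substitution rate, the protected
#' (active-site) positions, per-clade planted states, and the loop indel.
#'
#' @param tree rooted `phylo`; tip labels `<clade>_<leaf>`.
#' @param root_length root sequence length (loop span included).
#' @param rate expected substitutions per unprotected site per unit branch
#'   length (>= 0).
#' @param protected_positions 1-based root positions never hit by background
#'   substitutions (the active-site positions).
#' @param clade_presets named list: clade label -> named character vector
#'   (position -> planted residue), applied to every leaf of the clade.
#' @param loop list `(start, end, present_in)`: root span of the loop and the
#'   clades that keep it; other clades have the span deleted.
#' @param root_states optional named character vector fixing root residues at
#'   given positions (typically the canonical reference states).
#' @param preset_prob probability a preset position is applied per leaf
#'   (default 1: "mostly replaced" is simplified to "always").
#' @param seed integer seed driving every random draw.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, root_length, rate, protected_positions,
                            clade_presets = list(),
                            loop = NULL, root_states = NULL,
                            preset_prob = 1.0, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), root_length >= 1L, rate >= 0,
            preset_prob >= 0, preset_prob <= 1)
  protected_positions <- sort(unique(as.integer(protected_positions)))
  if (length(protected_positions) &&
      (min(protected_positions) < 1L || max(protected_positions) > root_length))
    stop("protected positions outside the root sequence")
  clade_of <- sub("_.*$", "", tree$tip.label)
  unknown <- setdiff(names(clade_presets), unique(clade_of))
  if (length(unknown)) stop("preset(s) reference unknown clade(s): ",
                            paste(unknown, collapse = ", "))
  for (lab in names(clade_presets)) {
    pr <- clade_presets[[lab]]
    if (!all(pr %in% AMINO_ACIDS))
      stop("preset for clade '", lab, "' plants invalid residue(s)")
    p <- as.integer(names(pr))
    if (any(is.na(p)) || any(p < 1L) || any(p > root_length))
      stop("preset for clade '", lab, "' names positions outside the root")
  }
  if (!is.null(loop)) {
    loop$start <- as.integer(loop$start)
    loop$end <- as.integer(loop$end)
    if (!(1L <= loop$start && loop$start <= loop$end && loop$end <= root_length))
      stop("loop span outside the root sequence")
    if (any(protected_positions >= loop$start & protected_positions <= loop$end))
      stop("loop span overlaps protected positions; planted fingerprints ",
           "would be undefined for loop-less clades")
    bad <- setdiff(loop$present_in, unique(clade_of))
    if (length(bad)) stop("loop present_in references unknown clade(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(tree = tree, root_length = as.integer(root_length),
                 rate = rate, protected_positions = protected_positions,
                 clade_presets = clade_presets, loop = loop,
                 root_states = root_states, preset_prob = preset_prob,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a clade-structured protein family
#'
#' Draws a root sequence uniformly over the 20 residues (then overwrites any
#' fixed `root_states`), descends the tree placing Poisson background
#' substitutions (mean `rate x branch length x n unprotected sites`,
#' uniformly placed, uniform over the 19 alternative residues, never at
#' protected positions), overwrites every leaf's protected positions with its
#' clade preset, and finally deletes the loop span from the leaves of clades
#' that do not carry it. Truth tables record clade membership, the planted
#' fingerprint of every leaf, and its loop state.
#'
#' @param spec a [simulation_spec()].
#' @return a `simulated_family`: list with `records` (sequence record set),
#'   `tree` (the true `phylo`), `spec`, and `truth` (list: `membership`
#'   data.frame, `fingerprints` character matrix leaves x protected
#'   positions, `loop` data.frame).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  L <- spec$root_length
  prot <- spec$protected_positions
  unprot <- setdiff(seq_len(L), prot)
  root <- sample(AMINO_ACIDS, L, replace = TRUE)
  if (!is.null(spec$root_states))
    root[as.integer(names(spec$root_states))] <- spec$root_states
  tr <- ape::reorder.phylo(spec$tree, "cladewise")  # parents precede children
  n_tip <- length(tr$tip.label)
  root_node <- n_tip + 1L
  node_seq <- vector("list", max(tr$edge))
  node_seq[[root_node]] <- root
  for (e in seq_len(nrow(tr$edge))) {
    s <- node_seq[[tr$edge[e, 1L]]]
    n_mut <- rpois(1L, spec$rate * tr$edge.length[e] * length(unprot))
    if (n_mut > 0L) {
      sites <- sample(unprot, n_mut, replace = TRUE)
      for (p in sites) s[p] <- sample(setdiff(AMINO_ACIDS, s[p]), 1L)
    }
    node_seq[[tr$edge[e, 2L]]] <- s
  }
  clade_of <- sub("_.*$", "", tr$tip.label)
  fp_truth <- matrix("", n_tip, length(prot),
                     dimnames = list(tr$tip.label, as.character(prot)))
  loop_present <- rep(TRUE, n_tip)
  out_seqs <- character(n_tip)
  for (i in seq_len(n_tip)) {
    s <- node_seq[[i]]
    pr <- spec$clade_presets[[clade_of[i]]]
    if (!is.null(pr)) {
      apply_it <- runif(length(pr)) <= spec$preset_prob
      s[as.integer(names(pr))[apply_it]] <- pr[apply_it]
    }
    if (length(prot)) fp_truth[i, ] <- s[prot]
    if (!is.null(spec$loop) && !(clade_of[i] %in% spec$loop$present_in)) {
      s <- s[-(spec$loop$start:spec$loop$end)]
      loop_present[i] <- FALSE
    }
    out_seqs[i] <- paste(s, collapse = "")
  }
  structure(list(
    records = seq_records(tr$tip.label, out_seqs),
    tree = tr,
    spec = spec,
    truth = list(
      membership = data.frame(id = tr$tip.label, clade = clade_of,
                              stringsAsFactors = FALSE),
      fingerprints = fp_truth,
      loop = data.frame(id = tr$tip.label, loop_present = loop_present,
                        stringsAsFactors = FALSE))),
    class = "simulated_family")
}

# Planted active-site states per clade for the default scenario, written on
# canonical reference numbering. C3-C5 stay at the canonical state; the
# bacterial outgroup (BO) carries the EUGO-like glycine at 424 and an
# aliphatic 459.
vao_clade_presets <- function() {
  list(
    C1 = c("61" = "F", "459" = "V", "409" = "T"),
    C2 = c("459" = "V"),
    C6 = c("424" = "A", "470" = "E", "61" = "F", "468" = "V", "409" = "E"),
    C7 = c("316" = "Q", "470" = "E", "61" = "M", "424" = "G", "459" = "C",
           "409" = "R"),
    BO = c("424" = "G", "459" = "V")
  )
}

#' Default VAO-family simulation scenario
#'
#' Emulates the structure of the fungal VAO family: 7 ingroup clades (6
#' leaves each), a 3-member bacterial-style outgroup, an oligomerization-loop
#' span carried by clades C1-C6 but deleted from C7 and the outgroup, and
#' per-clade planted substitutions at the 21 default active-site positions
#' (C1: 61F/459V/409T; C2: 459V; C6: 424A/470E/61F/468V/409E; C7:
#' 316Q/470E/61M/424G/459C/409R; outgroup: 424G/459V; C3-C5 canonical). The
#' root carries the canonical reference residues at all 21 positions, so any
#' C3-C5 (or C4) leaf can serve as the pipeline reference. Inter-clade stems
#' are 5x the pendant branches.
#'
#' @param seed integer seed.
#' @param leaves_per_clade leaves per ingroup clade (default 6).
#' @return a [simulation_spec()].
#' @export
default_vao_scenario <- function(seed = 1L, leaves_per_clade = 6L) {
  cfg <- read_cluster_config()
  prot <- as.integer(names(cfg$expected_reference_residues))
  tree <- build_clade_tree(n_clades = 7L, leaves_per_clade = leaves_per_clade,
                           intra_len = 0.02, inter_len = 0.10,
                           outgroup_size = 3L)
  simulation_spec(
    tree = tree,
    root_length = 560L,
    rate = 1.0,
    protected_positions = prot,
    clade_presets = vao_clade_presets(),
    loop = list(start = 220L, end = 240L,
                present_in = paste0("C", 1:6)),
    root_states = cfg$expected_reference_residues,
    preset_prob = 1.0,
    seed = seed)
}

#' Write a simulated family and its truth tables to a directory
#'
#' Emits `family.fasta`, `true_tree.nwk`, `membership.tsv`,
#' `fingerprints.tsv`, `loop_states.tsv` and `spec.json` (an echo of the
#' scenario parameters).
#'
#' @param fam a `simulated_family`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_family <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fam$records, file.path(dir, "family.fasta"))
  write_newick(fam$tree, file.path(dir, "true_tree.nwk"))
  write.table(fam$truth$membership, file.path(dir, "membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- data.frame(id = rownames(fam$truth$fingerprints),
                   fam$truth$fingerprints, check.names = FALSE)
  write.table(fp, file.path(dir, "fingerprints.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fam$truth$loop, file.path(dir, "loop_states.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- fam$spec
  echo <- list(root_length = spec$root_length, rate = spec$rate,
               protected_positions = spec$protected_positions,
               clade_presets = lapply(spec$clade_presets, as.list),
               loop = spec$loop, preset_prob = spec$preset_prob,
               seed = spec$seed)
  jsonlite::write_json(echo, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
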