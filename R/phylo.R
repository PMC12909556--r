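#' Pairwise p-distance matrix from an alignment
#'
#' `d(i,j)` is the proportion of mismatching residues over comparable
#' columns — columns where both rows carry a residue that is neither a gap
#' nor `X`. Pairs with no comparable column get the maximal distance 1.
#'
#' @param a an `alignment` with at least 2 rows.
#' @return symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
p_distance_matrix <- function(a) {
  if (length(a$ids) < 2L) stop("need at least 2 sequences")
  m <- as.matrix.alignment(a)
  ok <- m != GAP & m != "X"
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(a$ids, a$ids))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    D[i, j] <- D[j, i] <-
      if (nc == 0L) 1 else sum(m[i, comp] != m[j, comp]) / nc
  }
  D
}

#' Neighbor-joining tree
#'
#' Wraps the canonical NJ implementation (ape); negative branch-length
#' estimates, which NJ can produce on non-additive inputs, are clamped to 0.
#' On an additive matrix the leaf-to-leaf path lengths of the result
#' reproduce the input distances exactly (up to floating point).
#'
#' @param d symmetric distance matrix with dimnames, at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must have taxon names")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Read a Newick tree
#'
#' @param path Newick file (single tree; quoted labels and branch lengths
#'   supported).
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1L]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1L]] == ")", -1L, 0L)))
  if (any(depth < 0L))
    stop("unbalanced parentheses at character ", which(depth < 0L)[1L])
  if (length(depth) && depth[length(depth)] != 0L)
    stop("unbalanced parentheses at character ", nchar(txt))
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("cannot parse Newick in ", path)
  tr
}

#' Write a tree in Newick format
#'
#' @param t a `phylo` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  # 15 significant digits so branch lengths survive a round trip
  ape::write.tree(t, file = path, digits = 15)
  invisible(path)
}

#' Root a tree on the branch separating an outgroup
#'
#' @param t a `phylo` tree.
#' @param outgroup_ids non-empty character vector of leaf labels; must form a
#'   monophyletic group in the unrooted tree and must not contain every leaf.
#' @return a rooted `phylo` tree; the ingroup is the complement of the
#'   outgroup.
#' @export
root_with_outgroup <- function(t, outgroup_ids) {
  outgroup_ids <- unique(as.character(outgroup_ids))
  if (!length(outgroup_ids)) stop("outgroup is empty")
  missing <- setdiff(outgroup_ids, t$tip.label)
  if (length(missing)) stop("outgroup id(s) not in tree: ",
                            paste(missing, collapse = ", "))
  if (length(outgroup_ids) >= length(t$tip.label))
    stop("outgroup contains every leaf; no ingroup remains")
  if (length(outgroup_ids) > 1L &&
      !ape::is.monophyletic(t, outgroup_ids)) {
    mr <- ape::getMRCA(t, outgroup_ids)
    inside <- ape::extract.clade(t, mr)$tip.label
    stop("outgroup is not monophyletic; the smallest bipartition containing ",
         "it also includes: ",
         paste(setdiff(inside, outgroup_ids), collapse = ", "))
  }
  ape::root(t, outgroup = outgroup_ids, resolve.root = TRUE)
}

# children list and parent vector from a phylo edge matrix
tree_index <- function(t) {
  parent <- integer(max(t$edge))
  parent[t$edge[, 2L]] <- t$edge[, 1L]
  list(parent = parent, n_tip = length(t$tip.label))
}

# node ids of the subtree rooted at `node` (inclusive), via edge scan
subtree_nodes <- function(t, node) {
  nodes <- node
  repeat {
    kids <- t$edge[t$edge[, 1L] %in% nodes, 2L]
    new <- setdiff(kids, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  nodes
}

#' Cut a rooted tree into clades
#'
#' Automatic mode (`k`): the `k - 1` longest internal branches inside the
#' ingroup subtree are cut; the resulting leaf partition defines the clades.
#' Ties are broken by the smaller child-node id. Explicit mode
#' (`membership`): a named vector leaf id -> clade label; groups that are not
#' monophyletic in the tree raise a warning (recorded, not fatal).
#'
#' @param t a rooted `phylo` tree.
#' @param k number of clades (>= 1), automatic mode.
#' @param membership named character vector, explicit mode (overrides `k`).
#' @param outgroup_ids leaves excluded from clade extraction.
#' @return named list: clade label -> character vector of leaf ids; labels
#'   are `K1..Kk` in order of first appearance along the tree's tip order
#'   (automatic mode) or the supplied labels (explicit mode).
#' @export
extract_clades <- function(t, k = NULL, membership = NULL,
                           outgroup_ids = character()) {
  ingroup <- setdiff(t$tip.label, outgroup_ids)
  if (!length(ingroup)) stop("no ingroup leaves")
  if (!is.null(membership)) {
    unknown <- setdiff(names(membership), t$tip.label)
    if (length(unknown)) stop("membership names unknown leaf id(s): ",
                              paste(unknown, collapse = ", "))
    uncovered <- setdiff(ingroup, names(membership))
    if (length(uncovered)) stop("membership does not cover ingroup leaf id(s): ",
                                paste(uncovered, collapse = ", "))
    groups <- split(names(membership), membership)
    for (g in names(groups))
      if (length(groups[[g]]) > 1L && !ape::is.monophyletic(t, groups[[g]]))
        warning("clade '", g, "' is not monophyletic in the tree", call. = FALSE)
    return(groups)
  }
  if (is.null(k) || k < 1L) stop("k must be >= 1 (or give explicit membership)")
  if (k == 1L) {
    out <- list(K1 = ingroup)
    return(out)
  }
  idx <- tree_index(t)
  in_root <- if (length(ingroup) == 1L) match(ingroup, t$tip.label)
             else ape::getMRCA(t, ingroup)
  nodes <- subtree_nodes(t, in_root)
  # internal edges strictly inside the ingroup subtree
  is_internal_edge <- t$edge[, 1L] %in% nodes & t$edge[, 2L] %in% nodes &
    t$edge[, 2L] > idx$n_tip
  cand <- which(is_internal_edge)
  if (length(cand) < k - 1L)
    stop("tree has only ", length(cand),
         " internal ingroup branches; cannot cut into ", k, " clades")
  ord <- cand[order(-t$edge.length[cand], t$edge[cand, 2L])]
  cut_children <- t$edge[ord[seq_len(k - 1L)], 2L]
  leaf_ids <- match(ingroup, t$tip.label)
  assign_leaf <- function(leaf) {
    node <- leaf
    while (node != in_root) {
      if (node %in% cut_children) return(as.character(node))
      node <- idx$parent[node]
    }
    "root"
  }
  comp <- vapply(leaf_ids, assign_leaf, "")
  # label clades K1..Kk in tip order of first appearance
  first <- comp[order(leaf_ids)]
  labels <- stats::setNames(paste0("K", seq_len(k)), unique(first))
  groups <- split(ingroup, labels[comp])
  groups[order(as.integer(sub("^K", "", names(groups))))]
}
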