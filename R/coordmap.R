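#' Read an active-site cluster configuration
#'
#' The configuration is JSON with fields `reference_id`, `clusters` (a list
#' of `{name, positions, role}` with 1-based positions on the ungapped
#' reference sequence) and an optional `expected_reference_residues` block
#' mapping positions to the residue the reference is expected to carry —
#' a guard against off-by-one numbering mistakes.
#'
#' @param path JSON file; omit for the packaged default, the five active-site
#'   clusters of the fungal vanillyl alcohol oxidase (VAO) family anchored on
#'   PsVAO numbering.
#' @return an object of class `cluster_config`.
#' @export
read_cluster_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vao_clusters.json", package = "cladefp",
                        mustWork = TRUE)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$clusters) || !length(cfg$clusters))
    stop("cluster config has no clusters: ", path)
  cl <- lapply(cfg$clusters, function(x) {
    list(name = as.character(x$name),
         positions = as.integer(x$positions),
         role = if (is.null(x$role)) "" else as.character(x$role))
  })
  exp_res <- NULL
  if (!is.null(cfg$expected_reference_residues)) {
    exp_res <- unlist(cfg$expected_reference_residues)
    names(exp_res) <- names(cfg$expected_reference_residues)
  }
  validate_clusters(cl)
  structure(list(reference_id = cfg$reference_id, clusters = cl,
                 expected_reference_residues = exp_res),
            class = "cluster_config")
}

validate_clusters <- function(clusters) {
  nm <- vapply(clusters, `[[`, "", "name")
  if (any(duplicated(nm))) stop("duplicate cluster names")
  for (cl in clusters) {
    p <- cl$positions
    if (length(p) < 1L || any(p < 1L)) stop("cluster '", cl$name,
                                            "' needs positive positions")
    if (any(diff(p) <= 0L)) stop("positions in cluster '", cl$name,
                                 "' must be strictly increasing")
  }
  all_pos <- unlist(lapply(clusters, `[[`, "positions"))
  if (any(duplicated(all_pos)))
    stop("position(s) assigned to more than one cluster: ",
         paste(unique(all_pos[duplicated(all_pos)]), collapse = ", "))
  invisible(TRUE)
}

# Ordered (cluster, position) scaffold common to every fingerprint.
cluster_scaffold <- function(clusters) {
  data.frame(
    cluster = rep(vapply(clusters, `[[`, "", "name"),
                  vapply(clusters, function(x) length(x$positions), 1L)),
    position = unlist(lapply(clusters, `[[`, "positions")),
    stringsAsFactors = FALSE)
}

#' Map reference residue numbering to alignment columns
#'
#' Builds the strictly monotone map from 1-based residue indices on the
#' ungapped reference sequence to 0-based alignment column indices: the k-th
#' non-gap character of the reference row sits in column `pairs[k]`.
#'
#' @param a an `alignment`.
#' @param ref_id id of the reference row.
#' @return an object of class `position_map` with `ref_id`, `ref_length` and
#'   `pairs` (integer vector named by residue index, values 0-based columns).
#' @export
build_position_map <- function(a, ref_id) {
  i <- match(ref_id, a$ids)
  if (is.na(i)) stop("reference id '", ref_id, "' not present in alignment")
  chars <- strsplit(a$seqs[i], "")[[1L]]
  cols <- which(chars != GAP) - 1L
  names(cols) <- seq_along(cols)
  structure(list(ref_id = ref_id, ref_length = length(cols), pairs = cols),
            class = "position_map")
}

#' Check the reference against expected residues in the config
#'
#' Warns (does not stop) when the reference sequence disagrees with the
#' `expected_reference_residues` block, listing every discordant position —
#' the usual symptom of an off-by-one numbering error or a wrong reference.
#'
#' @param ref_residues ungapped reference sequence.
#' @param config a `cluster_config`.
#' @return invisibly, a data.frame of mismatches (possibly empty).
#' @export
check_reference_residues <- function(ref_residues, config) {
  exp_res <- config$expected_reference_residues
  if (is.null(exp_res)) return(invisible(data.frame()))
  pos <- as.integer(names(exp_res))
  obs <- substring(ref_residues, pos, pos)
  bad <- which(obs != exp_res | obs == "")
  mism <- data.frame(position = pos[bad], expected = unname(exp_res[bad]),
                     observed = obs[bad], stringsAsFactors = FALSE)
  if (nrow(mism))
    warning("reference disagrees with expected residues at position(s): ",
            paste(sprintf("%d (expected %s, found %s)", mism$position,
                          mism$expected, mism$observed), collapse = "; "),
            call. = FALSE)
  invisible(mism)
}

#' Extract one sequence's active-site fingerprint
#'
#' Reads, for every cluster position, the symbol the target row presents in
#' the alignment column that carries that reference position. A gap in the
#' target yields `-`: deletions at active-site positions are informative and
#' are never imputed from neighbouring residues.
#'
#' @param a an `alignment`.
#' @param pm a [build_position_map()] result for the reference row of `a`.
#' @param clusters list of cluster definitions (from a `cluster_config`).
#' @param seq_id the row to fingerprint.
#' @return a `fingerprint`: data.frame with columns `cluster`, `position`,
#'   `symbol`, and attribute `seq_id`.
#' @export
extract_fingerprint <- function(a, pm, clusters, seq_id) {
  i <- match(seq_id, a$ids)
  if (is.na(i)) stop("sequence id '", seq_id, "' not present in alignment")
  scaf <- cluster_scaffold(clusters)
  over <- scaf$position[scaf$position > pm$ref_length]
  if (length(over))
    stop("cluster position(s) exceed reference length (", pm$ref_length, "): ",
         paste(over, collapse = ", "))
  cols <- pm$pairs[as.character(scaf$position)] + 1L
  chars <- strsplit(a$seqs[i], "")[[1L]]
  out <- data.frame(cluster = scaf$cluster, position = scaf$position,
                    symbol = chars[cols], stringsAsFactors = FALSE)
  attr(out, "seq_id") <- seq_id
  class(out) <- c("fingerprint", "data.frame")
  out
}

#' Fingerprint every row of an alignment
#'
#' @param a an `alignment` containing the reference row.
#' @param clusters list of cluster definitions, or a whole `cluster_config`.
#' @param ref_id reference row id (defaults to the config's `reference_id`).
#' @return a `fingerprint_matrix`: list with `scaffold` (cluster/position
#'   data.frame), `symbols` (character matrix, one row per sequence in
#'   alignment order) and `ref_id`.
#' @export
fingerprint_matrix <- function(a, clusters, ref_id = NULL) {
  if (inherits(clusters, "cluster_config")) {
    if (is.null(ref_id)) ref_id <- clusters$reference_id
    clusters <- clusters$clusters
  }
  if (is.null(ref_id)) stop("ref_id is required")
  pm <- build_position_map(a, ref_id)
  scaf <- cluster_scaffold(clusters)
  over <- scaf$position[scaf$position > pm$ref_length]
  if (length(over))
    stop("cluster position(s) exceed reference length (", pm$ref_length, "): ",
         paste(over, collapse = ", "))
  cols <- pm$pairs[as.character(scaf$position)] + 1L
  m <- as.matrix.alignment(a)[, cols, drop = FALSE]
  colnames(m) <- paste0(scaf$cluster, ":", scaf$position)
  structure(list(scaffold = scaf, symbols = m, ref_id = ref_id,
                 clusters = clusters),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint matrix: %d sequences x %d positions (%d clusters), reference '%s'\n",
              nrow(x$symbols), nrow(x$scaffold),
              length(unique(x$scaffold$cluster)), x$ref_id))
  invisible(x)
}

#' Pull one fingerprint out of a fingerprint matrix
#' @param fm a `fingerprint_matrix`.
#' @param seq_id row id.
#' @export
get_fingerprint <- function(fm, seq_id) {
  i <- match(seq_id, rownames(fm$symbols))
  if (is.na(i)) stop("no fingerprint for id '", seq_id, "'")
  out <- cbind(fm$scaffold, data.frame(symbol = unname(fm$symbols[i, ]),
                                       stringsAsFactors = FALSE))
  attr(out, "seq_id") <- seq_id
  class(out) <- c("fingerprint", "data.frame")
  out
}

#' Hamming distance between two fingerprints
#'
#' Counts positions (optionally restricted to a subset of clusters) where the
#' two fingerprints differ. `-` and `X` are treated conservatively: they
#' mismatch every symbol, including themselves, so two aligned gaps still
#' count as divergence.
#'
#' @param f,g `fingerprint` objects on identical scaffolding.
#' @param scope `"all"` or a character vector of cluster names.
#' @return integer distance in `[0, n positions in scope]`.
#' @export
fingerprint_distance <- function(f, g, scope = "all") {
  if (!identical(f$cluster, g$cluster) || !identical(f$position, g$position))
    stop("fingerprints have different scaffolding")
  sel <- if (identical(scope, "all")) rep(TRUE, nrow(f)) else f$cluster %in% scope
  if (!any(sel)) stop("scope selects no positions")
  a <- f$symbol[sel]
  b <- g$symbol[sel]
  match_ok <- a == b & !(a %in% c(GAP, "X"))
  sum(!match_ok)
}

#' Export a fingerprint matrix as TSV
#'
#' One row per sequence, one column per `cluster:position`, plus one
#' concatenated motif column per cluster.
#'
#' @param fm a `fingerprint_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(fm, path) {
  motifs <- sapply(unique(fm$scaffold$cluster), function(cl) {
    apply(fm$symbols[, fm$scaffold$cluster == cl, drop = FALSE], 1L,
          paste, collapse = "")
  })
  df <- data.frame(id = rownames(fm$symbols), fm$symbols,
                   motifs, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(fm$symbols),
                 paste0(unique(fm$scaffold$cluster), "_motif"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
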