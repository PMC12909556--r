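#' Per-clade consensus fingerprints and conservation
#'
#' For every clade and every scaffold position, the modal symbol among the
#' clade's members and the fraction of members carrying it. Ties are broken
#' by alphabetical symbol order with the gap sorting last, so profiles are
#' deterministic.
#'
#' @param fm a `fingerprint_matrix`.
#' @param clades named list: clade label -> leaf ids (see [extract_clades()]).
#' @return a `data.frame` with columns `clade`, `cluster`, `position`,
#'   `consensus`, `conservation`, `n_members`.
#' @export
clade_profiles <- function(fm, clades) {
  if (!length(clades)) stop("no clades given")
  rows <- rownames(fm$symbols)
  out <- list()
  for (lab in names(clades)) {
    ids <- clades[[lab]]
    if (!length(ids)) stop("clade '", lab, "' is empty")
    missing <- setdiff(ids, rows)
    if (length(missing)) stop("clade '", lab, "' member(s) without fingerprint: ",
                              paste(missing, collapse = ", "))
    sub <- fm$symbols[ids, , drop = FALSE]
    cons <- apply(sub, 2L, modal_symbol)
    freq <- vapply(seq_len(ncol(sub)),
                   function(j) mean(sub[, j] == cons[j]), 0)
    out[[lab]] <- data.frame(clade = lab, cluster = fm$scaffold$cluster,
                             position = fm$scaffold$position,
                             consensus = unname(cons), conservation = freq,
                             n_members = length(ids), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# modal symbol with deterministic tie-break: alphabetical, gap last
modal_symbol <- function(symbols) {
  u <- c(sort(setdiff(unique(symbols), GAP)), intersect(GAP, symbols))
  counts <- vapply(u, function(s) sum(symbols == s), 0L)
  u[which.max(counts)]
}

#' Detect presence of a loop segment across an alignment
#'
#' The loop is given as a residue span on the reference; its alignment
#' columns are the mapped columns of those positions. Occupancy is the
#' fraction of loop columns in which a sequence carries a residue; the loop
#' is called present when occupancy reaches the threshold.
#'
#' @param a an `alignment`.
#' @param loop_region integer `c(start, end)`, 1-based inclusive on reference
#'   numbering.
#' @param pm the reference [build_position_map()].
#' @param threshold occupancy needed to call the loop present (default 0.5).
#' @return `data.frame` with columns `seq_id`, `occupancy`, `present`.
#' @export
detect_loop <- function(a, loop_region, pm, threshold = 0.5) {
  start <- as.integer(loop_region[1L])
  end <- as.integer(loop_region[2L])
  if (!(1L <= start && start <= end && end <= pm$ref_length))
    stop("loop region [", start, ", ", end,
         "] outside reference (length ", pm$ref_length, ")")
  cols <- pm$pairs[as.character(start:end)] + 1L
  m <- as.matrix.alignment(a)[, cols, drop = FALSE]
  occ <- rowMeans(m != GAP)
  data.frame(seq_id = a$ids, occupancy = unname(occ),
             present = unname(occ >= threshold), stringsAsFactors = FALSE)
}

#' Group clades into subfamilies by loop state
#'
#' A clade is loop-`present` when at least 90% of its members carry the loop,
#' loop-`absent` when at most 10% do, and `mixed` otherwise. Subfamilies are
#' the maximal groups of clades sharing a non-mixed state (so at most two);
#' mixed clades are reported unassigned. Loop-present clades come first in
#' the labelling (`SF1`, `SF2`).
#'
#' @param clades named list: clade label -> leaf ids.
#' @param loop_calls output of [detect_loop()] covering every clade member.
#' @return a `subfamily_assignment`: list with `subfamilies` (named list:
#'   subfamily label -> clade labels), `loop_state` (named character, per
#'   subfamily), `clade_state` (named character, per clade) and `unassigned`
#'   (mixed clade labels).
#' @export
assign_subfamilies <- function(clades, loop_calls) {
  state <- vapply(names(clades), function(lab) {
    ids <- clades[[lab]]
    i <- match(ids, loop_calls$seq_id)
    if (anyNA(i)) stop("clade '", lab, "' member(s) without loop call: ",
                       paste(ids[is.na(i)], collapse = ", "))
    frac <- mean(loop_calls$present[i])
    if (frac >= 0.9) "present" else if (frac <= 0.1) "absent" else "mixed"
  }, "")
  subfamilies <- list()
  loop_state <- character()
  for (s in c("present", "absent")) {
    members <- names(state)[state == s]
    if (length(members)) {
      lab <- paste0("SF", length(subfamilies) + 1L)
      subfamilies[[lab]] <- members
      loop_state[[lab]] <- s
    }
  }
  structure(list(subfamilies = subfamilies, loop_state = loop_state,
                 clade_state = state,
                 unassigned = names(state)[state == "mixed"]),
            class = "subfamily_assignment")
}

#' @export
print.subfamily_assignment <- function(x, ...) {
  cat(length(x$subfamilies), "subfamilies\n")
  for (lab in names(x$subfamilies))
    cat(sprintf("  %s (loop %s): %s\n", lab, x$loop_state[[lab]],
                paste(x$subfamilies[[lab]], collapse = ", ")))
  if (length(x$unassigned))
    cat("  unassigned (mixed):", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}

#' Rank candidates by active-site divergence from a reference
#'
#' Orders the members of the named clades by decreasing fingerprint Hamming
#' distance to the reference fingerprint (ties broken by id). The plain
#' unweighted distance is used deliberately: candidate selection in family
#' surveys is qualitative, and a weighting scheme would suggest precision the
#' underlying comparison does not have.
#'
#' @param fm a `fingerprint_matrix`.
#' @param reference_fp the reference `fingerprint`.
#' @param clades named list: clade label -> leaf ids.
#' @param within character vector of clade labels to rank within.
#' @param scope `"all"` or a subset of cluster names (see
#'   [fingerprint_distance()]).
#' @return `data.frame` with columns `seq_id`, `clade`, `distance`, ordered
#'   by decreasing distance.
#' @export
rank_candidates <- function(fm, reference_fp, clades, within, scope = "all") {
  within <- intersect(within, names(clades))
  ids <- unlist(clades[within], use.names = FALSE)
  if (!length(ids)) stop("candidate selection is empty")
  clade_of <- rep(within, lengths(clades[within]))
  d <- vapply(ids, function(id)
    fingerprint_distance(get_fingerprint(fm, id), reference_fp, scope), 0)
  out <- data.frame(seq_id = ids, clade = clade_of, distance = unname(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$distance, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
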