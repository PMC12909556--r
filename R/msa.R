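#' Aligned sequence set
#'
#' An `alignment` holds equal-length gapped rows over the amino-acid alphabet
#' plus `-`. Stripping gaps from a row must recover the source sequence.
#'
#' @param ids character vector of unique row identifiers.
#' @param seqs gapped residue strings, all the same length.
#' @return an object of class `alignment` with elements `ids` and `seqs`.
#' @export
new_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs must have equal length")
  if (any(duplicated(ids))) stop("duplicate row id(s): ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    off <- ids[w != w[1L]]
    stop("ragged alignment rows (length differs from first row): ",
         paste(off, collapse = ", "))
  }
  validate_residues(seqs, ids, allow_gap = TRUE)
  structure(list(ids = ids, seqs = seqs), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns\n", length(x$ids), n_col(x)))
  invisible(x)
}

#' Number of columns in an alignment
#' @param a an `alignment`.
#' @export
n_col <- function(a) if (length(a$seqs)) nchar(a$seqs[1L]) else 0L

#' Alignment as a character matrix (rows = sequences, named by id)
#' @param x an `alignment`.
#' @param ... unused.
#' @export
as.matrix.alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

matrix_to_alignment <- function(m) {
  new_alignment(rownames(m), apply(m, 1L, paste, collapse = ""))
}

#' Drop columns that are gaps in every row
#' @param a an `alignment`.
#' @export
drop_allgap_columns <- function(a) {
  m <- as.matrix.alignment(a)
  keep <- colSums(m != GAP) > 0L
  matrix_to_alignment(m[, keep, drop = FALSE])
}

#' Remove gaps from alignment rows
#' @param a an `alignment`.
#' @return the ungapped sequence record set.
#' @export
ungap_alignment <- function(a) {
  seq_records(a$ids, gsub(GAP, "", a$seqs, fixed = TRUE))
}

#' Protein scoring scheme for alignment
#'
#' Defaults to BLOSUM62 (as shipped with Biostrings, restricted to the 20
#' standard residues plus `X`) with affine gap penalties: a gap of length k
#' costs `gap_open + (k-1) * gap_extend`.
#'
#' @param substitution symmetric integer substitution matrix with residue
#'   dimnames; `NULL` for BLOSUM62.
#' @param gap_open,gap_extend negative penalties, `gap_open <= gap_extend < 0`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution = NULL, gap_open = -10, gap_extend = -1) {
  if (is.null(substitution)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    keep <- c(AMINO_ACIDS, "X")
    substitution <- e$BLOSUM62[keep, keep]
  }
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("require gap_open <= gap_extend < 0")
  structure(list(substitution = substitution,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

score_letters <- function(scheme, chars, id) {
  bad <- setdiff(unique(chars), rownames(scheme$substitution))
  if (length(bad))
    stop("sequence '", id, "' contains letters absent from the scoring matrix: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment of two protein sequences. The score is
#' the optimum over all global alignments under the scheme; swapping the
#' arguments swaps the rows but not the score.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return list with `a`, `b` (gapped strings) and `score`.
#' @export
pairwise_global <- function(a, b, scheme = scoring_scheme()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < 1L || nchar(b) < 1L) stop("sequences must be non-empty")
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  score_letters(scheme, ca, "a"); score_letters(scheme, cb, "b")
  S <- scheme$substitution[ca, cb, drop = FALSE]
  r <- nw_affine_cpp(S, scheme$gap_open, scheme$gap_extend)
  gapped <- function(chars, idx) {
    out <- rep(GAP, length(idx))
    out[idx > 0L] <- chars[idx[idx > 0L]]
    paste(out, collapse = "")
  }
  list(a = gapped(ca, r$a_idx), b = gapped(cb, r$b_idx), score = r$score)
}

#' k-mer distance matrix for guide-tree construction
#'
#' `d(i,j) = 1 - |shared k-mers| / min(|k-mers i|, |k-mers j|)` over distinct
#' k-mer sets; `d` lies in `[0,1]` with 0 on the diagonal.
#'
#' @param seqs character vector of sequences (or a record set, whose ids name
#'   the matrix).
#' @param k word length, `>= 1`; every sequence must be at least `k` long.
#' @export
kmer_distance_matrix <- function(seqs, k = 3L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    seqs <- seqs$residues
  } else ids <- names(seqs)
  if (k < 1L) stop("k must be >= 1")
  if (any(nchar(seqs) < k))
    stop("sequence(s) shorter than k = ", k)
  sets <- lapply(seqs, function(s) {
    L <- nchar(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    D[i, j] <- D[j, i] <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  D
}

# Average-of-pairs profile-profile merge. Gaps inside profile columns score
# gap_extend against residues and 0 against gaps; new gaps inserted between
# the two profiles pay the affine penalty in the DP.
merge_profiles <- function(A, B, scheme) {
  letters_ext <- c(rownames(scheme$substitution), GAP)
  ne <- length(letters_ext)
  Se <- matrix(scheme$gap_extend, ne, ne, dimnames = list(letters_ext, letters_ext))
  nr <- nrow(scheme$substitution)
  Se[1:nr, 1:nr] <- scheme$substitution
  Se[ne, ne] <- 0
  freq <- function(P) {
    FM <- matrix(0, ne, ncol(P))
    for (i in seq_len(ne)) FM[i, ] <- colSums(P == letters_ext[i])
    FM
  }
  S <- crossprod(freq(A), Se %*% freq(B)) / (nrow(A) * nrow(B))
  r <- nw_affine_cpp(S, scheme$gap_open, scheme$gap_extend)
  L <- length(r$a_idx)
  Ao <- matrix(GAP, nrow(A), L, dimnames = list(rownames(A), NULL))
  Bo <- matrix(GAP, nrow(B), L, dimnames = list(rownames(B), NULL))
  Ao[, r$a_idx > 0L] <- A[, r$a_idx[r$a_idx > 0L], drop = FALSE]
  Bo[, r$b_idx > 0L] <- B[, r$b_idx[r$b_idx > 0L], drop = FALSE]
  rbind(Ao, Bo)
}

#' Progressive multiple sequence alignment
#'
#' Desk-scale progressive aligner: a UPGMA guide tree on k-mer distances,
#' then profile-profile merges scored by average-of-pairs substitution score
#' with affine gaps. Deterministic for a fixed input; row order equals input
#' order. Not a ClustalW/MAFFT replacement for large or highly divergent
#' families — external alignments can be imported with [read_alignment()].
#'
#' @param records a sequence record set with at least one row.
#' @param scheme a [scoring_scheme()].
#' @param k guide-tree word length (clamped to the shortest sequence).
#' @return an `alignment` whose gap-stripped rows equal the input records.
#' @export
progressive_msa <- function(records, scheme = scoring_scheme(), k = 3L) {
  n <- nrow(records)
  if (n < 1L) stop("no sequences to align")
  for (i in seq_len(n))
    score_letters(scheme, strsplit(records$residues[i], "")[[1L]], records$id[i])
  if (n == 1L) return(new_alignment(records$id, records$residues))
  k <- max(1L, min(k, min(nchar(records$residues))))
  D <- kmer_distance_matrix(records, k)
  hc <- hclust(as.dist(D), method = "average")
  profiles <- vector("list", nrow(hc$merge))
  leaf_profile <- function(i) {
    matrix(strsplit(records$residues[i], "")[[1L]], nrow = 1L,
           dimnames = list(records$id[i], NULL))
  }
  node <- function(x) if (x < 0L) leaf_profile(-x) else profiles[[x]]
  for (s in seq_len(nrow(hc$merge)))
    profiles[[s]] <- merge_profiles(node(hc$merge[s, 1L]), node(hc$merge[s, 2L]),
                                    scheme)
  M <- profiles[[length(profiles)]]
  M <- M[records$id, , drop = FALSE]
  M <- M[, colSums(M != GAP) > 0L, drop = FALSE]
  matrix_to_alignment(M)
}

#' Read an alignment from aligned FASTA or Clustal
#'
#' @param path input file.
#' @param format `"afa"` (aligned FASTA) or `"clustal"`.
#' @return an `alignment`.
#' @export
read_alignment <- function(path, format = c("afa", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "afa") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no records in ", path)
    ids <- sub("\\s.*$", "", trimws(names(set)))
    seqs <- toupper(gsub("[ \t\r]", "", as.character(set)))
  } else {
    parsed <- read_clustal_lines(readLines(path, warn = FALSE), path)
    ids <- parsed$ids
    seqs <- parsed$seqs
  }
  w <- nchar(seqs)
  if (length(unique(w)) > 1L)
    stop("ragged alignment in ", path, "; offending id(s): ",
         paste(ids[w != max(w)], collapse = ", "))
  new_alignment(ids, seqs)
}

# Minimal interleaved Clustal parser: a "CLUSTAL" header line, then blocks of
# "<name> <chunk> [column count]" rows; conservation lines (leading space)
# and blank lines are skipped. Chunks accumulate per name in order of first
# appearance.
read_clustal_lines <- function(lines, path = "<clustal>") {
  if (!length(lines) || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
    stop("not a Clustal file (missing CLUSTAL header line): ", path)
  chunks <- list()
  for (ln in lines[-1L]) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 2L) stop("malformed Clustal line: ", ln)
    chunks[[f[1L]]] <- c(chunks[[f[1L]]], f[2L])
  }
  if (!length(chunks)) stop("no alignment rows in ", path)
  list(ids = names(chunks),
       seqs = toupper(vapply(chunks, paste, "", collapse = "")))
}

#' Write an alignment to aligned FASTA or Clustal
#'
#' @param a an `alignment`.
#' @param path output file.
#' @param format `"afa"` or `"clustal"` (interleaved 60-column blocks).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, format = c("afa", "clustal")) {
  format <- match.arg(format)
  if (format == "afa") {
    set <- Biostrings::BStringSet(a$seqs)
    names(set) <- a$ids
    Biostrings::writeXStringSet(set, path, width = 60L)
  } else {
    width <- 60L
    pad <- max(nchar(a$ids)) + 3L
    lines <- c("CLUSTAL multiple sequence alignment", "")
    for (start in seq(1L, n_col(a), by = width)) {
      chunk <- substr(a$seqs, start, min(start + width - 1L, n_col(a)))
      lines <- c(lines, paste0(formatC(a$ids, width = -pad), chunk), "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}
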