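#' Construct a set of sequence records
#'
#' A sequence record set is a plain `data.frame` with columns `id`,
#' `residues` and `description`. Ids are the first whitespace-delimited token
#' of a FASTA header and must be unique within a set; residues are upper-case
#' amino acids (the 20 standard letters plus `X` for ambiguity) with no gap
#' characters.
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of amino-acid strings.
#' @param description free-text annotation, recycled if scalar.
#' @return a `data.frame` with columns `id`, `residues`, `description`.
#' @export
seq_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (any(!nzchar(id)))
    stop("empty sequence id")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  if (any(nchar(residues) < 1L))
    stop("zero-length sequence for id(s): ",
         paste(id[nchar(residues) < 1L], collapse = ", "))
  validate_residues(residues, id, allow_gap = FALSE)
  data.frame(id = id, residues = residues,
             description = rep_len(as.character(description), length(id)),
             stringsAsFactors = FALSE)
}

# Residue alphabet check shared by readers and constructors. Reports the
# first offending character and its 1-based position per sequence.
validate_residues <- function(residues, id, allow_gap = FALSE) {
  allowed <- paste0(AMINO_ACIDS, collapse = "")
  allowed <- paste0(allowed, "X", if (allow_gap) "-")
  bad <- regexpr(sprintf("[^%s]", allowed), residues)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    ch <- substr(residues[i], bad[i], bad[i])
    if (ch == GAP)
      stop(sprintf("gap character in unaligned sequence '%s' at position %d",
                   id[i], bad[i]))
    stop(sprintf("illegal residue character '%s' in sequence '%s' at position %d",
                 ch, id[i], bad[i]))
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Residues are upper-cased and internal whitespace/carriage returns are
#' stripped. The record id is the first whitespace-delimited word of the
#' header; the remainder becomes the description.
#'
#' @param path path to a FASTA file.
#' @return a sequence record set (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in ", path)
  headers <- trimws(names(set))
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- toupper(gsub("[ \t\r]", "", as.character(set)))
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  if (any(nchar(res) < 1L))
    stop("empty sequence for id(s): ", paste(id[nchar(res) < 1L], collapse = ", "))
  validate_residues(res, id, allow_gap = FALSE)
  seq_records(id, res, desc)
}

#' Write sequence records to FASTA
#'
#' @param records a sequence record set.
#' @param path output path.
#' @param width line-wrap width, default 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  headers <- trimws(paste(records$id, records$description))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Combine record sets and remove duplicate sequences
#'
#' Records with identical residue strings collapse to the first-encountered
#' record; input order defines "first" and is preserved in the output. Two
#' records that share an id but differ in sequence are an error: the sets are
#' inconsistent and no safe merge exists. Near-identical sequences are kept —
#' a duplicate is exact string identity only.
#'
#' @param sets a single record set or a list of them, in priority order.
#' @return a list with `unique` (the merged record set) and `dropped` (a
#'   named list: kept id -> character vector of the ids collapsed into it).
#' @export
merge_and_deduplicate <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  all <- do.call(rbind, sets)
  kept <- all[0L, , drop = FALSE]
  seen_res <- character()   # residues of every record seen, named by id
  dropped <- list()
  for (r in seq_len(nrow(all))) {
    id <- all$id[r]
    res <- all$residues[r]
    if (id %in% names(seen_res) && !identical(seen_res[[id]], res))
      stop("id '", id, "' occurs with two different sequences across sets")
    seen_res[[id]] <- res
    j <- match(res, kept$residues)
    if (is.na(j)) {
      kept <- rbind(kept, all[r, , drop = FALSE])
    } else {
      keeper <- kept$id[j]
      dropped[[keeper]] <- c(dropped[[keeper]], id)
    }
  }
  rownames(kept) <- NULL
  list(unique = kept, dropped = dropped)
}
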