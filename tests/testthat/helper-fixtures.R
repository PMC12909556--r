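# Shared fixture builders: everything is generated in code, no data files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# write a string to a temp file, returning the path
textConnection_file <- function(text, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# random gapped alignment: n rows over width columns, gap probability p
random_alignment <- function(n, width, p_gap = 0.3, ids = paste0("s", seq_len(n))) {
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(AA20, width, replace = TRUE)
    gaps <- runif(width) < p_gap
    # keep at least one residue so rows stay non-degenerate
    if (all(gaps)) gaps[sample(width, 1L)] <- FALSE
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, "")
  new_alignment(ids, seqs)
}

# brute-force oracle for the reference position map: scan the row, counting
# non-gap characters
scan_position_map <- function(row) {
  chars <- strsplit(row, "")[[1]]
  cols <- integer(0)
  for (j in seq_along(chars)) if (chars[j] != "-") cols <- c(cols, j - 1L)
  cols
}

# small cluster set reused by coordmap/sitecluster tests (positions on a
# short toy reference)
toy_clusters <- function() {
  list(list(name = "A", positions = c(2L, 5L), role = ""),
       list(name = "B", positions = c(3L, 7L, 8L), role = ""))
}

# default-config pipeline run on a simulated default scenario
run_default_scenario <- function(seed, leaves_per_clade = 6L, out_dir = tempfile()) {
  fam <- simulate_family(default_vao_scenario(seed = seed,
                                              leaves_per_clade = leaves_per_clade))
  cfg <- list(records = fam$records, ref_id = "C4_leaf01",
              loop = c(fam$spec$loop$start, fam$spec$loop$end),
              outgroup_ids = grep("^BO", fam$records$id, value = TRUE),
              k_clades = 7, out_dir = out_dir, seed = seed)
  list(fam = fam, result = run_pipeline(cfg))
}
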