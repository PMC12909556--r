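#' Run the full family-analysis pipeline
#'
#' Combine and deduplicate sequences, align (or import an alignment), map
#' reference numbering, extract fingerprints, build a neighbor-joining tree
#' (or import one), root on the outgroup, cut clades, call the loop, assign
#' subfamilies, and rank candidates by active-site divergence. Every artifact
#' is written to `out_dir`; reruns with an identical config reproduce
#' identical files.
#'
#' @param config a named list (or path to a JSON/YAML file) with fields:
#'   `fasta` (path, or a record set under `records`), `ref_id`,
#'   `cluster_config` (path; `NULL` for the packaged default), `loop`
#'   (`c(start, end)` on reference numbering — required), `outgroup_ids`,
#'   `k_clades` or `membership` (named vector or 2-column TSV path),
#'   `loop_threshold` (default 0.5), `alignment` (optional precomputed
#'   alignment path), `tree` (optional Newick path), `rank_scope` (default
#'   `"all"`), `out_dir`, `seed` (default 1).
#' @return invisibly, a list with every intermediate result (`records`,
#'   `dedup`, `alignment`, `position_map`, `fingerprints`, `tree`, `clades`,
#'   `profiles`, `loop_calls`, `subfamilies`, `candidates`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("[config] out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- stage("input", {
    if (!is.null(cfg$records)) cfg$records
    else {
      paths <- cfg$fasta
      if (is.null(paths)) stop("fasta (or records) is required")
      do.call(rbind, lapply(paths, read_fasta))
    }
  })
  dedup <- stage("dedup", merge_and_deduplicate(list(records)))
  records <- dedup$unique

  aln <- stage("align", {
    if (!is.null(cfg$alignment)) {
      fmt <- if (grepl("\\.aln$", cfg$alignment)) "clustal" else "afa"
      a <- read_alignment(cfg$alignment, fmt)
      missing <- setdiff(records$id, a$ids)
      if (length(missing))
        stop("imported alignment lacks sequence(s): ",
             paste(missing, collapse = ", "))
      a
    } else {
      if (nrow(records) < 2L)
        stop("need at least 2 sequences to align (got ", nrow(records), ")")
      progressive_msa(records)
    }
  })

  ref_id <- cfg$ref_id
  clus_cfg <- stage("clusters", read_cluster_config(cfg$cluster_config))
  if (is.null(ref_id)) ref_id <- clus_cfg$reference_id
  pm <- stage("coordmap", build_position_map(aln, ref_id))
  stage("coordmap", {
    ref_res <- gsub(GAP, "", aln$seqs[match(ref_id, aln$ids)], fixed = TRUE)
    check_reference_residues(ref_res, clus_cfg)
  })
  fm <- stage("fingerprint", fingerprint_matrix(aln, clus_cfg, ref_id))

  tree <- stage("tree", {
    if (!is.null(cfg$tree)) {
      t <- read_newick(cfg$tree)
      missing <- setdiff(aln$ids, t$tip.label)
      if (length(missing)) stop("imported tree lacks leaf/leaves: ",
                                paste(missing, collapse = ", "))
      t
    } else neighbor_joining(p_distance_matrix(aln))
  })
  outgroup <- as.character(cfg$outgroup_ids)
  if (!length(outgroup)) stop("[root] outgroup_ids is required")
  rooted <- stage("root", root_with_outgroup(tree, outgroup))

  clades <- stage("clades", {
    memb <- cfg$membership
    if (!is.null(memb) && length(memb) == 1L && is.character(memb) &&
        file.exists(memb)) {
      tab <- read.table(memb, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      memb <- stats::setNames(tab[[2L]], tab[[1L]])
    }
    extract_clades(rooted, k = cfg$k_clades, membership = memb,
                   outgroup_ids = outgroup)
  })

  profiles <- stage("profiles", clade_profiles(fm, clades))
  loop <- as.integer(cfg$loop)
  if (length(loop) != 2L) stop("[loop] config field 'loop' must be c(start, end)")
  thr <- if (is.null(cfg$loop_threshold)) 0.5 else cfg$loop_threshold
  loop_calls <- stage("loop", detect_loop(aln, loop, pm, thr))
  subfam <- stage("subfamilies", assign_subfamilies(clades, loop_calls))

  candidates <- stage("candidates", {
    ref_fp <- get_fingerprint(fm, ref_id)
    absent_sf <- names(subfam$loop_state)[subfam$loop_state == "absent"]
    within <- if (length(absent_sf)) unlist(subfam$subfamilies[absent_sf])
              else names(clades)
    scope <- if (is.null(cfg$rank_scope)) "all" else cfg$rank_scope
    rank_candidates(fm, ref_fp, clades, within, scope)
  })

  stage("write", {
    write_alignment(aln, file.path(out_dir, "alignment.afa"), "afa")
    write_newick(rooted, file.path(out_dir, "tree.nwk"))
    write_fingerprint_tsv(fm, file.path(out_dir, "fingerprints.tsv"))
    write.table(profiles, file.path(out_dir, "clade_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(loop_calls, file.path(out_dir, "loop_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(subfamilies = subfam$subfamilies,
           loop_state = as.list(subfam$loop_state),
           clade_state = as.list(subfam$clade_state),
           unassigned = subfam$unassigned),
      file.path(out_dir, "subfamilies.json"), auto_unbox = TRUE, pretty = TRUE)
    write.table(candidates, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_family_overview(rooted, fm, clades, subfam, outgroup,
                          file.path(out_dir, "family_overview.tsv"))
    write_run_log(cfg, file.path(out_dir, "run_log.json"))
  })

  invisible(list(records = records, dedup = dedup, alignment = aln,
                 position_map = pm, fingerprints = fm, tree = rooted,
                 clades = clades, profiles = profiles, loop_calls = loop_calls,
                 subfamilies = subfam, candidates = candidates,
                 out_dir = out_dir))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead")
      config <- yaml::yaml.load_file(config)
    } else {
      config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a JSON/YAML path")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(config$loop_threshold) &&
      (config$loop_threshold < 0 || config$loop_threshold > 1))
    stop("loop_threshold must lie in [0, 1]")
  config
}

# One row per leaf in rooted-tree display order: clade, subfamily, loop
# occupancy and per-cluster motifs — the tabular analogue of a tree-linked
# fingerprint figure.
write_family_overview <- function(rooted, fm, clades, subfam, outgroup, path) {
  n_tip <- length(rooted$tip.label)
  tip_order <- rooted$tip.label[rooted$edge[rooted$edge[, 2L] <= n_tip, 2L]]
  clade_of <- stats::setNames(rep(names(clades), lengths(clades)),
                              unlist(clades, use.names = FALSE))
  sf_of <- stats::setNames(rep(names(subfam$subfamilies),
                               lengths(subfam$subfamilies)),
                           unlist(subfam$subfamilies, use.names = FALSE))
  cl_names <- unique(fm$scaffold$cluster)
  motifs <- sapply(cl_names, function(cl)
    apply(fm$symbols[, fm$scaffold$cluster == cl, drop = FALSE], 1L,
          paste, collapse = ""))
  rows <- match(tip_order, rownames(fm$symbols))
  clade_lab <- ifelse(tip_order %in% outgroup, "outgroup",
                      unname(clade_of[tip_order]))
  df <- data.frame(id = tip_order,
                   clade = clade_lab,
                   subfamily = ifelse(is.na(sf_of[clade_lab]), "",
                                      sf_of[clade_lab]),
                   motifs[rows, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", "clade", "subfamily", paste0(cl_names, "_motif"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_run_log <- function(cfg, path) {
  # hash the analysis parameters only: where the artifacts land is not part
  # of the scientific configuration
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  ser <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                          force = TRUE)
  tmp <- tempfile()
  writeLines(ser, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(package = "cladefp",
         version = as.character(utils::packageVersion("cladefp")),
         seed = cfg$seed, config_md5 = hash),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
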