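# build a PsVAO-numbering-faithful toy reference: random residues with the
# canonical states planted at the 21 cluster positions
canonical_reference <- function(len = 520, seed = 5) {
  set.seed(seed)
  cfg <- read_cluster_config()
  chars <- sample(AA20, len, replace = TRUE)
  chars[as.integer(names(cfg$expected_reference_residues))] <-
    cfg$expected_reference_residues
  list(cfg = cfg, residues = paste(chars, collapse = ""))
}

test_that("packaged default config defines the five VAO clusters", {
  cfg <- read_cluster_config()
  names <- vapply(cfg$clusters, `[[`, "", "name")
  sizes <- vapply(cfg$clusters, function(x) length(x$positions), 1L)
  expect_equal(names, c("A", "H", "P", "T", "W"))
  expect_equal(sizes, c(4L, 3L, 5L, 3L, 6L))
  expect_equal(sum(sizes), 21L)
  scaf <- cladefp:::cluster_scaffold(cfg$clusters)
  expect_equal(scaf$position[scaf$cluster == "A"], c(316L, 413L, 469L, 470L))
  expect_equal(scaf$position[scaf$cluster == "W"],
               c(170L, 188L, 312L, 409L, 410L, 457L))
})

test_that("position map follows reference numbering through gaps", {
  a <- new_alignment(c("r", "o"), c("MKLVY", "MKLVY"))
  pm <- build_position_map(a, "r")
  expect_equal(unname(pm$pairs), 0:4)           # gap-free: p -> p-1

  a2 <- new_alignment("r", "M-K")
  pm2 <- build_position_map(a2, "r")
  expect_equal(pm2$pairs, c("1" = 0L, "2" = 2L))
  expect_equal(pm2$ref_length, 2L)

  expect_error(build_position_map(a, "nope"), "'nope'")
})

test_that("position map equals the linear-scan oracle on random alignments", {
  set.seed(202)
  for (i in 1:500) {
    a <- random_alignment(sample(2:4, 1), sample(5:40, 1), p_gap = 0.35)
    pm <- build_position_map(a, "s1")
    oracle <- scan_position_map(a$seqs[1])
    expect_equal(unname(pm$pairs), oracle)
    expect_equal(as.integer(names(pm$pairs)), seq_along(oracle))
    expect_true(all(diff(pm$pairs) > 0))        # strictly monotone
  }
})

test_that("the reference fingerprint reproduces the canonical residues", {
  ref <- canonical_reference()
  a <- new_alignment("PsVAO", ref$residues)
  pm <- build_position_map(a, "PsVAO")
  fp <- extract_fingerprint(a, pm, ref$cfg$clusters, "PsVAO")
  A <- fp[fp$cluster == "A", ]
  expect_equal(A$position, c(316L, 413L, 469L, 470L))
  expect_equal(A$symbol, c("L", "W", "V", "C"))
  exp <- ref$cfg$expected_reference_residues
  expect_equal(fp$symbol, unname(exp[as.character(fp$position)]))
  expect_silent(check_reference_residues(ref$residues, ref$cfg))
})

test_that("fingerprints pick up substitutions and deletions in homologs", {
  ref <- canonical_reference()
  hom <- ref$residues
  substr(hom, 424, 424) <- "A"                  # clade-C6-style P-cluster swap
  substr(hom, 470, 470) <- "E"                  # C6 A-cluster glutamate
  a <- new_alignment(c("PsVAO", "hom"), c(ref$residues, hom))
  pm <- build_position_map(a, "PsVAO")
  fp <- extract_fingerprint(a, pm, ref$cfg$clusters, "hom")
  expect_equal(fp$symbol[fp$cluster == "P" & fp$position == 424], "A")
  expect_equal(fp$symbol[fp$cluster == "A" & fp$position == 470], "E")
  # all other positions unchanged
  expect_equal(sum(fp$symbol != get_fingerprint(
    fingerprint_matrix(a, ref$cfg$clusters, "PsVAO"), "PsVAO")$symbol), 2)

  gapped <- new_alignment(c("PsVAO", "g"),
                          c(ref$residues, strrep("-", nchar(ref$residues))))
  pmg <- build_position_map(gapped, "PsVAO")
  fpg <- extract_fingerprint(gapped, pmg, ref$cfg$clusters, "g")
  expect_true(all(fpg$symbol == "-"))
})

test_that("out-of-range cluster positions are rejected with the offenders", {
  a <- new_alignment(c("r", "o"), c("MKLVYAGH", "MKLVYAGH"))
  pm <- build_position_map(a, "r")
  clusters <- list(list(name = "A", positions = c(2L, 12L, 30L), role = ""))
  expect_error(extract_fingerprint(a, pm, clusters, "o"), "12, 30")
})

test_that("fingerprint distance counts mismatches; gaps and X never match", {
  ref <- canonical_reference()
  cfg <- ref$cfg
  c6 <- ref$residues
  for (sw in list(c(470, "E"), c(61, "F"), c(468, "V"), c(424, "A"),
                  c(409, "E")))
    substr(c6, as.integer(sw[1]), as.integer(sw[1])) <- sw[2]
  a <- new_alignment(c("PsVAO", "c6", "gap"),
                     c(ref$residues, c6, strrep("-", nchar(ref$residues))))
  fm <- fingerprint_matrix(a, cfg, "PsVAO")
  f_ref <- get_fingerprint(fm, "PsVAO")
  f_c6 <- get_fingerprint(fm, "c6")
  f_gap <- get_fingerprint(fm, "gap")

  expect_equal(fingerprint_distance(f_ref, f_ref), 0)
  expect_equal(fingerprint_distance(f_ref, f_c6), 5)
  # oracle: direct per-position comparison
  expect_equal(sum(f_ref$symbol != f_c6$symbol), 5)
  expect_equal(fingerprint_distance(f_ref, f_gap), 21)
  expect_equal(fingerprint_distance(f_gap, f_gap), 21)   # gaps self-mismatch
  expect_equal(fingerprint_distance(f_ref, f_c6, scope = "A"), 1)
  expect_error(fingerprint_distance(f_ref, f_c6, scope = "Z"), "no positions")
})

test_that("fingerprint distance is symmetric and satisfies the triangle
           inequality; identity holds on gap-free fingerprints", {
  set.seed(303)
  cfg <- read_cluster_config()
  scaf <- cladefp:::cluster_scaffold(cfg$clusters)
  mk_fp <- function(symbols) {
    out <- cbind(scaf, data.frame(symbol = symbols, stringsAsFactors = FALSE))
    class(out) <- c("fingerprint", "data.frame")
    out
  }
  for (i in 1:50) {
    syms <- replicate(3, sample(c(AA20, "X", "-"), nrow(scaf), replace = TRUE,
                                prob = c(rep(1, 20), 0.3, 0.5)),
                      simplify = FALSE)
    f <- mk_fp(syms[[1]]); g <- mk_fp(syms[[2]]); h <- mk_fp(syms[[3]])
    expect_equal(fingerprint_distance(f, g), fingerprint_distance(g, f))
    expect_lte(fingerprint_distance(f, h),
               fingerprint_distance(f, g) + fingerprint_distance(g, h))
    clean <- mk_fp(sample(AA20, nrow(scaf), replace = TRUE))
    expect_equal(fingerprint_distance(clean, clean), 0)
  }
})

test_that("gap-only columns never change fingerprints", {
  set.seed(404)
  ref <- canonical_reference(len = 510)
  hom <- ref$residues
  substr(hom, 61, 61) <- "M"
  a <- new_alignment(c("PsVAO", "hom"), c(ref$residues, hom))
  fm1 <- fingerprint_matrix(a, ref$cfg, "PsVAO")
  # splice gap-only columns at random points
  ins <- sort(sample(0:nchar(ref$residues), 5))
  splice <- function(s) {
    parts <- substring(s, c(1, ins + 1), c(ins, nchar(s)))
    paste(parts, collapse = "-")
  }
  a2 <- new_alignment(a$ids, vapply(a$seqs, splice, ""))
  a2 <- drop_allgap_columns(a2)   # construction invariant: no all-gap columns
  fm1b <- fingerprint_matrix(a2, ref$cfg, "PsVAO")
  expect_equal(fm1b$symbols, fm1$symbols)

  a3 <- new_alignment(a$ids, vapply(a$seqs, splice, ""))
  fm2 <- fingerprint_matrix(a3, ref$cfg, "PsVAO")
  expect_equal(unname(fm2$symbols), unname(fm1$symbols))
})

test_that("a wrong reference triggers the expected-residue warning", {
  ref <- canonical_reference()
  shifted <- paste0("G", ref$residues)  # off-by-one numbering
  expect_warning(check_reference_residues(shifted, ref$cfg), "expected")
})
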