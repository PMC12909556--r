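# small fingerprint matrix fixture on the toy clusters (positions 2,5 / 3,7,8
# of an 8-residue reference)
toy_fm <- function(rows) {
  ref <- "MKLVYAGH"
  a <- new_alignment(c("ref", names(rows)), c(ref, unlist(rows)))
  fingerprint_matrix(a, toy_clusters(), "ref")
}

test_that("clade profiles report modal symbols and conservation", {
  fm <- toy_fm(list(m1 = "MKLVYAGH", m2 = "MKLVYAGH", m3 = "MKLVYAGH"))
  pr <- clade_profiles(fm, list(c1 = c("m1", "m2", "m3")))
  expect_true(all(pr$conservation == 1))
  expect_equal(pr$consensus, c("K", "Y", "L", "G", "H"))

  # tie {T,T,V,V}: alphabetical tie-break, conservation 0.5
  fm2 <- toy_fm(list(m1 = "MTLVYAGH", m2 = "MTLVYAGH",
                     m3 = "MVLVYAGH", m4 = "MVLVYAGH"))
  pr2 <- clade_profiles(fm2, list(c1 = paste0("m", 1:4)))
  at2 <- pr2[pr2$cluster == "A" & pr2$position == 2, ]
  expect_equal(at2$consensus, "T")
  expect_equal(at2$conservation, 0.5)

  # gap sorts last in ties
  fm3 <- toy_fm(list(m1 = "M-LVYAGH", m2 = "MKLVYAGH"))
  pr3 <- clade_profiles(fm3, list(c1 = c("m1", "m2")))
  expect_equal(pr3$consensus[pr3$position == 2], "K")

  expect_error(clade_profiles(fm, list(c1 = character(0))), "empty")
  expect_error(clade_profiles(fm, list(c1 = "ghost")), "ghost")
})

test_that("loop detection reads occupancy off mapped reference columns", {
  ref <- "MKLVYAGHWW"
  a <- new_alignment(c("ref", "full", "gone", "half"),
                     c(ref, "MKAVYAGHWW", "MK----GHWW", "MKL--AGHWW"))
  pm <- build_position_map(a, "ref")
  calls <- detect_loop(a, c(3, 6), pm, threshold = 0.5)
  expect_equal(calls$occupancy, c(1, 1, 0, 0.5))
  expect_equal(calls$present, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(detect_loop(a, c(5, 20), pm), "outside")

  # occupancy is invariant to gap-only columns inserted elsewhere
  a2 <- new_alignment(a$ids, paste0(substr(a$seqs, 1, 8), "--",
                                    substr(a$seqs, 9, 10)))
  pm2 <- build_position_map(a2, "ref")
  expect_equal(detect_loop(a2, c(3, 6), pm2, 0.5)$occupancy, calls$occupancy)
})

test_that("subfamily assignment groups clades by loop state", {
  clades <- c(lapply(1:6, function(i) paste0("C", i, "_", 1:4)),
              list(paste0("C7_", 1:4)))
  names(clades) <- paste0("C", 1:7)
  ids <- unlist(clades)
  calls <- data.frame(seq_id = ids,
                      occupancy = ifelse(grepl("^C7", ids), 0, 1),
                      present = !grepl("^C7", ids))
  sf <- assign_subfamilies(clades, calls)
  expect_length(sf$subfamilies, 2)
  expect_equal(lengths(sf$subfamilies), c(SF1 = 6L, SF2 = 1L))
  expect_equal(sf$loop_state, c(SF1 = "present", SF2 = "absent"))
  expect_equal(sf$subfamilies$SF2, "C7")

  # all present -> one subfamily
  all_pres <- data.frame(seq_id = ids, occupancy = 1, present = TRUE)
  expect_length(assign_subfamilies(clades, all_pres)$subfamilies, 1)

  # a clade at 50% presence is mixed and unassigned
  calls$present[calls$seq_id %in% clades$C3] <- c(TRUE, TRUE, FALSE, FALSE)
  sf2 <- assign_subfamilies(clades, calls)
  expect_equal(sf2$unassigned, "C3")
  expect_false("C3" %in% unlist(sf2$subfamilies))
  expect_equal(lengths(sf2$subfamilies), c(SF1 = 5L, SF2 = 1L))

  # boundary rule: >= 90% present / <= 10% absent
  calls$present[calls$seq_id %in% clades$C3] <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(assign_subfamilies(clades, calls)$clade_state[["C3"]], "mixed")
})

test_that("subfamily count is invariant to clade relabeling and order", {
  res <- run_default_scenario(seed = 3, leaves_per_clade = 4)$result
  sf1 <- res$subfamilies
  clades <- res$clades
  relabeled <- rev(clades)
  names(relabeled) <- paste0("grp", seq_along(relabeled))
  relabeled <- lapply(relabeled, rev)
  sf2 <- assign_subfamilies(relabeled, res$loop_calls)
  expect_equal(length(sf2$subfamilies), length(sf1$subfamilies))
  expect_setequal(unname(lengths(sf2$subfamilies)),
                  unname(lengths(sf1$subfamilies)))
})

test_that("candidate ranking orders by fingerprint divergence", {
  # planted family: C6 carries 5 substitutions, C2 carries 1
  res <- run_default_scenario(seed = 6, leaves_per_clade = 4)
  fm <- res$result$fingerprints
  clades <- res$result$clades
  ref_fp <- get_fingerprint(fm, "C4_leaf01")
  clade_of <- function(lab) {
    hits <- vapply(clades, function(m) any(grepl(lab, m)), TRUE)
    names(clades)[hits]
  }
  ranked <- rank_candidates(fm, ref_fp, clades,
                            within = c(clade_of("^C6_"), clade_of("^C2_")))
  c6 <- grepl("^C6_", ranked$seq_id)
  expect_equal(ranked$distance[c6], rep(5, 4))
  expect_equal(ranked$distance[!c6], rep(1, 4))
  expect_true(all(which(c6) < which(!c6)))        # C6 ranks above C2
  # ties broken by id
  expect_equal(ranked$seq_id[c6], sort(ranked$seq_id[c6]))

  # reference's own clade ranks at distance 0
  own <- rank_candidates(fm, ref_fp, clades, within = clade_of("^C4_"))
  expect_equal(own$distance[own$seq_id == "C4_leaf01"], 0)
  expect_equal(own$distance[nrow(own)], 0)

  # scope restricted to the A cluster bounds the distance by cluster size
  rankedA <- rank_candidates(fm, ref_fp, clades,
                             within = names(clades), scope = "A")
  expect_true(all(rankedA$distance <= 4))

  expect_error(rank_candidates(fm, ref_fp, clades, within = character(0)),
               "empty")
})
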