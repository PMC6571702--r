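test_that("variant library matches the designed histidine counts", {
  lib <- hst5_variants()
  expect_equal(lib$n_his,
               vapply(lib$sequence,
                      function(s) sum(strsplit(s, "")[[1]] == "H"), 1L),
               ignore_attr = TRUE)
  expect_equal(nchar(lib$sequence), rep(24L, 6), ignore_attr = TRUE)
  for (v in c("WT", "RAN", "DZM", "ZM", "2H", "DH")) {
    expect_equal(build_peptide(v)$n_his,
                 c(WT = 7L, RAN = 7L, DZM = 4L, ZM = 3L, `2H` = 2L,
                   DH = 0L)[[v]])
  }
  # same amino-acid composition for WT and its randomised permutation
  comp <- function(s) sort(strsplit(s, "")[[1]])
  expect_equal(comp(build_peptide("WT")$sequence),
               comp(build_peptide("RAN")$sequence))
  expect_error(build_peptide("XYZ"), "valid names")
})

test_that("wild type carries both motifs and the expected sticky set", {
  wt <- build_peptide("WT")
  expect_identical(substr(wt$sequence, 3, 8), "HAKRHH")   # N-terminal motif
  expect_identical(substr(wt$sequence, 15, 19), "HEKHH")  # HExxH zinc motif
  expect_true(wt$motif_intact)
  # residues H3 H7 H8 H15 E16 H18 H19 H21
  expect_equal(wt$sticky_residues, c(3L, 7L, 8L, 15L, 16L, 18L, 19L, 21L))
  # bead indices shift by one for the N-terminal bead
  expect_equal(sticky_set(wt, zinc_present = TRUE),
               c(3L, 7L, 8L, 15L, 16L, 18L, 19L, 21L) + 1L)
  expect_identical(sticky_set(wt, zinc_present = FALSE), integer(0))
  expect_identical(sticky_set(build_peptide("DH"), TRUE), integer(0))
})

test_that("sticky-set size is n_his plus one when the zinc motif is intact", {
  for (v in c("WT", "RAN", "DZM", "ZM", "2H", "DH")) {
    pep <- build_peptide(v)
    expected <- pep$n_his + as.integer(pep$motif_intact)
    expect_length(sticky_set(pep, TRUE), expected)
  }
  # motif survives only in WT and ZM
  expect_true(build_peptide("ZM")$motif_intact)
  expect_false(build_peptide("RAN")$motif_intact)
  expect_false(build_peptide("DZM")$motif_intact)
  expect_false(build_peptide("2H")$motif_intact)
})

test_that("charge assignment gives the hand-computed net charges", {
  wt <- build_peptide("WT")
  z <- assign_charges(wt)
  expect_length(z, 26)          # 24 residues + 2 terminal beads
  expect_identical(z[1], 1L)    # N-terminus
  expect_identical(z[26], -1L)  # C-terminus
  expect_identical(sum(z), 5L)  # 4K + 3R - D - E + termini
  expect_identical(sum(assign_charges(wt, "protonated-his")), 12L)
  # all-Gln variant has the identical charge pattern at neutral pH
  expect_identical(assign_charges(build_peptide("DH")), z)
  # idempotence: same input, same output
  expect_identical(assign_charges(wt), assign_charges(wt))
  for (v in c("RAN", "DZM", "ZM", "2H")) {
    expect_identical(sum(assign_charges(build_peptide(v))), 5L)
  }
  bad <- build_peptide("WT")
  bad$residues[3] <- "Z"
  expect_error(assign_charges(bad), "unknown residue")
})

test_that("bead chain topology follows the model", {
  ch <- bead_chain(build_peptide("WT"), zinc_present = TRUE)
  expect_equal(ch$n_beads, 26)
  expect_true(all(ch$radii == 2))
  expect_equal(nrow(ch$bonds), 25)
  expect_true(all(ch$bonds[, 2] - ch$bonds[, 1] == 1))
  expect_equal(sum(ch$sticky), 8)
  expect_false(any(bead_chain(build_peptide("WT"))$sticky))
})

test_that("build_system places the concentration-implied chain count", {
  wt <- build_peptide("WT")
  sys1 <- build_system(wt, 450, concentration = 1, seed = 1)
  expect_true(sys1$n_chains %in% 16:18)
  sys2 <- build_system(wt, 450, concentration = 2, seed = 1)
  expect_equal(sys2$n_chains, 2 * sys1$n_chains, tolerance = 0.06)
  expect_equal(build_system(wt, 450, n_chains = 16, seed = 1)$n_chains, 16)
  expect_error(build_system(wt, 450), "concentration")
})

test_that("initial configurations are overlap-free and reproducible", {
  wt <- build_peptide("WT")
  sys <- build_system(wt, 80, n_chains = 4, seed = 7)
  # brute-force all-pairs minimum-image check
  X <- sys$coords
  dmin <- Inf
  L <- sys$chain$n_beads
  chain_of <- rep(seq_len(4), each = L)
  idx_of <- rep(seq_len(L), 4)
  for (i in seq_len(nrow(X) - 1)) {
    for (j in (i + 1):nrow(X)) {
      if (chain_of[i] == chain_of[j] && abs(idx_of[i] - idx_of[j]) == 1) next
      d <- sqrt(sum(mi_vec(X[i, ] - X[j, ], 80)^2))
      dmin <- min(dmin, d)
    }
  }
  expect_gte(dmin, 4)
  sys_b <- build_system(wt, 80, n_chains = 4, seed = 7)
  expect_identical(sys$coords, sys_b$coords)
  sys_c <- build_system(wt, 80, n_chains = 4, seed = 8)
  expect_false(identical(sys$coords, sys_c$coords))
  # impossible packing errors out
  expect_error(build_system(wt, 22, n_chains = 40, seed = 1, max_tries = 5),
               "could not place")
})
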