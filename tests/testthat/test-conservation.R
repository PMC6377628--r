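test_that("information content matches closed forms", {
  # single-residue column: H = 0, R = log2(20)
  aln <- paste0(rep("L", 20), "A")
  aln <- vapply(seq_len(20), function(i) "LA", character(1))
  p <- columnProfiles(aln)
  expect_equal(p[[1]]$entropy_bits, 0)
  expect_equal(p[[1]]$information_bits, log2(20))
  expect_equal(unname(p[[1]]$letter_heights["L"]), log2(20))

  # uniform column over all 20 residues: H = log2(20), R = 0
  rows <- paste0(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), "L")
  pu <- columnProfiles(rows)
  expect_equal(pu[[1]]$entropy_bits, log2(20))
  expect_equal(pu[[1]]$information_bits, 0)

  # half L / half I: H = 1, R = log2(20) - 1
  half <- c(rep("LA", 10), rep("IA", 10))
  ph <- columnProfiles(half)
  expect_equal(ph[[1]]$entropy_bits, 1)
  expect_equal(ph[[1]]$information_bits, log2(20) - 1)
  expect_equal(unname(ph[[1]]$letter_heights[c("I", "L")]),
               rep(0.5 * (log2(20) - 1), 2))
})

test_that("gap handling follows the selected policy", {
  rows <- c("L-", "L-", "LA", "LA")
  pex <- columnProfiles(rows, gapPolicy = "exclude")
  expect_identical(pex[[2]]$gap_count, 2L)
  expect_equal(pex[[2]]$information_bits, log2(20))  # all non-gaps are A
  p21 <- columnProfiles(rows, gapPolicy = "count_as_21st")
  expect_equal(p21[[2]]$entropy_bits, 1)
  expect_equal(p21[[2]]$information_bits, log2(21) - 1)

  allGap <- c("-A", "-A", "-A")
  pg <- columnProfiles(allGap)
  expect_true(pg[[1]]$all_gap)
  expect_equal(pg[[1]]$information_bits, 0)
})

test_that("profiles are invariant to row permutation", {
  set.seed(7)
  rows <- vapply(1:30, function(i)
    paste(sample(c("A", "L", "G", "S", "-"), 12, TRUE), collapse = ""),
    character(1))
  p1 <- columnProfiles(rows)
  p2 <- columnProfiles(rows[sample.int(30)])
  expect_equal(vapply(p1, `[[`, numeric(1), "information_bits"),
               vapply(p2, `[[`, numeric(1), "information_bits"))
  expect_equal(vapply(p1, `[[`, integer(1), "gap_count"),
               vapply(p2, `[[`, integer(1), "gap_count"))
})

test_that("small-sample correction lowers information content", {
  rows <- rep("LA", 10)
  raw <- columnProfiles(rows)[[1]]$information_bits
  cor <- columnProfiles(rows, correction = TRUE)[[1]]$information_bits
  expect_lt(cor, raw)
  expect_equal(raw - cor, 19 / (2 * 10 * log(2)))
})

test_that("information profile table maps reference coordinates", {
  aln <- readChannelAlignment(writeTempFasta(list(ref = "ML-KA",
                                                  oth = "MLGKA")))
  tab <- informationProfile(aln, referenceRow = "ref")
  expect_identical(tab$ref_position, c(1L, 2L, NA, 3L, 4L))
  expect_identical(tab$ref_residue[3], NA_character_)
  expect_error(informationProfile(aln, referenceRow = "nope"),
               "reference row")
})

test_that("census tallies hinge classes and TM2.6 residues", {
  maps <- lapply(list(c("GIP", "L"), c("GVP", "L"), c("MIP", "V")),
                 function(sp) {
                   fx <- k2pFixture(3, hingeMotif = sp[1], tm26Residue = sp[2])
                   fx$truth$tm2map
                 })
  cen <- hingeCensus(maps)
  expect_identical(unname(cen$motif_class_counts["canonical_GIP"]), 1L)
  expect_identical(unname(cen$motif_class_counts["valine_variant"]), 1L)
  expect_identical(unname(cen$motif_class_counts["degenerate"]), 1L)
  expect_identical(cen$tm26_residue_counts, c(L = 2L, V = 1L))
  expect_identical(cen$n_failed, 0L)

  # input order invariance
  cen2 <- hingeCensus(rev(maps))
  expect_identical(cen$motif_class_counts, cen2$motif_class_counts)
  expect_identical(cen$tm26_residue_counts, cen2$tm26_residue_counts)

  # failures are tallied, not raised
  cen3 <- hingeCensus(c(maps, list(simpleError("bad channel"))))
  expect_identical(cen3$n_failed, 1L)
  expect_identical(cen3$n_channels, 4L)
  expect_error(hingeCensus(list()), "at least one")
})
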