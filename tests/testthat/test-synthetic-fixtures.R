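test_that("fixtures are deterministic per seed and validate their spec", {
  a <- k2pFixture(12)
  b <- k2pFixture(12)
  expect_identical(as.character(a$sequence), as.character(b$sequence))
  expect_false(identical(as.character(k2pFixture(13)$sequence),
                         as.character(a$sequence)))
  expect_error(k2pFixture(1, hingeMotif = "QQQ"), "grammar tier")
  expect_error(k2pFixture(1, sf1Text = "AAAAA"), "selectivity-filter")
  expect_error(k2pFixture(1, tm26Residue = "!"), "amino-acid")
  expect_error(k2pFixture(1, lengths = list(tm2 = c(10L, 10L))),
               "too short")
})

test_that("fixture truth is internally consistent", {
  fx <- k2pFixture(77, hingeMotif = "GVP", tm26Residue = "M")
  s <- as.character(fx$sequence)[[1]]
  tab <- architectureTable(fx$truth$architecture)
  sf1 <- tab[tab$element == "SF1", ]
  expect_identical(substr(s, sf1$start, sf1$end), sf1$matched_text)
  m <- fx$truth$tm2map
  expect_identical(substr(s, tm26Position(m), tm26Position(m)), "M")
  hingePos <- m@positions[["TM2.1"]]
  expect_identical(substr(s, hingePos, hingePos + 2), "GVP")
  tm2 <- tab[tab$element == "TM2", ]
  expect_true(hingePos >= tm2$start && tm26Position(m) <= tm2$end)
})

test_that("reverse translation round-trips under the standard code", {
  expect_identical(as.character(makeCds("MK"))[[1]], "ATGAAA")
  fx <- k2pFixture(8)
  cdsL <- makeCds(fx$sequence)
  expect_identical(translateCds(cdsL), as.character(fx$sequence)[[1]])
  cdsR1 <- makeCds(fx$sequence, "random", seed = 4)
  cdsR2 <- makeCds(fx$sequence, "random", seed = 4)
  expect_identical(as.character(cdsR1), as.character(cdsR2))
  expect_identical(translateCds(cdsR1), as.character(fx$sequence)[[1]])
  set.seed(2)
  for (i in 1:20) {
    p <- paste(sample(c("A", "C", "D", "K", "L", "M", "S", "W"), 30, TRUE),
               collapse = "")
    expect_identical(translateCds(makeCds(p, "random", seed = i)), p)
  }
  expect_error(makeCds("MXK"), "X")
})

test_that("generated alignments honor their column specifications", {
  spec <- list(c(G = 1), c(L = 0.5, I = 0.5), c(A = 0.25, C = 0.25,
                                                D = 0.25, E = 0.25))
  aln <- makeMsa(66, spec, seed = 3)
  expect_identical(nrow(aln), 66L)
  expect_identical(ncol(aln), 3L)
  p <- columnProfiles(aln)
  expect_equal(p[[1]]$information_bits, log2(20))
  expect_identical(names(p[[1]]$counts), "G")
  expect_true(all(names(p[[2]]$counts) %in% c("I", "L")))
  expect_error(makeMsa(10, list(c(L = 0.7))), "summing to 1")
  expect_error(makeMsa(1, spec), "at least 2")

  # a uniform column's information tends to zero for many rows
  unif <- setNames(rep(1 / 20, 20),
                   c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  big <- makeMsa(2000, list(unif), seed = 9)
  expect_lt(columnProfiles(big)[[1]]$information_bits, 0.02)
})

test_that("published TM2.6 labels are retrievable by channel", {
  tab <- knownTM26Labels()
  expect_identical(nrow(tab), 11L)
  expect_identical(knownTM26Labels("hTASK1")$label, "L122")
  expect_identical(knownTM26Labels("TWK-18")$label, "V158")
  expect_identical(knownTM26Labels("mTREK1")$label, "G171")
  expect_identical(nrow(knownTM26Labels("noSuchChannel")), 0L)
})

test_that("validation harness reports matches and flags discrepancies", {
  # synthetic stand-ins (not real reference sequences): TM2.6 placed at the
  # published coordinate for SUP-9, and off by +5 for a second copy
  good <- standInChannel("SUP-9", "L", 122L)
  off <- standInChannel("EGL-23", "L", 234L)  # published label is L229
  seqs <- c(good$sequence, off$sequence)
  rep <- validateKnownChannels(seqs)
  expect_identical(rep$observed_label[rep$channel == "SUP-9"], "L122")
  expect_true(rep$position_match[rep$channel == "SUP-9"])
  expect_identical(rep$note[rep$channel == "SUP-9"], "exact match")
  expect_false(rep$position_match[rep$channel == "EGL-23"])
  expect_match(rep$note[rep$channel == "EGL-23"], "offset \\+5")
  # unknown channels and unannotatable input are reported, not dropped
  junk <- Biostrings::AAStringSet(c(mystery = strrep("A", 300)))
  rep2 <- validateKnownChannels(junk)
  expect_match(rep2$note, "annotation failed")
})
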