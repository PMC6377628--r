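test_that("substitution series follow the strong-to-weak tier order", {
  s <- designSeries("L")
  expect_identical(s$target, c("N", "D", "S", "T", "G", "V"))
  expect_identical(s$tier, c("strong", "strong", "intermediate",
                             "intermediate", "weak", "weak"))
  # wild-type residue is dropped from its own tier
  sv <- designSeries("V")
  expect_false("V" %in% sv$target)
  expect_identical(sv$target[sv$tier == "weak"], "G")
  sn <- designSeries("N")
  expect_false("N" %in% sn$target)
  expect_identical(sn$target[sn$tier == "strong"], "D")
  # controls are opt-in and never duplicate series targets
  sg <- designSeries("G", includeControls = TRUE)
  expect_identical(sg$target[sg$tier == "control"], "L")
  expect_false(any(duplicated(sg$target)))
  expect_error(designSeries("Z"), "amino-acid")
})

test_that("minimal codon edits match hand-derived cases", {
  d <- minCodonEdits("GGC", "D")
  expect_identical(d$new_codon, "GAC")
  expect_identical(d$n_changes, 1L)
  expect_identical(d$changed_positions, "2")

  n <- minCodonEdits("CTT", "N")
  expect_identical(n$new_codon, "AAT")
  expect_identical(n$n_changes, 2L)

  same <- minCodonEdits("AAT", "N")
  expect_identical(same$n_changes, 0L)
  expect_identical(same$new_codon, "AAT")

  # all minimal options returned, lexicographically sorted
  e <- minCodonEdits("GAA", "D")  # GAT/GAC both 1 change
  expect_identical(e$new_codon, c("GAC", "GAT"))
  expect_identical(unique(e$n_changes), 1L)

  expect_error(minCodonEdits("TAA", "N"), "sense codon")
  expect_error(minCodonEdits("CTT", "*"), "stop")
  expect_error(minCodonEdits("CT", "N"), "3-base")
})

test_that("codon distance agrees with exhaustive search and is symmetric", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  # independent oracle: Hamming distance by direct character comparison
  # over every codon pair
  oracleDist <- function(from, to) {
    sum(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  }
  set.seed(11)
  for (wt in sample(sense, 12)) {
    for (target in c("N", "D", "S", "G", "W")) {
      mine <- minCodonEdits(wt, target)
      targetCodons <- names(code)[code == target]
      oracle <- min(vapply(targetCodons, oracleDist, integer(1), from = wt))
      expect_identical(unique(mine$n_changes), oracle)
    }
  }
  # symmetry of the Hamming distance between fixed codons
  expect_identical(oracleDist("CTT", "AAT"), oracleDist("AAT", "CTT"))
})

test_that("no single-base path converts Val/Phe/Leu codons to Asn", {
  code <- Biostrings::GENETIC_CODE
  for (aa in c("V", "F", "L")) {
    for (cod in names(code)[code == aa]) {
      expect_gte(minCodonEdits(cod, "N")$n_changes[1], 2L)
    }
  }
  # while the Gly -> Asp route is available as a single base change
  glyD <- vapply(names(code)[code == "G"],
                 function(cod) minCodonEdits(cod, "D")$n_changes[1],
                 integer(1))
  expect_identical(min(glyD), 1L)
})

test_that("protein edit labels validate against the live sequence", {
  fx <- k2pFixture(21, tm26Residue = "L")
  m <- fx$truth$tm2map
  pos <- tm26Position(m)
  expect_identical(planProteinEdit(fx$sequence, m, "N"),
                   paste0("L", pos, "N"))
  # sequence mutated since annotation -> stale
  s <- as.character(fx$sequence)[[1]]
  substr(s, pos, pos) <- "A"
  expect_error(planProteinEdit(s, m, "N"), "stale annotation")
})

test_that("CDS edits land on the right absolute coordinates", {
  cds <- strrep("GTT", 200)
  pe <- planCdsEdit(cds, 158, "N")
  expect_identical(pe$wt_codon, "GTT")
  expect_identical(pe$new_codon, "AAT")
  expect_identical(pe$n_changes, 2L)
  expect_identical(pe$cds_substitutions$cds_index, c(472L, 473L))

  # synonymous request: zero changes, codon untouched
  pv <- planCdsEdit(cds, 10, "V")
  expect_identical(pv$n_changes, 0L)
  expect_identical(pv$new_codon, "GTT")

  expect_error(planCdsEdit(paste0(cds, "A"), 3, "N"), "multiple of 3")
  expect_error(planCdsEdit(cds, 500, "N"), "outside")
  expect_error(planCdsEdit(cds, 5, "N", expectedResidue = "L"),
               "stale annotation")
})

test_that("applying a planned CDS edit yields the target residue", {
  fx <- k2pFixture(31, tm26Residue = "L")
  cds <- makeCds(fx$sequence, "random", seed = 5)
  pos <- tm26Position(fx$truth$tm2map)
  for (target in c("N", "D", "S")) {
    pe <- planCdsEdit(cds, pos, target,
                      expectedResidue = "L")
    s <- as.character(cds)[[1]]
    for (i in seq_len(nrow(pe$cds_substitutions))) {
      idx <- pe$cds_substitutions$cds_index[i]
      expect_identical(substr(s, idx, idx), pe$cds_substitutions$from[i])
      substr(s, idx, idx) <- pe$cds_substitutions$to[i]
    }
    prot <- translateCds(s)
    expect_identical(substr(prot, pos, pos), target)
  }
})

test_that("substitution plans assemble labels, tiers and codon edits", {
  fx <- k2pFixture(41, tm26Residue = "L")
  cds <- makeCds(fx$sequence)
  plan <- substitutionPlan(fx$sequence, fx$truth$tm2map, cds = cds)
  expect_identical(nrow(plan), 6L)
  pos <- tm26Position(fx$truth$tm2map)
  expect_identical(plan$mutation_label[1], paste0("L", pos, "N"))
  expect_identical(plan$wt_label[1], paste0("L", pos))
  expect_true(all(plan$n_changes >= 1L))
  expect_false("L" %in% plan$target)
})
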