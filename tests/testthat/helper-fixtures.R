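# Shared helpers for building small in-memory fixtures.

writeTempFasta <- function(records, wrap = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1L, nchar(s), wrap)
      substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

# synthetic stand-in for a published reference channel: a generated K2P-like
# protein whose TM2.6 residue and position are placed at the published
# label's coordinates (no real reference sequence is bundled)
standInChannel <- function(name, wtResidue, position, seed = 99L) {
  # fixed element lengths so TM2.6 lands exactly at `position`
  nterm <- position - 73L
  stopifnot(nterm >= 10L)
  k2pFixture(seed, tm26Residue = wtResidue, id = name,
             hingeOffset = 11L,
             lengths = list(nterm = c(nterm, nterm), tm1 = c(20L, 20L),
                            gap_tm1_ph1 = c(12L, 12L),
                            gap_sf1_tm2 = c(12L, 12L),
                            tm2 = c(22L, 22L)))
}

# all hinge motifs of grammar tiers 1-4
allHingeMotifs <- c("GIP", "GVP", "GCS", "GCA", "GCT",
                    "GMP", "MIP", "FVP", "GIA", "GLP", "GAP")
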