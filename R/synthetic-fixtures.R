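# Ground-truthed synthetic fixtures: K2P-like proteins with known
# architecture, coding sequences with known codons, alignments with known
# column conservation, and a table of published TM2.6 labels for known
# channels.
#
# The generator builds sequences whose hydrophobic helices are sampled from
# strongly hydrophobic residues and whose loops, pore helices and filter
# contexts are strictly hydrophilic, so segment boundaries are sharp and the
# annotation pipeline can be held to exact coordinate recovery. Dedicated
# edge-case fixtures, not the defaults, are the place to probe detector
# boundaries.

TM_BODY <- c("I", "L", "V", "F")           # KD >= 2.8
LOOP_RESIDUES <- c("S", "T", "N", "Q", "E", "K", "R", "D", "H", "G")  # KD < 0

.sampleRun <- function(n, pool) paste(sample(pool, n, replace = TRUE),
                                      collapse = "")

.fixtureLengths <- function() {
  # min gap of 11 between a filter and the following helix keeps the
  # half-window overshoot of the helix detector out of the filter text
  list(nterm = c(15L, 40L), tm1 = c(18L, 28L), gap_tm1_ph1 = c(10L, 20L),
       gap_sf1_tm2 = c(11L, 14L), tm2 = c(22L, 30L), loop2 = c(46L, 70L),
       tm3 = c(18L, 26L), loop3 = c(40L, 64L), gap_sf2_tm4 = c(11L, 14L),
       tm4 = c(18L, 28L), cterm = c(15L, 40L))
}

#' Generate a ground-truthed synthetic K2P-like protein
#'
#' Assembles a protein with the canonical K2P layout -- hydrophilic
#' N-terminus, TM1, pore helix 1, selectivity filter 1, TM2 carrying the
#' hinge motif with a chosen TM2.6 residue, intracellular loop, TM3, pore
#' helix 2, selectivity filter 2, TM4, C-terminus -- and records every true
#' coordinate. Deterministic for a given seed.
#'
#' @param seed integer RNG seed.
#' @param hingeMotif 3-residue hinge tripeptide; must belong to grammar
#'   tiers 1-4 unless \code{allowGeneralized}.
#' @param tm26Residue amino acid placed at TM2.6 (any letter, including
#'   unclassified ones for negative tests; default \code{"L"}).
#' @param sf1Text,sf2Text 5-residue selectivity-filter texts; must match
#'   T-x-G-[YFL]-G. Defaults \code{"TIGYG"} and \code{"TVGFG"}.
#' @param id sequence id.
#' @param lengths optional named list overriding element length ranges
#'   (each \code{c(min, max)}); see source for element names.
#' @param hingeOffset optional fixed 1-based position of TM2.1 within the
#'   TM2 helix (default: sampled); must leave 5 residues before the motif
#'   and 3 after TM2.6 inside the helix.
#' @param allowGeneralized accept a tier-5 generalized hinge motif.
#' @return list with \code{sequence} (named single-record
#'   \code{AAStringSet}) and \code{truth}, a list holding the true
#'   \code{architecture} (\code{\linkS4class{K2PArchitecture}}) and
#'   \code{tm2map} (\code{\linkS4class{TM2Map}}).
#' @export
k2pFixture <- function(seed, hingeMotif = "GIP", tm26Residue = "L",
                       sf1Text = "TIGYG", sf2Text = "TVGFG",
                       id = sprintf("synthK2P_%d", seed),
                       lengths = list(), hingeOffset = NULL,
                       allowGeneralized = FALSE) {
  tier <- .hingeTier(hingeMotif, allowGeneralized = allowGeneralized)
  if (is.na(tier))
    stop("hingeMotif '", hingeMotif, "' is not in an enabled grammar tier",
         call. = FALSE)
  if (!tm26Residue %in% c(AA_LETTERS, "X"))
    stop("tm26Residue must be an amino-acid letter", call. = FALSE)
  if (!grepl(paste0("^", SF1_PATTERN, "$"), sf1Text))
    stop("sf1Text does not match the selectivity-filter pattern T-x-G-[YFL]-G",
         call. = FALSE)
  if (!grepl(paste0("^", SF2_PATTERN, "$"), sf2Text) &&
      !grepl(paste0("^", SF1_PATTERN, "$"), sf2Text))
    stop("sf2Text does not match the selectivity-filter pattern",
         call. = FALSE)
  rng <- utils::modifyList(.fixtureLengths(), lengths)
  set.seed(as.integer(seed))
  draw <- function(nm) {
    r <- rng[[nm]]
    if (r[1L] > r[2L]) stop("invalid length range for ", nm, call. = FALSE)
    if (r[1L] == r[2L]) return(as.integer(r[1L]))
    sample(seq.int(r[1L], r[2L]), 1L)
  }

  nterm <- .sampleRun(draw("nterm"), LOOP_RESIDUES)
  tm1 <- .sampleRun(draw("tm1"), TM_BODY)
  gap1 <- .sampleRun(draw("gap_tm1_ph1"), LOOP_RESIDUES)
  ph1 <- .sampleRun(8L, LOOP_RESIDUES)
  gapSf1 <- .sampleRun(draw("gap_sf1_tm2"), LOOP_RESIDUES)

  tm2Len <- draw("tm2")
  # hinge offset within TM2: >= 5 body residues before the motif, and
  # TM2.6 at least 2 residues inside the helix end
  maxOffset <- tm2Len - 8L
  if (maxOffset < 6L)
    stop("TM2 too short to host the hinge motif and TM2.4-TM2.6",
         call. = FALSE)
  if (is.null(hingeOffset)) {
    hingeOffset <- sample(seq.int(6L, maxOffset), 1L)  # 1-based within TM2
  } else {
    hingeOffset <- as.integer(hingeOffset)
    if (hingeOffset < 6L || hingeOffset > maxOffset)
      stop("hingeOffset must lie in [6, TM2 length - 8]", call. = FALSE)
  }
  tm2Chars <- sample(TM_BODY, tm2Len, replace = TRUE)
  tm2Chars[hingeOffset + 0:2] <- strsplit(hingeMotif, "")[[1L]]
  # TM2.4/TM2.5 avoid F so no spurious hinge match (e.g. FVP) can start at
  # TM2.4 whatever the TM2.6 residue is
  tm2Chars[hingeOffset + 3:4] <- sample(c("I", "L", "V"), 2L, replace = TRUE)
  tm2Chars[hingeOffset + 5L] <- tm26Residue
  tm2 <- paste(tm2Chars, collapse = "")

  loop2 <- .sampleRun(draw("loop2"), LOOP_RESIDUES)
  tm3 <- .sampleRun(draw("tm3"), TM_BODY)
  loop3 <- .sampleRun(draw("loop3"), LOOP_RESIDUES)
  ph2 <- .sampleRun(8L, LOOP_RESIDUES)
  gapSf2 <- .sampleRun(draw("gap_sf2_tm4"), LOOP_RESIDUES)
  tm4 <- .sampleRun(draw("tm4"), TM_BODY)
  cterm <- .sampleRun(draw("cterm"), LOOP_RESIDUES)

  parts <- c(nterm, tm1, gap1, ph1, sf1Text, gapSf1, tm2, loop2, tm3,
             loop3, ph2, sf2Text, gapSf2, tm4, cterm)
  partNames <- c("nterm", "TM1", "gap1", "Ph1", "SF1", "gapSf1", "TM2",
                 "loop2", "TM3", "loop3", "Ph2", "SF2", "gapSf2", "TM4",
                 "cterm")
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  names(starts) <- names(ends) <- partNames
  seqStr <- paste(parts, collapse = "")
  res <- strsplit(seqStr, "")[[1L]]
  kd <- .kdValues(res)

  segNames <- SEGMENT_ORDER
  segStarts <- starts[c("TM1", "Ph1", "SF1", "TM2", "TM3", "Ph2", "SF2",
                        "TM4")]
  segEnds <- ends[c("TM1", "Ph1", "SF1", "TM2", "TM3", "Ph2", "SF2", "TM4")]
  rngs <- IRanges::IRanges(start = unname(segStarts), end = unname(segEnds),
                           names = segNames)
  mh <- vapply(seq_along(segNames), function(i)
    mean(kd[segStarts[i]:segEnds[i]]), numeric(1))
  S4Vectors::mcols(rngs) <- S4Vectors::DataFrame(
    matched_text = ifelse(segNames %in% c("SF1", "SF2"),
                          c(rep(NA, 2), sf1Text, rep(NA, 3), sf2Text, NA),
                          NA),
    mean_hydropathy = ifelse(grepl("^TM", segNames), mh, NA))
  arch <- new("K2PArchitecture", channelId = id, segments = rngs,
              seqLength = length(res))

  hingeStart <- unname(starts["TM2"]) + hingeOffset - 1L
  pos <- hingeStart + 0:5
  tm2map <- new("TM2Map", channelId = id,
                positions = stats::setNames(as.integer(pos), TM2_LABELS),
                residues = stats::setNames(res[pos], TM2_LABELS),
                hingeClass = .tierClass(tier), hingeText = hingeMotif)

  seqSet <- Biostrings::AAStringSet(stats::setNames(seqStr, id))
  list(sequence = seqSet, truth = list(architecture = arch, tm2map = tm2map))
}

#' Reverse-translate a protein into a coding sequence
#'
#' @param protein protein sequence (character, \code{AAString}, or
#'   single-record \code{AAStringSet}); may not contain \code{X}.
#' @param codonChoice \code{"lexicographic"} (first codon alphabetically)
#'   or \code{"random"} (uniform over synonymous codons; seeded).
#' @param seed RNG seed used when \code{codonChoice = "random"}.
#' @param code genetic code table.
#' @return single-record \code{DNAStringSet}; translation equals the input.
#' @export
makeCds <- function(protein, codonChoice = c("lexicographic", "random"),
                    seed = 1L, code = Biostrings::GENETIC_CODE) {
  codonChoice <- match.arg(codonChoice)
  s <- .asResidueString(protein)
  res <- strsplit(s, "")[[1L]]
  if (any(res == "X"))
    stop("cannot reverse-translate a protein containing X", call. = FALSE)
  if (!all(res %in% AA_LETTERS))
    stop("protein contains letters outside the amino-acid alphabet",
         call. = FALSE)
  byAA <- split(names(code), unname(code))
  byAA <- lapply(byAA, sort)
  if (codonChoice == "random") set.seed(as.integer(seed))
  codons <- vapply(res, function(a) {
    opts <- byAA[[a]]
    if (codonChoice == "lexicographic") opts[1L]
    else opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  id <- .seqId(protein, "cds")
  Biostrings::DNAStringSet(stats::setNames(paste(codons, collapse = ""), id))
}

#' Translate a coding sequence (standard code)
#' @param cds character or \code{DNAStringSet}.
#' @return character protein sequence.
#' @export
translateCds <- function(cds) {
  x <- if (is(cds, "DNAStringSet")) cds
       else Biostrings::DNAStringSet(toupper(as.character(cds)))
  as.character(Biostrings::translate(x, no.init.codon = TRUE))[[1L]]
}

#' Generate an alignment with controlled per-column composition
#'
#' Samples each column independently from a given residue frequency table,
#' producing alignments with known conservation for testing logo
#' computations.
#'
#' @param nRows number of rows.
#' @param columnSpec list of named numeric vectors (one per column); each
#'   must sum to 1 over amino-acid letters and/or \code{"-"}.
#' @param seed RNG seed.
#' @return an \code{AAMultipleAlignment} with rows named
#'   \code{seq1..seqN}.
#' @export
makeMsa <- function(nRows, columnSpec, seed = 1L) {
  nRows <- as.integer(nRows)
  if (nRows < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  for (j in seq_along(columnSpec)) {
    p <- columnSpec[[j]]
    if (is.null(names(p)) ||
        !all(names(p) %in% c(AA_LETTERS, "X", "-")) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("column ", j, ": frequencies must be named amino-acid ",
           "probabilities summing to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  cols <- lapply(columnSpec, function(p)
    sample(names(p), nRows, replace = TRUE, prob = p))
  m <- do.call(cbind, cols)
  rows <- apply(m, 1L, paste, collapse = "")
  Biostrings::AAMultipleAlignment(
    stats::setNames(rows, paste0("seq", seq_len(nRows))))
}

# published wild-type TM2.6 labels for channels with characterized
# gain-of-function series
KNOWN_TM26 <- data.frame(
  channel = c("hTASK1", "hTASK3", "mTASK2", "mTREK1", "mTREK2", "mTRAAK",
              "mTRESK", "TWK-18", "UNC-58", "EGL-23", "SUP-9"),
  wt_residue = c("L", "L", "L", "G", "G", "G", "F", "V", "F", "L", "L"),
  position = c(122L, 122L, 127L, 171L, 196L, 133L, 156L, 158L, 294L, 229L,
               122L),
  stringsAsFactors = FALSE)
KNOWN_TM26$label <- paste0(KNOWN_TM26$wt_residue, KNOWN_TM26$position)

#' Published TM2.6 labels of characterized channels
#'
#' Wild-type TM2.6 residue and position for the vertebrate and nematode
#' channels with characterized TM2.6 gain-of-function mutants (e.g. hTASK1
#' L122, mTREK1 G171, TWK-18 V158). Labels only; no sequences are bundled.
#'
#' @param channel optional channel name; when given, returns that row (or a
#'   zero-row data.frame if unknown).
#' @return data.frame with columns \code{channel}, \code{wt_residue},
#'   \code{position}, \code{label}.
#' @export
knownTM26Labels <- function(channel = NULL) {
  if (is.null(channel)) return(KNOWN_TM26)
  KNOWN_TM26[KNOWN_TM26$channel %in% channel, , drop = FALSE]
}

#' Validate annotated TM2.6 positions against published labels
#'
#' Runs the architecture + TM2 numbering pipeline on user-supplied channel
#' sequences (e.g. public reference isoforms downloaded by the user) whose
#' record ids match channels in \code{\link{knownTM26Labels}}, and compares
#' the annotated TM2.6 to the published label. Discrepancies -- including
#' numbering offsets from isoform choice -- are reported in the output, not
#' absorbed.
#'
#' @param seqs an \code{AAStringSet} (or FASTA path) of reference channel
#'   sequences named by channel.
#' @param allowGeneralized passed to \code{\link{mapTM2}}.
#' @return data.frame with \code{channel}, \code{expected_label},
#'   \code{observed_label}, \code{position_match}, \code{residue_match},
#'   \code{note} (annotation errors and offsets are spelled out).
#' @export
validateKnownChannels <- function(seqs, allowGeneralized = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- readChannelFasta(seqs)
  stopifnot(is(seqs, "AAStringSet"))
  known <- knownTM26Labels()
  ids <- names(seqs)
  rows <- lapply(ids, function(id) {
    exp <- known[known$channel == id, ]
    expLabel <- if (nrow(exp)) exp$label else NA_character_
    obs <- tryCatch(mapTM2(seqs[id], allowGeneralized = allowGeneralized),
                    error = function(e) e)
    if (is(obs, "TM2Map")) {
      obsLabel <- tm26Label(obs)
      posMatch <- if (nrow(exp)) tm26Position(obs) == exp$position else NA
      resMatch <- if (nrow(exp)) tm26Residue(obs) == exp$wt_residue else NA
      note <- if (!nrow(exp)) "channel not in the published table"
              else if (isTRUE(posMatch) && isTRUE(resMatch)) "exact match"
              else if (isTRUE(resMatch))
                sprintf("numbering offset %+d vs published label (isoform?)",
                        tm26Position(obs) - exp$position)
              else "residue mismatch vs published label"
    } else {
      obsLabel <- NA_character_; posMatch <- NA; resMatch <- NA
      note <- paste("annotation failed:", conditionMessage(obs))
    }
    data.frame(channel = id, expected_label = expLabel,
               observed_label = obsLabel, position_match = posMatch,
               residue_match = resMatch, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
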