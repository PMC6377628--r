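# TM2.1-TM2.6 numbering anchored on the TM2 glycine hinge.
#
# The hinge tripeptide at the center of TM2 is matched by a tiered grammar:
#   tier 1  GIP                 canonical glycine-isoleucine-proline motif
#   tier 2  GVP                 valine variant (TWIK2, TASK2, ...)
#   tier 3  G-C-[SAT]           THIK-type motif
#   tier 4  GMP MIP FVP GIA GLP GAP   enumerated degenerate motifs
#   tier 5  [GMF]-[IVCLMA]-[PSAT]     generalized class (opt-in)
# The first motif residue is TM2.1 (even when it is not a glycine, as in the
# MIP/FVP channels); TM2.6 is five residues downstream.

HINGE_CLASSES <- c("canonical_GIP", "valine_variant", "THIK_type", "degenerate")

.hingeTier <- function(triplet, allowGeneralized = FALSE) {
  if (triplet == "GIP") return(1L)
  if (triplet == "GVP") return(2L)
  if (grepl("^GC[SAT]$", triplet)) return(3L)
  if (triplet %in% c("GMP", "MIP", "FVP", "GIA", "GLP", "GAP")) return(4L)
  if (allowGeneralized && grepl("^[GMF][IVCLMA][PSAT]$", triplet)) return(5L)
  NA_integer_
}

.tierClass <- function(tier) {
  switch(tier, "canonical_GIP", "valine_variant", "THIK_type",
         "degenerate", "degenerate")
}

#' Match the TM2 hinge motif
#'
#' Scans the TM2 segment for the best-scoring hinge tripeptide under the
#' tiered grammar (see Details in the package vignette). A higher tier
#' always wins; among equal-tier matches the one whose center is closest to
#' the TM2 midpoint is kept (hinge glycines sit near the helix center), and
#' remaining ties go to the upstream match.
#'
#' @param seq full protein sequence.
#' @param tm2 integer \code{c(start, end)} of the TM2 segment within
#'   \code{seq}, or \code{NULL} to scan the whole sequence.
#' @param allowGeneralized enable the tier-5 generalized motif class
#'   \code{[GMF][IVCLMA][PSAT]} (an extrapolation for novel channels;
#'   off by default).
#' @return list with elements \code{start} (1-based index of the first motif
#'   residue in the full sequence), \code{text}, \code{class} (one of
#'   \code{canonical_GIP}, \code{valine_variant}, \code{THIK_type},
#'   \code{degenerate}), and \code{tier}.
#' @export
matchHingeMotif <- function(seq, tm2 = NULL, allowGeneralized = FALSE) {
  s <- .asResidueString(seq)
  n <- nchar(s)
  if (is.null(tm2)) tm2 <- c(1L, n)
  tm2 <- as.integer(tm2[1:2])
  if (tm2[2L] - tm2[1L] + 1L < 8L)
    stop("TM2 segment too short to host the hinge motif (need >= 8 residues)",
         call. = FALSE)
  starts <- seq.int(tm2[1L], tm2[2L] - 2L)
  trip <- substring(s, starts, starts + 2L)
  tiers <- vapply(trip, .hingeTier, integer(1),
                  allowGeneralized = allowGeneralized, USE.NAMES = FALSE)
  ok <- which(!is.na(tiers))
  if (length(ok) == 0L) stop("no hinge motif in TM2 segment", call. = FALSE)
  bestTier <- min(tiers[ok])
  cand <- ok[tiers[ok] == bestTier]
  mid <- (tm2[1L] + tm2[2L]) / 2
  dist <- abs((starts[cand] + 1L) - mid)
  cand <- cand[order(dist, starts[cand])]
  i <- cand[1L]
  if (starts[i] + 5L > n)
    stop("TM2.6 out of range: fewer than 3 residues follow the hinge motif",
         call. = FALSE)
  list(start = starts[i], text = trip[i],
       class = .tierClass(tiers[i]), tier = tiers[i])
}

#' TM2Map: TM2.1-TM2.6 residue assignments of one channel
#'
#' Six consecutive residue labels anchored on the hinge motif: TM2.1 is the
#' first motif residue, TM2.2/TM2.3 the remaining motif residues, and
#' TM2.4-TM2.6 the next three residues (read from the full sequence; they
#' may extend up to 3 residues past the annotated TM2 end).
#'
#' @slot channelId character.
#' @slot positions named integer, 1-based residue indices for
#'   \code{TM2.1}..\code{TM2.6}.
#' @slot residues named character, amino acids at those positions.
#' @slot hingeClass hinge motif class.
#' @slot hingeText 3-residue motif text.
#' @export
setClass("TM2Map",
  representation(channelId = "character", positions = "integer",
                 residues = "character", hingeClass = "character",
                 hingeText = "character"))

TM2_LABELS <- paste0("TM2.", 1:6)

setValidity("TM2Map", function(object) {
  if (!identical(names(object@positions), TM2_LABELS))
    return("positions must be named TM2.1..TM2.6")
  if (!identical(unname(diff(object@positions)), rep(1L, 5L)))
    return("TM2 positions must be consecutive")
  if (!identical(names(object@residues), TM2_LABELS))
    return("residues must be named TM2.1..TM2.6")
  if (paste0(object@residues[2:3], collapse = "") !=
      substring(object@hingeText, 2L, 3L))
    return("TM2.2/TM2.3 must equal hinge motif positions 2 and 3")
  if (!object@hingeClass %in% HINGE_CLASSES)
    return("unknown hinge class")
  TRUE
})

setMethod("show", "TM2Map", function(object) {
  cat("TM2Map for", object@channelId,
      sprintf("(hinge %s, %s)\n", object@hingeText, object@hingeClass))
  print(data.frame(label = TM2_LABELS, position = unname(object@positions),
                   residue = unname(object@residues)))
})

#' @export
setMethod("channelId", "TM2Map", function(x) x@channelId)

#' TM2.6 position of a TM2Map
#' @param x a \code{TM2Map}.
#' @export
tm26Position <- function(x) {
  stopifnot(is(x, "TM2Map"))
  unname(x@positions[["TM2.6"]])
}

#' TM2.6 residue of a TM2Map
#' @param x a \code{TM2Map}.
#' @export
tm26Residue <- function(x) {
  stopifnot(is(x, "TM2Map"))
  unname(x@residues[["TM2.6"]])
}

#' Hinge class of a TM2Map
#' @param x a \code{TM2Map}.
#' @export
hingeClass <- function(x) {
  stopifnot(is(x, "TM2Map"))
  x@hingeClass
}

#' Wild-type TM2.6 label (e.g. "L122")
#' @param x a \code{TM2Map}.
#' @export
tm26Label <- function(x) paste0(tm26Residue(x), tm26Position(x))

#' Assign TM2.1-TM2.6 positions from a matched hinge
#'
#' @param seq full protein sequence.
#' @param hinge result of \code{\link{matchHingeMotif}}.
#' @param channelId id recorded in the map.
#' @return a \code{\linkS4class{TM2Map}}.
#' @export
assignTM2Positions <- function(seq, hinge, channelId = .seqId(seq)) {
  s <- .asResidueString(seq)
  if (hinge$start + 5L > nchar(s))
    stop("TM2.6 out of range: hinge too close to the sequence end",
         call. = FALSE)
  pos <- hinge$start + 0:5
  res <- substring(s, pos, pos)
  new("TM2Map", channelId = channelId,
      positions = stats::setNames(as.integer(pos), TM2_LABELS),
      residues = stats::setNames(res, TM2_LABELS),
      hingeClass = hinge$class, hingeText = hinge$text)
}

#' Annotate architecture and TM2 numbering in one call
#'
#' Convenience pipeline: \code{\link{annotateArchitecture}} then
#' \code{\link{matchHingeMotif}} within TM2 and
#' \code{\link{assignTM2Positions}}.
#'
#' @param seq protein sequence.
#' @param architecture optional precomputed \code{K2PArchitecture}.
#' @param allowGeneralized passed to \code{\link{matchHingeMotif}}.
#' @param ... further arguments to \code{\link{annotateArchitecture}}.
#' @return a \code{\linkS4class{TM2Map}}.
#' @export
mapTM2 <- function(seq, architecture = NULL, allowGeneralized = FALSE, ...) {
  if (is.null(architecture)) architecture <- annotateArchitecture(seq, ...)
  tm2 <- segmentBounds(architecture, "TM2")
  hinge <- matchHingeMotif(seq, tm2, allowGeneralized = allowGeneralized)
  assignTM2Positions(seq, hinge, channelId = channelId(architecture))
}

# census of TM2.6 identities across 66 vertebrate, insect and nematode
# channels: leucine and isoleucine dominate; a handful of channels carry
# G, F, V, M or A.
TM26_CENSUS_NOTES <- c(
  L = "most common TM2.6 residue (e.g. TASK1/3, TASK2, SUP-9, EGL-23)",
  I = "second most common TM2.6 residue",
  G = "rare; found in TREK1, TREK2, TRAAK, KCNK0/ORK1",
  F = "rare; found in TRESK, TWK-17, TWK-24, UNC-58",
  V = "rare; found in TALK1, TWK-14, TWK-18, TWK-29",
  M = "rare; found in TWIK2, TWK-16, TWK-43",
  A = "rare; found in TWK-25"
)

#' Classify a TM2.6 residue against the channel-family census
#'
#' Leucine and isoleucine are the common TM2.6 identities across the K2P
#' family; glycine, phenylalanine, valine, methionine and alanine occur in a
#' few named channels; anything else is unclassified.
#'
#' @param residue single amino-acid letter.
#' @return list with \code{residue}, \code{category} (\code{"common"},
#'   \code{"rare"} or \code{"unclassified"}), and \code{note} naming
#'   exemplar channels.
#' @export
classifyTM26 <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      !residue %in% AA_LETTERS)
    stop("residue must be a single canonical amino-acid letter",
         call. = FALSE)
  category <- if (residue %in% c("L", "I")) "common"
              else if (residue %in% c("G", "F", "V", "M", "A")) "rare"
              else "unclassified"
  note <- if (category == "unclassified") "not observed at TM2.6 in the family census"
          else TM26_CENSUS_NOTES[[residue]]
  list(residue = residue, category = category, note = note)
}
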