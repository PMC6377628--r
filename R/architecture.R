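# K2P architecture annotation.
#
# The canonical K2P subunit layout along the sequence is
#   TM1 < Ph1 < SF1 < TM2 < TM3 < Ph2 < SF2 < TM4
# with the two selectivity filters found by the potassium-channel signature
# T-x-G-[YFL]-G and the transmembrane helices by Kyte-Doolittle hydropathy.

SEGMENT_ORDER <- c("TM1", "Ph1", "SF1", "TM2", "TM3", "Ph2", "SF2", "TM4")

#' K2PArchitecture: located segments of one K2P channel
#'
#' Holds the eight canonical elements (TM1-TM4, Ph1/Ph2, SF1/SF2) of a K2P
#' subunit as a named \code{IRanges} in sequence order, with the matched
#' selectivity-filter text and per-helix mean hydropathy as metadata columns.
#' Validity enforces the canonical ordering and non-overlap.
#'
#' @slot channelId character id of the annotated channel.
#' @slot segments named \code{IRanges} (names \code{TM1}, \code{Ph1},
#'   \code{SF1}, \code{TM2}, \code{TM3}, \code{Ph2}, \code{SF2}, \code{TM4})
#'   with metadata columns \code{matched_text} and \code{mean_hydropathy}.
#' @slot seqLength length of the annotated sequence.
#' @export
setClass("K2PArchitecture",
  representation(channelId = "character",
                 segments = "IRanges",
                 seqLength = "integer"))

setValidity("K2PArchitecture", function(object) {
  seg <- object@segments
  if (!identical(names(seg), SEGMENT_ORDER))
    return("segments must be named TM1, Ph1, SF1, TM2, TM3, Ph2, SF2, TM4 in order")
  s <- IRanges::start(seg); e <- IRanges::end(seg)
  if (any(s > e)) return("segment start exceeds end")
  if (any(e[-length(e)] >= s[-1L]))
    return("segments overlap or violate canonical ordering")
  if (any(s < 1L) || any(e > object@seqLength))
    return("segment indices outside sequence")
  if (any(IRanges::width(seg[c("SF1", "SF2")]) != 5L))
    return("selectivity filters must be 5 residues")
  TRUE
})

setMethod("show", "K2PArchitecture", function(object) {
  cat("K2PArchitecture for", object@channelId,
      sprintf("(%d residues)\n", object@seqLength))
  print(architectureTable(object))
})

#' @describeIn K2PArchitecture channel id accessor
#' @param x a \code{K2PArchitecture}.
#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))

#' @export
setMethod("channelId", "K2PArchitecture", function(x) x@channelId)

#' Tabulate an architecture annotation
#'
#' @param x a \code{K2PArchitecture}.
#' @return data.frame with one row per element: \code{channel_id},
#'   \code{element}, \code{start}, \code{end}, \code{matched_text},
#'   \code{mean_hydropathy}.
#' @export
architectureTable <- function(x) {
  stopifnot(is(x, "K2PArchitecture"))
  seg <- x@segments
  data.frame(channel_id = x@channelId,
             element = names(seg),
             start = IRanges::start(seg),
             end = IRanges::end(seg),
             matched_text = S4Vectors::mcols(seg)$matched_text,
             mean_hydropathy = S4Vectors::mcols(seg)$mean_hydropathy,
             row.names = NULL)
}

#' Start/end of one architecture element
#' @param x a \code{K2PArchitecture}.
#' @param element one of \code{"TM1"}, \code{"Ph1"}, \code{"SF1"},
#'   \code{"TM2"}, \code{"TM3"}, \code{"Ph2"}, \code{"SF2"}, \code{"TM4"}.
#' @return integer vector \code{c(start, end)} (1-based, inclusive).
#' @export
segmentBounds <- function(x, element) {
  stopifnot(is(x, "K2PArchitecture"), element %in% SEGMENT_ORDER)
  seg <- x@segments[element]
  c(start = IRanges::start(seg), end = IRanges::end(seg))
}

# --- sequence coercion helpers ------------------------------------------

.asResidueString <- function(seq) {
  if (is(seq, "AAStringSet")) {
    if (length(seq) != 1L) stop("expected a single sequence", call. = FALSE)
    return(as.character(seq)[[1L]])
  }
  if (is(seq, "AAString")) return(as.character(seq))
  if (is.character(seq) && length(seq) == 1L) return(toupper(seq))
  stop("cannot interpret input as a single protein sequence", call. = FALSE)
}

.seqId <- function(seq, default = "channel") {
  if (is(seq, "AAStringSet") && !is.null(names(seq))) return(names(seq)[1L])
  if (is.character(seq) && !is.null(names(seq))) return(names(seq)[1L])
  default
}

# --- hydropathy ----------------------------------------------------------

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy over a centered odd-width window; one value
#' per admissible window center. \code{X} contributes 0.
#'
#' @param seq protein sequence (character, \code{AAString}, or single-record
#'   \code{AAStringSet}).
#' @param window odd window width, between 5 and 31 (default 15, a typical
#'   transmembrane-helix core).
#' @return data.frame with columns \code{center} (1-based index) and
#'   \code{hydropathy}.
#' @export
hydropathyProfile <- function(seq, window = 15L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 5L || window > 31L)
    stop("window must be odd and between 5 and 31", call. = FALSE)
  res <- strsplit(.asResidueString(seq), "")[[1L]]
  n <- length(res)
  if (n < window)
    stop("sequence shorter than window (", n, " < ", window, ")", call. = FALSE)
  vals <- KD_SCALE[res]
  if (anyNA(vals))
    stop("sequence contains letters outside the amino-acid alphabet",
         call. = FALSE)
  cs <- cumsum(c(0, vals))
  half <- (window - 1L) %/% 2L
  centers <- seq.int(half + 1L, n - half)
  means <- (cs[centers + half + 1L] - cs[centers - half]) / window
  data.frame(center = centers, hydropathy = unname(means))
}

# per-residue KD values for a residue vector
.kdValues <- function(res) unname(KD_SCALE[res])

# --- selectivity filters -------------------------------------------------

SF1_PATTERN <- "T[A-Z]G[YFL]G"
SF2_PATTERN <- "T[A-Z]G[FL]G"

.sfHits <- function(resString, pattern = SF1_PATTERN) {
  m <- gregexpr(pattern, resString, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m)
}

#' Locate selectivity-filter motifs
#'
#' Scans for the potassium-channel selectivity-filter signature
#' T-x-G-[YFL]-G (x = any residue). With \code{requirePair = TRUE} (the
#' default) the two pore-domain filters SF1 and SF2 are resolved: hits must
#' be at least \code{minSeparation} residues apart, and if more than two raw
#' hits exist the pair whose spacing is closest to \code{expectedSpacing}
#' (the canonical distance between the two filters of a K2P subunit) is
#' kept. A tie in the spacing score is an error listing the candidates.
#'
#' @param seq protein sequence.
#' @param expectedSpacing expected SF1-SF2 start-to-start distance in
#'   residues (default 190).
#' @param minSeparation minimum separation between SF1 and SF2 (default 40).
#' @param requirePair if \code{TRUE}, resolve and label exactly SF1 and SF2
#'   (erroring otherwise); if \code{FALSE}, return all raw hits unlabeled.
#' @return data.frame with columns \code{ordinal} (\code{"SF1"}/\code{"SF2"},
#'   or \code{NA} for raw hits), \code{start}, \code{end}, \code{matched_text}.
#' @export
findSelectivityFilters <- function(seq, expectedSpacing = 190,
                                   minSeparation = 40, requirePair = TRUE) {
  s <- .asResidueString(seq)
  starts <- .sfHits(s)
  hits <- data.frame(ordinal = rep(NA_character_, length(starts)),
                     start = starts, end = starts + 4L,
                     matched_text = if (length(starts))
                       substring(s, starts, starts + 4L) else character(0),
                     stringsAsFactors = FALSE)
  if (!requirePair) return(hits)
  if (nrow(hits) < 2L) {
    stop("not a recognizable K2P (needs two pore domains): found ",
         nrow(hits), " selectivity-filter hit(s)", call. = FALSE)
  }
  pairs <- which(outer(starts, starts, function(a, b) b - a) >= minSeparation,
                 arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    stop("not a recognizable K2P (needs two pore domains): hits closer than ",
         minSeparation, " residues", call. = FALSE)
  }
  spacing <- starts[pairs[, 2L]] - starts[pairs[, 1L]]
  score <- abs(spacing - expectedSpacing)
  best <- which(score == min(score))
  if (length(best) > 1L && nrow(hits) > 2L) {
    cand <- apply(pairs[best, , drop = FALSE], 1L, function(p)
      sprintf("%d-%d", starts[p[1L]], starts[p[2L]]))
    stop("ambiguous selectivity-filter pairing (tied spacing score): ",
         paste(cand, collapse = ", "), call. = FALSE)
  }
  p <- pairs[best[1L], ]
  out <- hits[c(p[[1L]], p[[2L]]), ]
  out$ordinal <- c("SF1", "SF2")
  rownames(out) <- NULL
  out
}

# --- transmembrane segments ----------------------------------------------

# Detect hydrophobic segments: maximal runs of window centers whose mean
# hydropathy passes `threshold`, extended to half-window edges and then
# trimmed inward while the terminal residue's own KD value is negative
# (half-window extension otherwise overshoots into flanking loops).
.hydrophobicSegments <- function(res, window = 15L, threshold = 1.0,
                                 lengthBounds = c(15L, 35L)) {
  n <- length(res)
  if (n < window) return(data.frame(start = integer(0), end = integer(0),
                                    mean_hydropathy = numeric(0)))
  prof <- hydropathyProfile(paste(res, collapse = ""), window)
  above <- prof$hydropathy >= threshold
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0),
                                     mean_hydropathy = numeric(0)))
  r <- rle(above)
  idxEnd <- cumsum(r$lengths)
  idxStart <- idxEnd - r$lengths + 1L
  runs <- which(r$values)
  half <- (window - 1L) %/% 2L
  kd <- .kdValues(res)
  segs <- lapply(runs, function(k) {
    a <- max(1L, prof$center[idxStart[k]] - half)
    b <- min(n, prof$center[idxEnd[k]] + half)
    while (a < b && kd[a] < 0) a <- a + 1L
    while (b > a && kd[b] < 0) b <- b - 1L
    c(a, b)
  })
  segs <- do.call(rbind, segs)
  keep <- (segs[, 2L] - segs[, 1L] + 1L) >= lengthBounds[1L] &
          (segs[, 2L] - segs[, 1L] + 1L) <= lengthBounds[2L]
  segs <- segs[keep, , drop = FALSE]
  mh <- vapply(seq_len(nrow(segs)), function(i)
    mean(kd[segs[i, 1L]:segs[i, 2L]]), numeric(1))
  data.frame(start = segs[, 1L], end = segs[, 2L], mean_hydropathy = mh)
}

#' Annotate the K2P architecture of a channel sequence
#'
#' Anchors on the two selectivity-filter hits, then assigns transmembrane
#' helices from the hydropathy profile: TM2 is the first hydrophobic segment
#' starting within \code{tmGap} residues downstream of SF1; TM1 the last
#' segment ending at least 10 residues upstream of Ph1; TM3 lies between TM2
#' and Ph2; TM4 starts within \code{tmGap} residues downstream of SF2. Ph1
#' and Ph2 are the 8-residue stretches immediately preceding each filter.
#'
#' @param seq protein sequence (named \code{AAStringSet} records carry the
#'   channel id).
#' @param window hydropathy window (odd, default 15).
#' @param tmThreshold minimum windowed mean hydropathy of an accepted helix
#'   (default 1.0, permissive for the short TM2 of K2Ps).
#' @param tmLength accepted helix length range (default \code{c(15, 35)}).
#' @param expectedSpacing,minSeparation passed to
#'   \code{\link{findSelectivityFilters}}.
#' @param tmGap maximum SF-to-helix gap for TM2/TM4 (default 15).
#' @param channelId id recorded in the result; defaults to the sequence name.
#' @return a \code{\linkS4class{K2PArchitecture}}.
#' @export
annotateArchitecture <- function(seq, window = 15L, tmThreshold = 1.0,
                                 tmLength = c(15L, 35L),
                                 expectedSpacing = 190, minSeparation = 40,
                                 tmGap = 15L,
                                 channelId = .seqId(seq)) {
  s <- .asResidueString(seq)
  res <- strsplit(s, "")[[1L]]
  sf <- findSelectivityFilters(s, expectedSpacing, minSeparation)
  sf1 <- sf[sf$ordinal == "SF1", ]
  sf2 <- sf[sf$ordinal == "SF2", ]
  if (sf1$start <= 8L)
    stop("Ph1 not found: SF1 too close to the N-terminus", call. = FALSE)
  ph1 <- c(sf1$start - 8L, sf1$start - 1L)
  ph2 <- c(sf2$start - 8L, sf2$start - 1L)

  segs <- .hydrophobicSegments(res, window, tmThreshold, tmLength)

  pick <- function(cond, label) {
    i <- which(cond)
    if (length(i) == 0L) stop(label, " not found", call. = FALSE)
    i
  }
  i2 <- pick(segs$start > sf1$end & segs$start <= sf1$end + tmGap, "TM2")[1L]
  i1 <- utils::tail(pick(segs$end <= ph1[1L] - 10L, "TM1"), 1L)
  i3 <- pick(segs$start > segs$end[i2] & segs$end < ph2[1L], "TM3")[1L]
  i4 <- pick(segs$start > sf2$end & segs$start <= sf2$end + tmGap, "TM4")[1L]

  starts <- c(segs$start[i1], ph1[1L], sf1$start, segs$start[i2],
              segs$start[i3], ph2[1L], sf2$start, segs$start[i4])
  ends <- c(segs$end[i1], ph1[2L], sf1$end, segs$end[i2],
            segs$end[i3], ph2[2L], sf2$end, segs$end[i4])
  rng <- IRanges::IRanges(start = starts, end = ends, names = SEGMENT_ORDER)
  S4Vectors::mcols(rng) <- S4Vectors::DataFrame(
    matched_text = c(NA, NA, sf1$matched_text, NA, NA, NA,
                     sf2$matched_text, NA),
    mean_hydropathy = c(segs$mean_hydropathy[i1], NA, NA,
                        segs$mean_hydropathy[i2], segs$mean_hydropathy[i3],
                        NA, NA, segs$mean_hydropathy[i4]))
  new("K2PArchitecture", channelId = channelId, segments = rng,
      seqLength = length(res))
}
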