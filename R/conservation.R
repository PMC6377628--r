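# Per-column conservation statistics (sequence-logo mathematics) and the
# hinge-motif / TM2.6 census across an annotated channel set.

.alnMatrix <- function(aln) {
  if (is(aln, "AAMultipleAlignment")) {
    s <- as.character(Biostrings::unmasked(aln))
    m <- do.call(rbind, strsplit(s, ""))
    rownames(m) <- names(s)
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L)
      stop("ragged alignment: rows have unequal lengths", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  } else stop("alignment must be an AAMultipleAlignment or character vector",
              call. = FALSE)
  if (nrow(m) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  m
}

#' Per-column conservation profiles of a channel alignment
#'
#' For each alignment column, residue counts, frequencies, Shannon entropy
#' (bits) and information content as drawn in a sequence logo:
#' \eqn{R = \log_2 S - H} with \eqn{H = -\sum_a p_a \log_2 p_a}, where
#' \eqn{S} is the alphabet size (20 when gaps are excluded from the
#' frequencies, 21 when counted as an extra symbol). Letter heights are
#' \eqn{p_a R}. Columns consisting only of gaps get information 0 and are
#' flagged.
#'
#' @param aln an \code{AAMultipleAlignment} (see
#'   \code{\link{readChannelAlignment}}) or character vector of equal-length
#'   rows.
#' @param gapPolicy \code{"exclude"} (default; frequencies over non-gap
#'   residues, \eqn{S = 20}) or \code{"count_as_21st"} (gap treated as a
#'   21st symbol).
#' @param correction apply the small-sample entropy correction
#'   \eqn{(S-1)/(2 n \ln 2)} subtracted from the information content (as
#'   common logo tools do); off by default.
#' @return list of per-column profiles, each a list with \code{column},
#'   \code{counts}, \code{gap_count}, \code{frequencies},
#'   \code{entropy_bits}, \code{information_bits}, \code{letter_heights},
#'   \code{all_gap}.
#' @export
columnProfiles <- function(aln, gapPolicy = c("exclude", "count_as_21st"),
                           correction = FALSE) {
  gapPolicy <- match.arg(gapPolicy)
  m <- .alnMatrix(aln)
  nRows <- nrow(m)
  lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gapCount <- sum(col == "-")
    obs <- col[col != "-"]
    if (gapPolicy == "count_as_21st") obs <- col
    S <- if (gapPolicy == "count_as_21st") 21L else 20L
    allGap <- length(col[col != "-"]) == 0L
    if (length(obs) == 0L) {
      counts <- integer(0)
      freqs <- numeric(0)
      H <- 0
      info <- 0
    } else {
      counts <- table(obs)
      freqs <- as.numeric(counts) / length(obs)
      names(freqs) <- names(counts)
      H <- -sum(freqs * log2(freqs))
      info <- log2(S) - H
      if (correction) info <- info - (S - 1) / (2 * length(obs) * log(2))
      info <- max(info, 0)
    }
    if (allGap) info <- 0
    list(column = j,
         counts = stats::setNames(as.integer(counts), names(counts)),
         gap_count = gapCount,
         frequencies = freqs,
         entropy_bits = H,
         information_bits = info,
         letter_heights = freqs * info,
         all_gap = allGap)
  })
}

#' Flat information-content table for an alignment
#'
#' @inheritParams columnProfiles
#' @param referenceRow optional row id; adds the reference sequence's
#'   residue and 1-based residue index for each column (NA at gaps).
#' @return data.frame with one row per column: \code{column},
#'   \code{n_residues}, \code{gap_count}, \code{entropy_bits},
#'   \code{information_bits}, \code{top_residue}, \code{top_height}, and
#'   optionally \code{ref_residue}, \code{ref_position}.
#' @export
informationProfile <- function(aln, gapPolicy = c("exclude", "count_as_21st"),
                               correction = FALSE, referenceRow = NULL) {
  profs <- columnProfiles(aln, gapPolicy, correction)
  out <- data.frame(
    column = vapply(profs, `[[`, integer(1), "column"),
    n_residues = vapply(profs, function(p) sum(p$counts), integer(1)),
    gap_count = vapply(profs, `[[`, integer(1), "gap_count"),
    entropy_bits = vapply(profs, `[[`, numeric(1), "entropy_bits"),
    information_bits = vapply(profs, `[[`, numeric(1), "information_bits"),
    top_residue = vapply(profs, function(p) {
      if (length(p$letter_heights) == 0L) NA_character_
      else names(which.max(p$letter_heights))
    }, character(1)),
    top_height = vapply(profs, function(p) {
      if (length(p$letter_heights) == 0L) NA_real_
      else max(p$letter_heights)
    }, numeric(1)))
  if (!is.null(referenceRow)) {
    m <- .alnMatrix(aln)
    if (!referenceRow %in% rownames(m))
      stop("reference row not in alignment: ", referenceRow, call. = FALSE)
    ref <- m[referenceRow, ]
    out$ref_residue <- ifelse(ref == "-", NA_character_, ref)
    out$ref_position <- ifelse(ref == "-", NA_integer_, cumsum(ref != "-"))
  }
  out
}

#' Hinge-motif and TM2.6 census over annotated channels
#'
#' Tallies hinge classes and TM2.6 residue identities over a set of
#' \code{\linkS4class{TM2Map}} annotations. Upstream annotation failures are
#' counted, not raised.
#'
#' @param maps list of \code{TM2Map} objects (entries that are \code{NULL}
#'   or condition objects count as failures).
#' @return list with \code{n_channels}, \code{motif_class_counts} (fixed
#'   class order), \code{tm26_residue_counts} (alphabetical),
#'   \code{tm26_category_counts}, and \code{n_failed}.
#' @export
hingeCensus <- function(maps) {
  if (length(maps) == 0L) stop("census needs at least one annotation",
                               call. = FALSE)
  ok <- vapply(maps, function(m) is(m, "TM2Map"), logical(1))
  good <- maps[ok]
  classes <- vapply(good, hingeClass, character(1))
  residues <- vapply(good, tm26Residue, character(1))
  categories <- vapply(residues, function(r) classifyTM26(r)$category,
                       character(1))
  motifCounts <- stats::setNames(
    vapply(HINGE_CLASSES, function(cl) sum(classes == cl), integer(1)),
    HINGE_CLASSES)
  resCounts <- table(factor(residues, levels = sort(unique(residues))))
  list(n_channels = length(maps),
       motif_class_counts = motifCounts,
       tm26_residue_counts = stats::setNames(as.integer(resCounts),
                                             names(resCounts)),
       tm26_category_counts = stats::setNames(
         vapply(c("common", "rare", "unclassified"),
                function(cat) sum(categories == cat), integer(1)),
         c("common", "rare", "unclassified")),
       n_failed = sum(!ok))
}
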