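# Gain-of-function mutation design at TM2.6 and minimal codon edits.
#
# Whole-cell and in-vivo allelic series rank the substitutions roughly
# N ~ D (strong) > S >= T (intermediate) > G ~ V (weak); hydrophobic L/V
# substitutions serve as controls. Codon edits are planned by brute force
# over the standard genetic code, reporting every codon that reaches the
# target amino acid with the fewest base changes.

GOF_TIERS <- list(strong = c("N", "D"), intermediate = c("S", "T"),
                  weak = c("G", "V"))

#' Design a graded TM2.6 substitution series
#'
#' Returns the gain-of-function substitution tiers for one wild-type TM2.6
#' residue, strongest first: asparagine/aspartate (strong),
#' serine/threonine (intermediate), glycine/valine (weak), and optionally
#' the hydrophobic leucine/valine controls. The wild-type residue is removed
#' from whichever tier it occupies; targets never repeat.
#'
#' @param wt wild-type amino acid at TM2.6.
#' @param includeControls add hydrophobic control substitutions (L, V).
#' @return data.frame with columns \code{target} and \code{tier}
#'   (\code{strong}, \code{intermediate}, \code{weak}, \code{control}),
#'   ordered strong to control.
#' @export
designSeries <- function(wt, includeControls = FALSE) {
  if (!is.character(wt) || length(wt) != 1L || !wt %in% AA_LETTERS)
    stop("wt must be a single canonical amino-acid letter", call. = FALSE)
  rows <- do.call(rbind, lapply(names(GOF_TIERS), function(tier) {
    targets <- setdiff(GOF_TIERS[[tier]], wt)
    if (length(targets) == 0L) return(NULL)
    data.frame(target = targets, tier = tier, stringsAsFactors = FALSE)
  }))
  if (includeControls) {
    ctl <- setdiff(c("L", "V"), c(wt, rows$target))
    if (length(ctl) > 0L)
      rows <- rbind(rows, data.frame(target = ctl, tier = "control",
                                     stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

.asCodon <- function(x, what = "codon") {
  x <- toupper(as.character(x))
  if (length(x) != 1L || nchar(x) != 3L ||
      !all(strsplit(x, "")[[1L]] %in% NT_LETTERS))
    stop(what, " must be a 3-base string over A/C/G/T: ", x, call. = FALSE)
  x
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Minimal-base-change codon edits to a target amino acid
#'
#' Brute-forces all codons of the target amino acid and returns every codon
#' reaching it with the minimum Hamming distance from the wild-type codon,
#' sorted lexicographically. A distance of 0 means the wild-type codon
#' already encodes the target.
#'
#' @param wtCodon wild-type sense codon (3 bases).
#' @param target target amino acid (single letter; stop is an error).
#' @param code genetic code table, codon -> amino acid
#'   (default \code{Biostrings::GENETIC_CODE}).
#' @return data.frame with columns \code{wt_codon}, \code{new_codon},
#'   \code{n_changes}, \code{changed_positions} (comma-joined 1-based
#'   within-codon positions).
#' @export
minCodonEdits <- function(wtCodon, target,
                          code = Biostrings::GENETIC_CODE) {
  wtCodon <- .asCodon(wtCodon, "wtCodon")
  if (is.na(code[wtCodon]) || code[wtCodon] == "*")
    stop("wtCodon must be a sense codon: ", wtCodon, call. = FALSE)
  if (!is.character(target) || length(target) != 1L)
    stop("target must be a single amino-acid letter", call. = FALSE)
  if (target == "*") stop("target may not be a stop codon", call. = FALSE)
  if (!target %in% AA_LETTERS)
    stop("target must be a canonical amino-acid letter: ", target,
         call. = FALSE)
  codons <- sort(names(code)[code == target])
  d <- vapply(codons, .hamming, integer(1), a = wtCodon)
  keep <- codons[d == min(d)]
  wtChars <- strsplit(wtCodon, "")[[1L]]
  data.frame(
    wt_codon = wtCodon,
    new_codon = keep,
    n_changes = min(d),
    changed_positions = vapply(keep, function(cd) {
      paste(which(strsplit(cd, "")[[1L]] != wtChars), collapse = ",")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Mutation label for a TM2.6 substitution
#'
#' Builds the conventional label (wild-type residue, position, target; e.g.
#' \code{"L122N"}) and verifies that the sequence still carries the mapped
#' wild-type residue at the TM2.6 position.
#'
#' @param seq protein sequence the map was computed from.
#' @param tm2map a \code{\linkS4class{TM2Map}} for \code{seq}.
#' @param target target amino acid.
#' @return character mutation label.
#' @export
planProteinEdit <- function(seq, tm2map, target) {
  stopifnot(is(tm2map, "TM2Map"))
  if (!target %in% AA_LETTERS)
    stop("target must be a canonical amino-acid letter", call. = FALSE)
  s <- .asResidueString(seq)
  pos <- tm26Position(tm2map)
  wt <- tm26Residue(tm2map)
  if (pos > nchar(s) || substring(s, pos, pos) != wt)
    stop("stale annotation: sequence residue at position ", pos,
         " does not match the mapped TM2.6 residue '", wt, "'",
         call. = FALSE)
  paste0(wt, pos, target)
}

#' Plan a minimal codon edit in a coding sequence
#'
#' Selects the minimal-distance codon for the target amino acid at a protein
#' position (lexicographic tie-break) and emits the absolute CDS
#' substitution coordinates.
#'
#' @param cds coding sequence (character or single-record
#'   \code{DNAStringSet}); length must be a multiple of 3.
#' @param proteinPosition 1-based protein position.
#' @param target target amino acid.
#' @param code genetic code table.
#' @param expectedResidue optional amino acid the CDS is expected to encode
#'   at that position; a mismatch is an error.
#' @return list with \code{protein_position}, \code{wt_codon},
#'   \code{new_codon}, \code{n_changes}, and \code{cds_substitutions}
#'   (data.frame \code{cds_index}, \code{from}, \code{to}).
#' @export
planCdsEdit <- function(cds, proteinPosition, target,
                        code = Biostrings::GENETIC_CODE,
                        expectedResidue = NULL) {
  s <- if (is(cds, "DNAStringSet")) as.character(cds)[[1L]]
       else if (is(cds, "DNAString")) as.character(cds)
       else toupper(as.character(cds)[[1L]])
  if (nchar(s) %% 3L != 0L)
    stop("CDS length must be a multiple of 3", call. = FALSE)
  proteinPosition <- as.integer(proteinPosition)
  if (proteinPosition < 1L || proteinPosition > nchar(s) %/% 3L)
    stop("protein position outside the CDS", call. = FALSE)
  cdsStart <- 3L * (proteinPosition - 1L) + 1L
  wtCodon <- substring(s, cdsStart, cdsStart + 2L)
  if (!is.null(expectedResidue) && code[wtCodon] != expectedResidue)
    stop("stale annotation: CDS codon ", wtCodon, " at position ",
         proteinPosition, " encodes '", code[wtCodon],
         "', expected '", expectedResidue, "'", call. = FALSE)
  edits <- minCodonEdits(wtCodon, target, code)
  newCodon <- edits$new_codon[1L]
  wtChars <- strsplit(wtCodon, "")[[1L]]
  newChars <- strsplit(newCodon, "")[[1L]]
  changed <- which(wtChars != newChars)
  list(protein_position = proteinPosition,
       wt_codon = wtCodon,
       new_codon = newCodon,
       n_changes = length(changed),
       cds_substitutions = data.frame(
         cds_index = cdsStart - 1L + changed,
         from = wtChars[changed],
         to = newChars[changed],
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Full substitution plan for one channel
#'
#' Combines \code{\link{designSeries}}, \code{\link{planProteinEdit}} and,
#' when a coding sequence is supplied, \code{\link{planCdsEdit}} into one
#' table describing the graded gain-of-function series at TM2.6.
#'
#' @param seq protein sequence.
#' @param tm2map a \code{\linkS4class{TM2Map}} for \code{seq}.
#' @param cds optional coding sequence for codon-edit planning.
#' @param includeControls passed to \code{\link{designSeries}}.
#' @param code genetic code table.
#' @return data.frame with columns \code{channel_id}, \code{wt_label},
#'   \code{target}, \code{tier}, \code{mutation_label}, and (with a CDS)
#'   \code{wt_codon}, \code{new_codon}, \code{n_changes},
#'   \code{cds_positions}.
#' @export
substitutionPlan <- function(seq, tm2map, cds = NULL,
                             includeControls = FALSE,
                             code = Biostrings::GENETIC_CODE) {
  stopifnot(is(tm2map, "TM2Map"))
  series <- designSeries(tm26Residue(tm2map), includeControls)
  out <- data.frame(
    channel_id = channelId(tm2map),
    wt_label = tm26Label(tm2map),
    target = series$target,
    tier = series$tier,
    mutation_label = vapply(series$target, function(t)
      planProteinEdit(seq, tm2map, t), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(cds)) {
    plans <- lapply(series$target, function(t)
      planCdsEdit(cds, tm26Position(tm2map), t, code,
                  expectedResidue = tm26Residue(tm2map)))
    out$wt_codon <- vapply(plans, `[[`, character(1), "wt_codon")
    out$new_codon <- vapply(plans, `[[`, character(1), "new_codon")
    out$n_changes <- vapply(plans, `[[`, integer(1), "n_changes")
    out$cds_positions <- vapply(plans, function(p)
      paste(p$cds_substitutions$cds_index, collapse = ","), character(1))
  }
  out
}
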