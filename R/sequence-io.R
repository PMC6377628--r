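# Sequence input/output.
#
# Sequences live in Biostrings containers: proteins in AAStringSet,
# coding sequences in DNAStringSet, alignments in AAMultipleAlignment.
# Residue positions are 1-based everywhere in the package.

.checkLetters <- function(chars, allowed, recordId, what = "sequence") {
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' in %s '%s' at position %d",
                 chars[bad[1L]], what, recordId, bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

.splitHeader <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  desc[desc == headers & !grepl("\\s", headers)] <- ""
  list(id = id, description = desc)
}

#' Read channel sequences from FASTA
#'
#' Reads unaligned FASTA and validates the alphabet. Protein sequences may
#' contain the 20 canonical amino acids plus \code{X}; nucleotide sequences
#' only \code{A}, \code{C}, \code{G}, \code{T}. Residues are uppercased on
#' input; the gap character \code{-} is rejected (use
#' \code{\link{readChannelAlignment}} for aligned input).
#'
#' @param path FASTA file path.
#' @param alphabet \code{"protein"} or \code{"nucleotide"}.
#' @return An \code{AAStringSet} (protein) or \code{DNAStringSet}
#'   (nucleotide). Names hold record ids; the full header description is in
#'   \code{metadata(x)$description}.
#' @export
readChannelFasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  hdr <- .splitHeader(names(raw))
  if (anyDuplicated(hdr$id)) {
    stop("duplicate ids in FASTA file: ",
         paste(unique(hdr$id[duplicated(hdr$id)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  allowed <- if (alphabet == "protein") c(AA_LETTERS, "X") else NT_LETTERS
  for (i in seq_along(seqs)) {
    .checkLetters(strsplit(seqs[i], "")[[1L]], allowed, hdr$id[i])
  }
  out <- if (alphabet == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(out) <- hdr$id
  S4Vectors::metadata(out)$description <- stats::setNames(hdr$desc, hdr$id)
  out
}

#' Read an aligned FASTA protein alignment
#'
#' Rows must all have the same number of columns and contain only amino-acid
#' letters, \code{X}, or the gap character \code{-}. At least two rows are
#' required.
#'
#' @param path aligned FASTA file path.
#' @return An \code{AAMultipleAlignment}.
#' @export
readChannelAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  if (length(raw) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  if (length(unique(Biostrings::width(raw))) != 1L) {
    stop("ragged alignment: rows have unequal lengths", call. = FALSE)
  }
  hdr <- .splitHeader(names(raw))
  if (anyDuplicated(hdr$id)) stop("duplicate ids in alignment", call. = FALSE)
  seqs <- toupper(as.character(raw))
  allowed <- c(AA_LETTERS, "X", "-")
  for (i in seq_along(seqs)) {
    .checkLetters(strsplit(seqs[i], "")[[1L]], allowed, hdr$id[i], "alignment row")
  }
  Biostrings::AAMultipleAlignment(stats::setNames(seqs, hdr$id))
}

#' Write a results table as TSV or JSON
#'
#' TSV output always carries a header line; an empty table yields a
#' header-only file. Column order is preserved as given. JSON output is an
#' array of row objects and round-trips through \code{jsonlite::fromJSON}.
#'
#' @param records a data.frame.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
writeResultTable <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "tsv") {
    utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

# Write sequences to FASTA (round-trip partner of readChannelFasta).
#' Write sequences to FASTA
#' @param x an XStringSet (or named character vector).
#' @param path output file path.
#' @export
writeChannelFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
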