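#' @importFrom Biostrings readBStringSet DNAStringSet writeXStringSet width
NULL

#' Read contigs from a FASTA file
#'
#' Reads a (wrapped or single-line) multi-record FASTA file without imposing
#' the strict DNA alphabet, so that raw records may still carry ambiguity
#' codes, gaps (\code{-}) and pads (\code{*}) to be cleaned downstream. The
#' record id is the first whitespace-delimited header token; the remainder of
#' the header is kept as the description.
#'
#' @param path path to a FASTA file.
#' @return a \code{BStringSet} named by the id, with a \code{description}
#'   metadata column.
#' @export
readContigs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0)
    mStop("emptyInputError", sprintf("no sequences in '%s'", path))
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  names(x) <- id
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc)
  x
}

#' Validate contig identifiers
#'
#' Input identifiers must be unique; a duplicate rejects the whole input so
#' no partial processing can occur.
#'
#' @param ids character vector of sequence ids (or a named XStringSet).
#' @return invisibly \code{TRUE}; raises a classed error otherwise.
#' @export
validateContigIds <- function(ids) {
  if (!is.character(ids)) ids <- names(ids)
  if (length(ids) == 0)
    mStop("emptyInputError", "no sequences: empty input")
  if (any(is.na(ids)) || any(!nzchar(ids)))
    mStop("emptyIdError", "empty sequence identifier")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    mStop("duplicateIdError",
          sprintf("duplicated sequence identifier: '%s'", dup[1]),
          id = dup[1])
  invisible(TRUE)
}

#' Clean a nucleotide sequence
#'
#' Uppercases, removes gaps (\code{-}) and pads (\code{*}), and replaces
#' every remaining character outside \code{A,C,G,T} (including \code{U}) by
#' \code{N}. Vectorised over its input; idempotent.
#'
#' @param seq character vector of sequences.
#' @return character vector over the \code{{A,C,G,T,N}} alphabet.
#' @export
cleanSequence <- function(seq) {
  out <- gsub("[-*]", "", toupper(seq))
  if (any(!nzchar(out)))
    mStop("degenerateSequenceError",
          "sequence empty after gap/pad removal")
  gsub("[^ACGT]", "N", out)
}

#' Clean a set of contigs
#'
#' @param contigs \code{BStringSet}/\code{DNAStringSet} or named character.
#' @return \code{DNAStringSet} of cleaned sequences, same names/order.
#' @export
cleanContigs <- function(contigs) {
  s <- as.character(contigs)
  Biostrings::DNAStringSet(stats::setNames(cleanSequence(s), names(contigs)))
}

#' Remove contigs shorter than a minimum length
#'
#' The threshold is strict: a contig exactly at \code{minLen} is kept.
#'
#' @param contigs \code{DNAStringSet}.
#' @param minLen minimum length in bp (default 200).
#' @return \code{DNAStringSet} of the kept contigs, input order preserved,
#'   with attribute \code{removed} holding the ids of dropped contigs.
#' @export
filterShortContigs <- function(contigs, minLen = 200) {
  stopifnot(minLen >= 0)
  keep <- Biostrings::width(contigs) >= minLen
  out <- contigs[keep]
  attr(out, "removed") <- names(contigs)[!keep]
  out
}

#' Preprocess contigs: validate, clean, filter
#'
#' Runs the full preprocessing stage: id validation (duplicates reject the
#' run), ambiguity/gap cleaning, and the minimum-length filter, and builds
#' the per-contig report.
#'
#' @param contigs \code{BStringSet} from \code{readContigs}, or a FASTA path.
#' @param minLen minimum contig length in bp.
#' @return list with \code{contigs} (cleaned, filtered \code{DNAStringSet}),
#'   \code{report} (data.frame: id, original_length, cleaned_length, kept)
#'   and \code{n_removed}.
#' @export
preprocessContigs <- function(contigs, minLen = 200) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- readContigs(contigs)
  validateContigIds(names(contigs))
  origLen <- Biostrings::width(contigs)
  cleaned <- cleanContigs(contigs)
  kept <- filterShortContigs(cleaned, minLen)
  report <- data.frame(
    id = names(contigs),
    original_length = origLen,
    cleaned_length = Biostrings::width(cleaned),
    kept = names(contigs) %in% names(kept),
    stringsAsFactors = FALSE)
  list(contigs = kept, report = report, n_removed = sum(!report$kept))
}

#' Write contigs as 60-column wrapped FASTA
#'
#' @param contigs \code{DNAStringSet}.
#' @param path output file.
#' @export
writeContigFasta <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path, width = 60)
  invisible(path)
}

#' Write the preprocessing report TSV
#'
#' @param report data.frame from \code{preprocessContigs}.
#' @param path output file.
#' @export
writePreprocessReport <- function(report, path) {
  lines <- c(paste(colnames(report), collapse = "\t"),
             apply(report, 1, function(r) paste(trimws(r), collapse = "\t")))
  writeLinesC(lines, path)
  invisible(path)
}
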