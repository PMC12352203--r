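#' Read a protein sequence from FASTA
#'
#' Reads the first record of a FASTA file. The identifier is the first
#' whitespace-delimited header token; UniProt-style `sp|Q16678|CP1B1_HUMAN`
#' headers are reduced to the accession (`Q16678`).
#'
#' @param path FASTA file.
#' @param strict passed to [proteinSequence()]: error (default) or flag
#'   non-standard residue letters.
#' @return a [ProteinSequence-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x demo", "ACDEF"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  header <- names(set)[1]
  token <- strsplit(trimws(header), "\\s+")[[1]][1]
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  id <- if (length(parts) >= 2L) parts[2] else token
  proteinSequence(id, as.character(set[[1]]), strict = strict)
}

#' Write a ProteinSequence to FASTA
#'
#' @param seq a [ProteinSequence-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seq, path) {
  set <- Biostrings::AAStringSet(as.character(seq))
  names(set) <- proteinId(seq)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
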