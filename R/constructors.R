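#' Construct a ProteinSequence
#'
#' @param id accession string.
#' @param seq single string of one-letter codes, or a character vector of
#'   single letters.
#' @param strict if `TRUE` (default) any letter outside the 20-letter standard
#'   alphabet is an error naming its position; if `FALSE` such letters are
#'   replaced by the unknown marker `X` with a warning so downstream per-residue
#'   positions stay aligned.
#' @return a [ProteinSequence-class] object.
#' @examples
#' proteinSequence("x", "ACDEF")
#' @export
proteinSequence <- function(id, seq, strict = TRUE) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  seq <- toupper(seq)
  bad <- which(!(seq %in% .AA20))
  if (length(bad)) {
    if (strict)
      stop(sprintf("illegal residue code '%s' at position %d of %s",
                   seq[bad[1]], bad[1], id))
    warning(sprintf("%d non-standard residue code(s) replaced by 'X' in %s (first at position %d)",
                    length(bad), id, bad[1]))
    seq[bad] <- "X"
  }
  new("ProteinSequence", id = id, residues = seq)
}

#' Construct a PerResidueTrack
#'
#' @param proteinId accession string the track aligns to.
#' @param trackName label; tracks named `"pLDDT"` take values in `[0, 100]`,
#'   all others in `[0, 1]`.
#' @param values numeric vector, `NA` marking missing residues.
#' @return a [PerResidueTrack-class] object.
#' @export
perResidueTrack <- function(proteinId, trackName, values) {
  new("PerResidueTrack", proteinId = proteinId, trackName = trackName,
      values = as.numeric(values))
}

#' Construct a VariantScoreTable
#'
#' @param proteinId accession string.
#' @param pos integer positions (1-based).
#' @param ref,alt one-letter reference and alternate residues.
#' @param score pathogenicity scores in `[0, 1]`.
#' @param class optional class labels.
#' @return a [VariantScoreTable-class] object.
#' @export
variantScoreTable <- function(proteinId, pos, ref, alt, score,
                              class = NA_character_) {
  e <- data.frame(pos = as.integer(pos),
                  ref = rep_len(as.character(ref), length(pos)),
                  alt = as.character(alt), score = as.numeric(score),
                  class = rep_len(as.character(class), length(pos)),
                  stringsAsFactors = FALSE)
  e <- e[order(e$pos, e$alt), , drop = FALSE]
  rownames(e) <- NULL
  new("VariantScoreTable", proteinId = proteinId, entries = e)
}

#' Construct a RegionSet
#'
#' Intervals are 1-based and inclusive ("residues 1-14" covers 14 residues).
#' Regions of one kind must be non-overlapping; they are sorted by start.
#'
#' @param proteinId accession string.
#' @param start,end integer interval bounds, inclusive.
#' @param kind region kind label(s), e.g. `"IDPR"`, `"DPR"`,
#'   `"aggregation_hotspot"`, `"context_dependent"`; recycled.
#' @return a [RegionSet-class] object.
#' @export
regionSet <- function(proteinId, start = integer(), end = integer(),
                      kind = character()) {
  if (length(start) != length(end))
    stop("'start' and 'end' must have equal length")
  if (any(end < start)) stop("region end must be >= start")
  kind <- rep_len(as.character(kind), length(start))
  o <- order(kind, start)
  r <- IRanges::IRanges(start = as.integer(start)[o], end = as.integer(end)[o])
  S4Vectors::mcols(r)$kind <- kind[o]
  new("RegionSet", proteinId = proteinId, ranges = r)
}

fitResult <- function(a, b, c, rSquared, n, converged) {
  new("FitResult", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      rSquared = as.numeric(rSquared), n = as.integer(n),
      converged = isTRUE(converged))
}
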