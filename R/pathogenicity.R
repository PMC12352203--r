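#' Classify a pathogenicity score
#'
#' Applies the AlphaMissense three-class scheme: scores below 0.34 are likely
#' benign, scores above 0.564 likely pathogenic, and the closed band between
#' the two cutoffs (inclusive at both ends, so the three classes partition
#' `[0, 1]`) is ambiguous.
#'
#' @param score numeric score(s) in `[0, 1]`; vectorized.
#' @param benignMax lower cutoff (default 0.34).
#' @param pathogenicMin upper cutoff (default 0.564).
#' @return character vector over `"likely_benign"`, `"ambiguous"`,
#'   `"likely_pathogenic"`; `NA` in gives `NA` out.
#' @examples
#' classifyScore(c(0.9839, 0.381, 0.1))
#' @export
classifyScore <- function(score, benignMax = 0.34, pathogenicMin = 0.564) {
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop("score must lie in [0, 1]")
  out <- ifelse(score < benignMax, "likely_benign",
                ifelse(score <= pathogenicMin, "ambiguous",
                       "likely_pathogenic"))
  out[is.na(score)] <- NA_character_
  out
}

#' Per-residue mean pathogenicity track
#'
#' For every residue, averages the scores of all substitutions recorded at
#' that position (typically all 19 alternates). Residues with no recorded
#' substitution are missing, never 0.
#'
#' @param table a [VariantScoreTable-class].
#' @param length protein length (number of residues in the output track).
#' @return a [PerResidueTrack-class] named `"mean_pathogenicity"`.
#' @export
perResidueMean <- function(table, length) {
  e <- variantEntries(table)
  if (nrow(e) && max(e$pos) > length)
    stop("variant position ", max(e$pos), " exceeds protein length ", length)
  v <- rep(NA_real_, length)
  if (nrow(e)) {
    m <- tapply(e$score, e$pos, mean)
    v[as.integer(names(m))] <- as.numeric(m)
  }
  perResidueTrack(proteinId(table), "mean_pathogenicity", v)
}

#' Protein-level mean pathogenicity
#'
#' The headline number is the arithmetic mean over all substitution entries.
#' The mean of per-residue means is also computed; when entry counts differ
#' across residues the two can differ, in which case a message flags it. The
#' secondary mean is attached as attribute `"residueMean"`.
#'
#' @param table a [VariantScoreTable-class] with at least one entry.
#' @return numeric scalar (per-variant mean) with attribute `residueMean`.
#' @export
proteinMean <- function(table) {
  e <- variantEntries(table)
  if (nrow(e) == 0L) stop("empty variant table")
  perVariant <- mean(e$score)
  perResidue <- mean(tapply(e$score, e$pos, mean))
  if (abs(perVariant - perResidue) > 1e-9 * max(abs(perVariant), 1))
    message(sprintf(
      "per-variant mean (%.6f) and residue-of-means mean (%.6f) differ; reporting per-variant",
      perVariant, perResidue))
  structure(perVariant, residueMean = perResidue)
}

#' Look up a single variant
#'
#' Accepts either notation (`"G61E"` or `"p.Gly61Glu"`). When a sequence is
#' supplied, the reference letter of the variant is cross-checked against it.
#'
#' @param table a [VariantScoreTable-class].
#' @param variant variant string.
#' @param seq optional [ProteinSequence-class] for reference checking.
#' @return list with `score`, `class` (from [classifyScore()]), `pos`, `ref`,
#'   `alt`.
#' @export
lookupVariant <- function(table, variant, seq = NULL) {
  p <- parseVariant(variant)
  if (!is.null(seq)) {
    if (p$pos > length(seq))
      stop("position ", p$pos, " beyond sequence length ", length(seq))
    actual <- seq@residues[p$pos]
    if (actual != p$ref)
      stop(sprintf("ref mismatch: variant says %s at %d but sequence has %s",
                   p$ref, p$pos, actual))
  }
  e <- variantEntries(table)
  hit <- which(e$pos == p$pos & e$alt == p$alt)
  if (length(hit) == 0L)
    stop("variant ", variant, " not present in table")
  if (e$ref[hit] != p$ref)
    stop(sprintf("ref mismatch: table has %s at %d, variant says %s",
                 e$ref[hit], p$pos, p$ref))
  list(score = e$score[hit], class = classifyScore(e$score[hit]),
       pos = p$pos, ref = p$ref, alt = p$alt)
}
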