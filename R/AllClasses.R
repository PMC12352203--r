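#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
NULL

# 20-letter standard amino-acid alphabet, plus 'X' as the unknown marker
# tolerated by non-strict readers.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' ProteinSequence: an identified amino-acid chain
#'
#' Holds a protein accession and its one-letter residue string. Positions are
#' 1-based throughout the package. Only the 20 standard amino acids (plus `X`
#' as an explicit unknown marker) are accepted.
#'
#' @slot id single accession string (e.g. `"Q16678"`).
#' @slot residues character vector of one-letter codes, one per position.
#' @export
setClass("ProteinSequence",
         representation(id = "character", residues = "character"))

setValidity("ProteinSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@residues) < 1L)
    msg <- c(msg, "sequence must contain at least one residue")
  bad <- which(!(object@residues %in% c(.AA20, "X")))
  if (length(bad))
    msg <- c(msg, sprintf("illegal residue code '%s' at position %d",
                          object@residues[bad[1]], bad[1]))
  if (length(msg)) msg else TRUE
})

#' PerResidueTrack: one numeric value per residue
#'
#' A named per-residue signal aligned to a protein sequence: a disorder
#' predictor output, the consensus mean disorder profile (`"MDP"`), a
#' per-residue mean pathogenicity, a droplet-promoting probability (`"p_DP"`),
#' or AlphaFold model confidence (`"pLDDT"`). Values may be `NA` (missing);
#' non-missing values must be finite and lie in `[0, 1]`, except for the
#' `"pLDDT"` track which lies in `[0, 100]`.
#'
#' @slot proteinId accession the track is aligned to.
#' @slot trackName track label.
#' @slot values numeric vector, one element per residue position.
#' @export
setClass("PerResidueTrack",
         representation(proteinId = "character", trackName = "character",
                        values = "numeric"))

setValidity("PerResidueTrack", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L)
    msg <- c(msg, "'proteinId' must be a single string")
  if (length(object@trackName) != 1L || !nzchar(object@trackName))
    msg <- c(msg, "'trackName' must be a single non-empty string")
  if (length(object@values) < 1L)
    msg <- c(msg, "track must contain at least one value")
  v <- object@values[!is.na(object@values)]
  if (any(!is.finite(v)))
    msg <- c(msg, "non-missing track values must be finite")
  hi <- if (identical(object@trackName, "pLDDT")) 100 else 1
  tol <- 1e-9
  if (length(v) && (min(v) < -tol || max(v) > hi + tol))
    msg <- c(msg, sprintf("track '%s' values must lie in [0, %g]",
                          object@trackName, hi))
  if (length(msg)) msg else TRUE
})

#' VariantScoreTable: per-substitution pathogenicity scores
#'
#' One row per (position, alternate residue) missense substitution with its
#' pathogenicity score in `[0, 1]` and an optional class label.
#'
#' @slot proteinId accession string.
#' @slot entries data.frame with columns `pos` (integer, 1-based), `ref`,
#'   `alt` (one-letter codes), `score` (numeric in `[0, 1]`) and `class`
#'   (character, may be `NA`).
#' @export
setClass("VariantScoreTable",
         representation(proteinId = "character", entries = "data.frame"))

setValidity("VariantScoreTable", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("pos", "ref", "alt", "score", "class")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    if (any(e$ref == e$alt)) msg <- c(msg, "ref and alt residues must differ")
    if (any(e$score < 0 | e$score > 1, na.rm = TRUE))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (any(is.na(e$score))) msg <- c(msg, "scores must not be missing")
    if (anyDuplicated(paste(e$pos, e$alt)))
      msg <- c(msg, "duplicate (position, alt) entry")
  }
  if (length(msg)) msg else TRUE
})

#' RegionSet: typed 1-based inclusive intervals on a sequence
#'
#' Intervals such as intrinsically disordered regions (`"IDPR"`),
#' droplet-promoting regions (`"DPR"`) or aggregation hot spots, stored as an
#' [IRanges::IRanges] with a `kind` metadata column. Regions of one kind are
#' non-overlapping and sorted by start.
#'
#' @slot proteinId accession string.
#' @slot ranges [IRanges::IRanges] with `mcols(ranges)$kind`.
#' @export
setClass("RegionSet",
         representation(proteinId = "character", ranges = "IRanges"))

setValidity("RegionSet", function(object) {
  msg <- character()
  r <- object@ranges
  if (is.null(S4Vectors::mcols(r)$kind) && length(r))
    return("ranges must carry a 'kind' metadata column")
  if (length(r)) {
    if (any(IRanges::start(r) < 1L))
      msg <- c(msg, "region starts must be >= 1")
    kinds <- S4Vectors::mcols(r)$kind
    for (k in unique(kinds)) {
      rk <- r[kinds == k]
      if (is.unsorted(IRanges::start(rk)))
        msg <- c(msg, sprintf("regions of kind '%s' must be sorted by start", k))
      if (length(rk) > 1L &&
          any(IRanges::start(rk)[-1L] <= IRanges::end(rk)[-length(rk)]))
        msg <- c(msg, sprintf("regions of kind '%s' must not overlap", k))
    }
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: parameters and goodness of fit of the exponential-decay model
#'
#' Result of fitting `y = a * exp(-b * x) + c` (optionally with `c` fixed at 0)
#' by least squares.
#'
#' @slot a amplitude, in score units.
#' @slot b decay rate per unit disorder, constrained non-negative.
#' @slot c offset, in score units.
#' @slot rSquared coefficient of determination `1 - SS_res/SS_tot`.
#' @slot n number of residue pairs used.
#' @slot converged whether the optimiser reported convergence.
#' @export
setClass("FitResult",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        rSquared = "numeric", n = "integer",
                        converged = "logical"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (object@b < 0) msg <- c(msg, "decay rate 'b' must be >= 0")
  if (object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' GraphSummary: headline statistics of an interaction network
#'
#' @slot nNodes node count.
#' @slot nEdges edge count.
#' @slot avgNodeDegree `2 * nEdges / nNodes`.
#' @slot avgLocalClustering mean local (Watts-Strogatz) clustering
#'   coefficient, with nodes of degree < 2 contributing 0.
#' @export
setClass("GraphSummary",
         representation(nNodes = "integer", nEdges = "integer",
                        avgNodeDegree = "numeric",
                        avgLocalClustering = "numeric"))

setValidity("GraphSummary", function(object) {
  msg <- character()
  if (object@nNodes > 0 &&
      abs(object@avgNodeDegree - 2 * object@nEdges / object@nNodes) > 1e-9)
    msg <- c(msg, "avgNodeDegree must equal 2 * nEdges / nNodes")
  if (object@avgLocalClustering < -1e-12 || object@avgLocalClustering > 1 + 1e-12)
    msg <- c(msg, "avgLocalClustering must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LLPSCall: phase-separation classification of a protein
#'
#' Droplet `"driver"` when the overall liquid-liquid phase separation
#' probability pLLPS is at least 0.60; `"client"` when pLLPS is below 0.60 but
#' droplet-promoting regions exist; `"none"` otherwise.
#'
#' @slot pLLPS overall spontaneous phase-separation probability in `[0, 1]`.
#' @slot dprs [RegionSet] of droplet-promoting regions.
#' @slot classification one of `"driver"`, `"client"`, `"none"`.
#' @export
setClass("LLPSCall",
         representation(pLLPS = "numeric", dprs = "RegionSet",
                        classification = "character"))

setValidity("LLPSCall", function(object) {
  if (object@pLLPS < 0 || object@pLLPS > 1)
    return("pLLPS must lie in [0, 1]")
  expect <- if (object@pLLPS >= 0.60) "driver"
            else if (length(object@dprs@ranges) > 0L) "client" else "none"
  if (!identical(object@classification, expect))
    return(sprintf("classification '%s' inconsistent with pLLPS/DPRs (expect '%s')",
                   object@classification, expect))
  TRUE
})
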