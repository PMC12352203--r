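#' Accessors for DisorderMap objects
#'
#' Small accessor generics: `proteinId()` returns the accession an object is
#' tied to; `trackName()`/`trackValues()` the label and numeric values of a
#' [PerResidueTrack]; `variantEntries()` the substitution table of a
#' [VariantScoreTable]; `regionTable()` a plain data.frame view (1-based
#' inclusive `start`, `end`, `kind`) of a [RegionSet].
#'
#' @param x object.
#' @return see details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("trackName", function(x) standardGeneric("trackName"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("variantEntries", function(x) standardGeneric("variantEntries"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setMethod("proteinId", "ProteinSequence", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("proteinId", "PerResidueTrack", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("proteinId", "VariantScoreTable", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("proteinId", "RegionSet", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("trackName", "PerResidueTrack", function(x) x@trackName)

#' @rdname accessors
#' @export
setMethod("trackValues", "PerResidueTrack", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("variantEntries", "VariantScoreTable", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("regionTable", "RegionSet", function(x) {
  r <- x@ranges
  data.frame(start = IRanges::start(r), end = IRanges::end(r),
             kind = if (length(r)) S4Vectors::mcols(r)$kind else character())
})

#' @export
setMethod("length", "ProteinSequence", function(x) length(x@residues))

#' @export
setMethod("length", "PerResidueTrack", function(x) length(x@values))

#' @export
setMethod("length", "RegionSet", function(x) length(x@ranges))

#' @export
setMethod("as.character", "ProteinSequence",
          function(x) paste(x@residues, collapse = ""))

setMethod("show", "ProteinSequence", function(object) {
  s <- as.character(object)
  if (nchar(s) > 40) s <- paste0(substr(s, 1, 37), "...")
  cat(sprintf("ProteinSequence %s: %d aa\n  %s\n",
              object@id, length(object), s))
})

setMethod("show", "PerResidueTrack", function(object) {
  v <- object@values
  cat(sprintf("PerResidueTrack '%s' on %s: %d residues (%d missing)\n",
              object@trackName, object@proteinId, length(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range [%.3f, %.3f], mean %.3f\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                mean(v, na.rm = TRUE)))
})

setMethod("show", "VariantScoreTable", function(object) {
  e <- object@entries
  cat(sprintf("VariantScoreTable for %s: %d substitutions at %d positions\n",
              object@proteinId, nrow(e), length(unique(e$pos))))
})

setMethod("show", "RegionSet", function(object) {
  tab <- regionTable(object)
  cat(sprintf("RegionSet on %s: %d region(s)\n", object@proteinId, nrow(tab)))
  if (nrow(tab))
    for (i in seq_len(min(nrow(tab), 10)))
      cat(sprintf("  %s %d-%d\n", tab$kind[i], tab$start[i], tab$end[i]))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "Exponential decay fit y = a*exp(-b*x) + c\n  a = %.6g, b = %.6g, c = %.6g\n  R^2 = %.4f on n = %d pairs (converged: %s)\n",
    object@a, object@b, object@c, object@rSquared, object@n, object@converged))
})

setMethod("show", "GraphSummary", function(object) {
  cat(sprintf(
    "GraphSummary: %d nodes, %d edges\n  average node degree %.2f, average local clustering %.3f\n",
    object@nNodes, object@nEdges, object@avgNodeDegree,
    object@avgLocalClustering))
})

setMethod("show", "LLPSCall", function(object) {
  cat(sprintf("LLPSCall: pLLPS = %.4f, %d DPR(s) -> %s\n",
              object@pLLPS, length(object@dprs), object@classification))
})
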