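#' Extract droplet-promoting regions (DPRs)
#'
#' Maximal runs of consecutive residues whose droplet-promoting probability
#' is at least the threshold (0.60 by convention). Thin wrapper over
#' [extractRegions()] with `kind = "DPR"`. The default minimum run length of
#' 5 suppresses single-residue blips; set `minLength = 1` for raw runs.
#'
#' @param pDp a [PerResidueTrack-class] of droplet-promoting probabilities.
#' @param threshold probability cutoff (default 0.60).
#' @param minLength minimum run length kept (default 5).
#' @return a [RegionSet-class] of kind `"DPR"`.
#' @export
extractDprs <- function(pDp, threshold = 0.60, minLength = 5L) {
  extractRegions(pDp, threshold = threshold, minLength = minLength,
                 kind = "DPR")
}

#' Classify a protein's phase-separation behaviour
#'
#' Droplet driver when the overall spontaneous phase-separation probability
#' pLLPS is 0.60 or more; droplet client when pLLPS is below 0.60 but the
#' protein carries droplet-promoting regions; otherwise none.
#'
#' @param pLLPS protein-level probability in `[0, 1]`.
#' @param dprs a [RegionSet-class] of droplet-promoting regions.
#' @return an [LLPSCall-class].
#' @examples
#' dprs <- regionSet("p", c(1, 295), c(14, 322), "DPR")
#' classifyLlps(0.3692, dprs)  # client
#' @export
classifyLlps <- function(pLLPS, dprs) {
  if (is.na(pLLPS) || pLLPS < 0 || pLLPS > 1)
    stop("pLLPS must lie in [0, 1]")
  cls <- if (pLLPS >= 0.60) "driver"
         else if (length(dprs) > 0L) "client" else "none"
  new("LLPSCall", pLLPS = pLLPS, dprs = dprs, classification = cls)
}

#' Overlap report between two region sets
#'
#' For every region of `a`, lists the regions of `b` it intersects, with the
#' intersection length (in residues, under 1-based inclusive coordinates, so
#' adjacency is not overlap) and the Jaccard index
#' `|A intersect B| / |A union B|` per pair.
#'
#' @param a,b [RegionSet-class] objects on the same protein.
#' @return data.frame with columns `a_start`, `a_end`, `a_kind`, `b_start`,
#'   `b_end`, `b_kind`, `intersection`, `jaccard`; zero rows when nothing
#'   overlaps.
#' @export
annotateOverlaps <- function(a, b) {
  if (!identical(proteinId(a), proteinId(b)))
    stop("region sets are on different proteins: ",
         proteinId(a), " vs ", proteinId(b))
  ra <- a@ranges; rb <- b@ranges
  hits <- IRanges::findOverlaps(ra, rb)
  qa <- ra[S4Vectors::queryHits(hits)]
  qb <- rb[S4Vectors::subjectHits(hits)]
  inter <- IRanges::width(IRanges::pintersect(qa, qb))
  un <- IRanges::width(qa) + IRanges::width(qb) - inter
  data.frame(
    a_start = IRanges::start(qa), a_end = IRanges::end(qa),
    a_kind = if (length(qa)) S4Vectors::mcols(qa)$kind else character(),
    b_start = IRanges::start(qb), b_end = IRanges::end(qb),
    b_kind = if (length(qb)) S4Vectors::mcols(qb)$kind else character(),
    intersection = inter,
    jaccard = if (length(inter)) inter / un else numeric())
}
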