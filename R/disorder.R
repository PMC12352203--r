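#' Consensus mean disorder profile (MDP)
#'
#' Averages several per-residue disorder predictor tracks into the mean
#' disorder profile, the per-residue arithmetic mean over non-missing
#' predictor values, together with the per-residue sample standard deviation
#' (the error band around the consensus; 0 where only one predictor reports).
#'
#' @param tracks list of [PerResidueTrack-class] of equal length with values
#'   in `[0, 1]`.
#' @return list with `mdp` (track named `"MDP"`) and `sd` (track named
#'   `"MDP_sd"`).
#' @examples
#' t1 <- perResidueTrack("p", "a", c(0.2, 0.6))
#' t2 <- perResidueTrack("p", "b", c(0.4, 0.8))
#' trackValues(computeMdp(list(t1, t2))$mdp)
#' @export
computeMdp <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  lens <- vapply(tracks, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("tracks differ in length: ", paste(unique(lens), collapse = ", "))
  m <- do.call(cbind, lapply(tracks, trackValues))
  nOk <- rowSums(!is.na(m))
  if (any(nOk == 0L))
    stop("residue ", which(nOk == 0L)[1], " is missing in all tracks")
  mdp <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1L, function(r) stats::sd(r[!is.na(r)]))
  sdv[nOk == 1L] <- 0
  pid <- proteinId(tracks[[1]])
  list(mdp = perResidueTrack(pid, "MDP", mdp),
       sd = perResidueTrack(pid, "MDP_sd", sdv))
}

#' Percentage of predicted disordered residues (PPDR)
#'
#' Share (in percent) of non-missing residues whose disorder score is greater
#' than or equal to the threshold (0.5 by convention: the boundary between
#' ordered and disordered states).
#'
#' @param track a [PerResidueTrack-class] of disorder scores.
#' @param threshold disorder cutoff, default 0.5.
#' @return percentage in `[0, 100]`.
#' @examples
#' ppdr(perResidueTrack("p", "d", c(0.6, 0.4, 0.5, 0.2)))  # 50
#' @export
ppdr <- function(track, threshold = 0.5) {
  v <- trackValues(track)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("track has no non-missing values")
  100 * sum(v >= threshold) / length(v)
}

#' Classify a protein by its PPDR
#'
#' Fixed three-way scheme: highly ordered below 10%, moderately disordered
#' from 10% up to (but excluding) 30%, highly disordered at 30% and above.
#'
#' @param ppdrValue percentage(s) in `[0, 100]`; vectorized.
#' @return character vector over `"highly_ordered"`,
#'   `"moderately_disordered"`, `"highly_disordered"`.
#' @export
classifyDisorder <- function(ppdrValue) {
  if (any(is.na(ppdrValue)) || any(ppdrValue < 0 | ppdrValue > 100))
    stop("PPDR must lie in [0, 100]")
  ifelse(ppdrValue < 10, "highly_ordered",
         ifelse(ppdrValue < 30, "moderately_disordered", "highly_disordered"))
}

#' Extract threshold-run regions from a per-residue track
#'
#' Maximal runs of consecutive residues with value greater than or equal to
#' `threshold`. Missing values break runs; runs shorter than `minLength` are
#' dropped. Serves both disordered-region extraction (disorder tracks,
#' threshold 0.5) and droplet-promoting-region extraction (p_DP tracks,
#' threshold 0.60, see [extractDprs()]).
#'
#' @param track a [PerResidueTrack-class].
#' @param threshold finite cutoff; residues at or above it belong to a run.
#' @param minLength minimum run length kept (default 1).
#' @param kind region kind label for the result.
#' @return a [RegionSet-class].
#' @examples
#' tr <- perResidueTrack("p", "d", c(0.7, 0.7, 0.3, 0.9))
#' regionTable(extractRegions(tr, 0.5, kind = "IDPR"))
#' @export
extractRegions <- function(track, threshold, minLength = 1L, kind = "region") {
  stopifnot(is.finite(threshold), minLength >= 1L)
  v <- trackValues(track)
  above <- !is.na(v) & v >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLength
  regionSet(proteinId(track), starts[keep], ends[keep], kind)
}

#' Summarise disorder across predictors
#'
#' Computes PPDR and the three-way disorder category per predictor and for
#' the consensus MDP.
#'
#' @param tracks list of predictor [PerResidueTrack-class] objects.
#' @param threshold disorder cutoff used by [ppdr()], default 0.5.
#' @return list with `perPredictor` (data.frame: `predictor`, `ppdr`,
#'   `category`), `mdpPpdr`, `mdpCategory`, and the `mdp`/`sd` tracks.
#' @export
disorderSummary <- function(tracks, threshold = 0.5) {
  cons <- computeMdp(tracks)
  pp <- vapply(tracks, ppdr, numeric(1), threshold = threshold)
  per <- data.frame(predictor = vapply(tracks, trackName, ""),
                    ppdr = unname(pp),
                    category = classifyDisorder(unname(pp)),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  mp <- ppdr(cons$mdp, threshold)
  list(perPredictor = per, mdpPpdr = mp, mdpCategory = classifyDisorder(mp),
       mdp = cons$mdp, sd = cons$sd)
}

#' Convert a RegionSet to BED-style coordinates
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so a
#' region `start..end` becomes `(start - 1, end)`.
#'
#' @param regions a [RegionSet-class].
#' @return data.frame with `chrom` (protein id), `chromStart`, `chromEnd`,
#'   `name` (kind).
#' @export
regionsToBed <- function(regions) {
  tab <- regionTable(regions)
  data.frame(chrom = proteinId(regions),
             chromStart = tab$start - 1L,
             chromEnd = tab$end,
             name = tab$kind)
}
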