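#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every knob the generators use, with defaults that emulate a
#' CYP1B1-like study protein: 543 residues, six correlated pseudo-predictors
#' of disorder, a planted exponential-decay coupling between latent disorder
#' and variant pathogenicity (`a = 0.6`, `b = 4`, `c = 0.2`), per-variant
#' noise 0.1, per-predictor noise 0.05, three planted droplet-promoting
#' regions at 1-14, 295-322 and 367-377, an overall phase-separation
#' probability of 0.3692, and a 56-node / 268-edge interaction graph.
#'
#' A single global `seed` fans out to fixed per-generator substreams, so
#' adding one generator to a script never perturbs the draws of another.
#'
#' @param length residue count.
#' @param nPredictors number of pseudo-predictor disorder tracks.
#' @param decayParams named vector `c(a=, b=, c=)` of the planted decay.
#' @param variantNoiseSd Gaussian noise sd on each variant score.
#' @param predictorNoiseSd Gaussian noise sd on each predictor track.
#' @param smoothness moving-average window applied to the latent profile.
#' @param plantedDprs list of `c(start, end)` intervals (1-based inclusive,
#'   disjoint) forced above the droplet threshold.
#' @param composition named frequency vector over the 20 codes (uniform by
#'   default).
#' @param graphSpec named vector `c(nNodes=, nEdges=)`.
#' @param pLLPS protein-level phase-separation probability to report.
#' @param proteinId accession used for all generated objects.
#' @param seed integer master seed.
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(length = 543L, nPredictors = 6L,
                             decayParams = c(a = 0.6, b = 4, c = 0.2),
                             variantNoiseSd = 0.1, predictorNoiseSd = 0.05,
                             smoothness = 21L,
                             plantedDprs = list(c(1L, 14L), c(295L, 322L),
                                                c(367L, 377L)),
                             composition = NULL,
                             graphSpec = c(nNodes = 56L, nEdges = 268L),
                             pLLPS = 0.3692,
                             proteinId = "SYNP001", seed = 1L) {
  if (is.null(composition)) {
    composition <- rep(1 / 20, 20)
    names(composition) <- .AA20
  }
  composition <- composition[.AA20]
  if (any(is.na(composition)) || abs(sum(composition) - 1) > 1e-6)
    stop("composition must be named over the 20 codes and sum to 1")
  stopifnot(length >= 1L, nPredictors >= 1L,
            variantNoiseSd >= 0, predictorNoiseSd >= 0, smoothness >= 1L,
            pLLPS >= 0, pLLPS <= 1)
  d <- decayParams[c("a", "b", "c")]
  if (any(is.na(d))) stop("decayParams must be named c(a=, b=, c=)")
  if (d["b"] < 0) stop("decay rate must be >= 0")
  if (d["a"] + d["c"] > 1 + 1e-9)
    warning("a + c > 1: scores at zero disorder will be clipped to 1")
  if (length(plantedDprs)) {
    iv <- do.call(rbind, plantedDprs)
    if (any(iv < 1L) || any(iv[, 2] > length) || any(iv[, 2] < iv[, 1]))
      stop("planted intervals must satisfy 1 <= start <= end <= length")
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1] <= iv[-nrow(iv), 2]))
      stop("planted intervals must be disjoint")
  }
  if (graphSpec["nEdges"] >
      graphSpec["nNodes"] * (graphSpec["nNodes"] - 1) / 2)
    stop("infeasible edge count: max is n*(n-1)/2")
  structure(list(length = as.integer(length),
                 nPredictors = as.integer(nPredictors),
                 decayParams = d, variantNoiseSd = variantNoiseSd,
                 predictorNoiseSd = predictorNoiseSd,
                 smoothness = as.integer(smoothness),
                 plantedDprs = plantedDprs, composition = composition,
                 graphSpec = graphSpec, pLLPS = pLLPS,
                 proteinId = proteinId, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# fixed per-generator substream offsets (kept < 2^31 with any small seed)
.subSeed <- function(config, offset) config$seed * 1000L + offset

#' Generate a random protein sequence
#'
#' Residues drawn i.i.d. from the configured composition.
#'
#' @param config a [simulationConfig()].
#' @return a [ProteinSequence-class].
#' @export
genSequence <- function(config) {
  set.seed(.subSeed(config, 1L))
  res <- sample(.AA20, config$length, replace = TRUE,
                prob = config$composition)
  proteinSequence(config$proteinId, res)
}

#' Generate a latent disorder profile and noisy predictor tracks
#'
#' The latent profile is a Gaussian random walk smoothed by a centered moving
#' average (window `smoothness`), standardised, and squashed to `[0, 1]`
#' through a logistic map. Each pseudo-predictor observes the latent profile
#' plus independent Gaussian noise (sd `predictorNoiseSd`), clipped to
#' `[0, 1]`.
#'
#' @param config a [simulationConfig()].
#' @return list with `latent` (a [PerResidueTrack-class]) and `tracks`
#'   (list of `nPredictors` tracks named `pred1`, `pred2`, ...).
#' @export
genDisorderTracks <- function(config) {
  set.seed(.subSeed(config, 2L))
  n <- config$length
  walk <- cumsum(stats::rnorm(n))
  sm <- .runMean(walk, min(config$smoothness, n))
  z <- (sm - mean(sm)) / max(stats::sd(sm), .Machine$double.eps)
  latent <- stats::plogis(2 * z)
  tracks <- lapply(seq_len(config$nPredictors), function(k) {
    obs <- latent + stats::rnorm(n, 0, config$predictorNoiseSd)
    perResidueTrack(config$proteinId, paste0("pred", k),
                    pmin(1, pmax(0, obs)))
  })
  names(tracks) <- vapply(tracks, trackName, "")
  list(latent = perResidueTrack(config$proteinId, "latent", latent),
       tracks = tracks)
}

#' Generate a variant score table from a planted decay
#'
#' For every residue and each of its 19 alternate residues, the score is
#' `a * exp(-b * latent_i) + c` plus Gaussian noise (sd `variantNoiseSd`),
#' clipped to `[0, 1]`. Class labels follow [classifyScore()].
#'
#' @param config a [simulationConfig()].
#' @param latent latent disorder [PerResidueTrack-class] (from
#'   [genDisorderTracks()]).
#' @param seq the [ProteinSequence-class] providing reference residues.
#' @return a [VariantScoreTable-class] with `19 * length` entries.
#' @export
genPathogenicity <- function(config, latent, seq) {
  stopifnot(length(latent) == config$length, length(seq) == config$length)
  set.seed(.subSeed(config, 3L))
  d <- config$decayParams
  lv <- trackValues(latent)
  ref <- seq@residues
  alts <- lapply(ref, function(r) setdiff(.AA20, r))
  pos <- rep(seq_len(config$length), each = 19L)
  refCol <- rep(ref, each = 19L)
  altCol <- unlist(alts)
  mu <- d["a"] * exp(-d["b"] * lv[pos]) + d["c"]
  score <- pmin(1, pmax(0, mu + stats::rnorm(length(pos), 0,
                                             config$variantNoiseSd)))
  variantScoreTable(config$proteinId, pos, refCol, altCol, unname(score),
                    classifyScore(unname(score)))
}

#' Generate a droplet-promoting probability track
#'
#' Inside planted intervals the probability is `0.60 + U(0, 0.35)`; outside
#' it is `U(0, 0.55)`, safely below the 0.60 threshold, so region extraction
#' recovers exactly the planted intervals.
#'
#' @param config a [simulationConfig()].
#' @return list with `track` (a [PerResidueTrack-class] named `"p_DP"`) and
#'   `pLLPS` (from the config).
#' @export
genPdp <- function(config) {
  set.seed(.subSeed(config, 4L))
  n <- config$length
  v <- stats::runif(n, 0, 0.55)
  for (iv in config$plantedDprs) {
    idx <- iv[1]:iv[2]
    v[idx] <- 0.60 + stats::runif(length(idx), 0, 0.35)
  }
  list(track = perResidueTrack(config$proteinId, "p_DP", v),
       pLLPS = config$pLLPS)
}

#' Generate a random interaction graph
#'
#' A uniform random simple graph with exactly the configured node and edge
#' counts (Erdos-Renyi G(n, m)), edge weights drawn from the 900-1000
#' high-confidence score band.
#'
#' @param config a [simulationConfig()].
#' @return an undirected [igraph::igraph] with `weight` edge attribute.
#' @export
genGraph <- function(config) {
  set.seed(.subSeed(config, 5L))
  n <- as.integer(config$graphSpec["nNodes"])
  m <- as.integer(config$graphSpec["nEdges"])
  g <- igraph::sample_gnm(n, m, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  igraph::E(g)$weight <- sample(900:1000, m, replace = TRUE)
  g
}

#' Write a full set of synthetic pipeline inputs
#'
#' Generates every input the pipeline reads (FASTA sequence, variant score
#' TSV, disorder profile CSV, droplet-probability CSV, edge-list TSV) into a
#' directory, and returns the file paths together with the ground truth used
#' to generate them.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths) and `truth` (latent track,
#'   planted decay parameters, planted DPR intervals, graph).
#' @export
writeSyntheticInputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq <- genSequence(config)
  dis <- genDisorderTracks(config)
  am <- genPathogenicity(config, dis$latent, seq)
  pdp <- genPdp(config)
  g <- genGraph(config)
  paths <- c(
    sequence = file.path(dir, "sequence.fasta"),
    amTable = file.path(dir, "variants.tsv"),
    disorderCsv = file.path(dir, "disorder.csv"),
    fuzdrop = file.path(dir, "pdp.csv"),
    stringEdges = file.path(dir, "edges.tsv"))
  writeFasta(seq, paths["sequence"])
  writeAlphaMissense(am, paths["amTable"])
  writeDisorderCsv(dis$tracks, paths["disorderCsv"], seq = seq)
  writeFuzdropProfile(pdp$track, pdp$pLLPS, paths["fuzdrop"], seq = seq)
  writeStringEdges(g, paths["stringEdges"])
  list(paths = paths,
       truth = list(latent = dis$latent, decayParams = config$decayParams,
                    plantedDprs = config$plantedDprs, graph = g,
                    pLLPS = config$pLLPS))
}
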