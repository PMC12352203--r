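#' Build a pipeline configuration
#'
#' Gathers input paths, the fixed analysis thresholds and output options for
#' [runPipeline()]. Any input path may be `NULL`; the corresponding stage is
#' then skipped with a notice.
#'
#' @param sequence FASTA file.
#' @param amTable variant score TSV (AlphaMissense dialect).
#' @param disorderCsv multi-predictor disorder CSV.
#' @param fuzdrop droplet-probability CSV with pLLPS header.
#' @param stringEdges edge-list TSV.
#' @param structure PDB file for B-factor repainting.
#' @param background composition background name or CSV path (see
#'   [loadBackground()]).
#' @param disorderThreshold disorder cutoff (default 0.5).
#' @param amBenignMax,amPathogenicMin pathogenicity class cutoffs
#'   (defaults 0.34 and 0.564).
#' @param pllpsThreshold droplet threshold (default 0.60).
#' @param stringMinScore edge confidence threshold on the 0-1 scale
#'   (default 0.900).
#' @param window smoothing window for the correlation stage (default 10).
#' @param dprMinLength minimum droplet-region run length (default 5).
#' @param outDir output directory.
#' @param seed integer seed for the resampling stages.
#' @param iterations composition bootstrap iterations.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(sequence = NULL, amTable = NULL,
                           disorderCsv = NULL, fuzdrop = NULL,
                           stringEdges = NULL, structure = NULL,
                           background = "synthetic_globular",
                           disorderThreshold = 0.5, amBenignMax = 0.34,
                           amPathogenicMin = 0.564, pllpsThreshold = 0.60,
                           stringMinScore = 0.900, window = 10L,
                           dprMinLength = 5L,
                           outDir = tempfile("dismap_"), seed = 1L,
                           iterations = 2000L) {
  structure(list(sequence = sequence, amTable = amTable,
                 disorderCsv = disorderCsv, fuzdrop = fuzdrop,
                 stringEdges = stringEdges, structure = structure,
                 background = background,
                 disorderThreshold = disorderThreshold,
                 amBenignMax = amBenignMax,
                 amPathogenicMin = amPathogenicMin,
                 pllpsThreshold = pllpsThreshold,
                 stringMinScore = stringMinScore,
                 window = as.integer(window),
                 dprMinLength = as.integer(dprMinLength),
                 outDir = outDir, seed = as.integer(seed),
                 iterations = as.integer(iterations)),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and reports all violations at once rather than
#' stopping at the first.
#'
#' @param config a [pipelineConfig()].
#' @return list with `valid` (logical) and `errors` (character vector, empty
#'   when valid).
#' @export
validatePipelineConfig <- function(config) {
  errors <- character()
  chk01 <- function(x, nm) {
    if (!is.numeric(config[[x]]) || is.na(config[[x]]) ||
        config[[x]] < 0 || config[[x]] > 1)
      errors <<- c(errors, sprintf("%s must lie in [0, 1]", nm))
  }
  chk01("disorderThreshold", "disorder threshold")
  chk01("amBenignMax", "benign cutoff")
  chk01("amPathogenicMin", "pathogenic cutoff")
  chk01("pllpsThreshold", "pLLPS threshold")
  chk01("stringMinScore", "edge confidence threshold")
  if (is.numeric(config$amBenignMax) && is.numeric(config$amPathogenicMin) &&
      config$amBenignMax > config$amPathogenicMin)
    errors <- c(errors,
                "benign cutoff must not exceed the pathogenic cutoff")
  if (!is.numeric(config$window) || config$window < 1)
    errors <- c(errors, "window must be >= 1")
  if (!is.numeric(config$dprMinLength) || config$dprMinLength < 1)
    errors <- c(errors, "dprMinLength must be >= 1")
  if (!is.numeric(config$iterations) || config$iterations < 100)
    errors <- c(errors, "iterations must be >= 100")
  for (p in c("sequence", "amTable", "disorderCsv", "fuzdrop",
              "stringEdges", "structure"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      errors <- c(errors, sprintf("input '%s' not readable: %s",
                                  p, config[[p]]))
  list(valid = length(errors) == 0L, errors = errors)
}

#' Run the full disorder-pathogenicity pipeline
#'
#' Executes, for whichever inputs are configured: consensus disorder
#' profiling (MDP, PPDR, disordered regions), per-residue pathogenicity
#' aggregation, the exponential-decay correlation between the two,
#' droplet-region extraction and phase-separation classification, amino-acid
#' composition enrichment, and network summary statistics. Absent optional
#' inputs skip their stage with a notice. Per-stage CSVs, a JSON report and
#' an input-checksum manifest are written to `outDir`.
#'
#' @param config a [pipelineConfig()].
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
runPipeline <- function(config) {
  val <- validatePipelineConfig(config)
  if (!val$valid)
    stop("invalid pipeline configuration:\n  ",
         paste(val$errors, collapse = "\n  "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "DisorderMap",
                 version = as.character(utils::packageVersion("DisorderMap")),
                 seed = config$seed, stages = list())
  seq <- NULL; mdp <- NULL; pathTrack <- NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$sequence)) {
    seq <- stage("sequence", readFasta(config$sequence))
    report$stages$sequence <- list(id = proteinId(seq), length = length(seq))
  } else message("no sequence input; sequence/composition stages skipped")

  if (!is.null(config$disorderCsv)) {
    report$stages$disorder <- stage("disorder", {
      pid <- if (is.null(seq)) "unknown" else proteinId(seq)
      tracks <- readDisorderCsv(config$disorderCsv, proteinId = pid)
      ds <- disorderSummary(tracks, threshold = config$disorderThreshold)
      mdp <- ds$mdp
      writeDisorderCsv(c(tracks, list(ds$mdp, ds$sd)),
                       file.path(config$outDir, "disorder_profile.csv"),
                       seq = seq)
      idpr <- extractRegions(ds$mdp, config$disorderThreshold, kind = "IDPR")
      utils::write.csv(regionTable(idpr),
                       file.path(config$outDir, "idpr_regions.csv"),
                       row.names = FALSE)
      list(ppdr = stats::setNames(as.list(ds$perPredictor$ppdr),
                                  ds$perPredictor$predictor),
           category = stats::setNames(as.list(ds$perPredictor$category),
                                      ds$perPredictor$predictor),
           mdpPpdr = ds$mdpPpdr, mdpCategory = ds$mdpCategory,
           idprRegions = regionTable(idpr))
    })
  } else message("no disorder input; disorder stage skipped")

  if (!is.null(config$amTable)) {
    report$stages$pathogenicity <- stage("pathogenicity", {
      pid <- if (is.null(seq)) stop("pathogenicity stage needs a sequence")
             else proteinId(seq)
      am <- readAlphaMissense(config$amTable, pid)
      pathTrack <- perResidueMean(am, length(seq))
      pm <- proteinMean(am)
      out <- data.frame(res_index = seq_len(length(seq)),
                        res = seq@residues,
                        mean_pathogenicity = trackValues(pathTrack),
                        class_of_mean = classifyScore(
                          trackValues(pathTrack), config$amBenignMax,
                          config$amPathogenicMin))
      utils::write.csv(out,
                       file.path(config$outDir, "pathogenicity.csv"),
                       row.names = FALSE, na = "NA")
      list(nVariants = nrow(variantEntries(am)),
           proteinMean = as.numeric(pm),
           residueMeanOfMeans = attr(pm, "residueMean"))
    })
  } else message("no variant table; pathogenicity stage skipped")

  if (!is.null(mdp) && !is.null(pathTrack)) {
    report$stages$correlation <- stage("correlation", {
      cor <- correlateDisorderPathogenicity(mdp, pathTrack,
                                            window = config$window)
      utils::write.csv(cor$table,
                       file.path(config$outDir, "correlation_pairs.csv"),
                       row.names = FALSE, na = "NA")
      f <- cor$fit
      list(a = f@a, b = f@b, c = f@c, rSquared = f@rSquared, n = f@n,
           converged = f@converged, window = config$window)
    })
  }

  if (!is.null(config$fuzdrop)) {
    report$stages$phase <- stage("phase", {
      pid <- if (is.null(seq)) "unknown" else proteinId(seq)
      fz <- readFuzdropProfile(config$fuzdrop, proteinId = pid)
      dprs <- extractDprs(fz$track, threshold = config$pllpsThreshold,
                          minLength = config$dprMinLength)
      call <- classifyLlps(fz$pLLPS, dprs)
      utils::write.csv(regionTable(dprs),
                       file.path(config$outDir, "dpr_regions.csv"),
                       row.names = FALSE)
      list(pLLPS = fz$pLLPS, classification = call@classification,
           dprRegions = regionTable(dprs))
    })
  } else message("no droplet-probability input; phase stage skipped")

  if (!is.null(seq)) {
    report$stages$composition <- stage("composition", {
      bg <- loadBackground(config$background)
      comp <- compositionSignificance(seq, bg,
                                      iterations = config$iterations,
                                      seed = config$seed)
      utils::write.csv(comp,
                       file.path(config$outDir, "composition.csv"),
                       row.names = FALSE, na = "NA")
      list(nSignificant = sum(comp$significant, na.rm = TRUE),
           enriched = comp$code[comp$significant & comp$fracDiff > 0],
           depleted = comp$code[comp$significant & comp$fracDiff < 0])
    })
  }

  if (!is.null(config$stringEdges)) {
    report$stages$network <- stage("network", {
      g <- readStringEdges(config$stringEdges,
                           minScore = config$stringMinScore)
      if (igraph::vcount(g) == 0L) {
        list(nNodes = 0L, nEdges = 0L)
      } else {
        gs <- graphSummary(g)
        list(nNodes = gs@nNodes, nEdges = gs@nEdges,
             avgNodeDegree = gs@avgNodeDegree,
             avgLocalClustering = gs@avgLocalClustering)
      }
    })
  } else message("no edge list; network stage skipped")

  if (!is.null(config$structure) && !is.null(pathTrack)) {
    report$stages$paint <- stage("paint", {
      out <- file.path(config$outDir, "painted.pdb")
      writePaintedStructure(config$structure, pathTrack, out)
      list(output = out)
    })
  }

  inputs <- Filter(Negate(is.null),
                   config[c("sequence", "amTable", "disorderCsv", "fuzdrop",
                            "stringEdges", "structure")])
  manifest <- data.frame(input = names(inputs),
                         path = unlist(inputs),
                         md5 = unname(tools::md5sum(unlist(inputs))))
  utils::write.csv(manifest, file.path(config$outDir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
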