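test_that("generators are deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 71)
  expect_identical(as.character(genSequence(cfg)),
                   as.character(genSequence(cfg)))
  d1 <- genDisorderTracks(cfg); d2 <- genDisorderTracks(cfg)
  expect_identical(trackValues(d1$latent), trackValues(d2$latent))
  expect_identical(lapply(d1$tracks, trackValues),
                   lapply(d2$tracks, trackValues))
  expect_identical(trackValues(genPdp(cfg)$track),
                   trackValues(genPdp(cfg)$track))
  g1 <- genGraph(cfg); g2 <- genGraph(cfg)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  s <- genSequence(cfg)
  a1 <- genPathogenicity(cfg, d1$latent, s)
  a2 <- genPathogenicity(cfg, d1$latent, s)
  expect_identical(variantEntries(a1), variantEntries(a2))
})

test_that("sequence generator respects the configured composition", {
  compA <- setNames(rep(0, 20), topIdpOrder()); compA["A"] <- 1
  cfg <- simulationConfig(length = 20, composition = compA,
                          plantedDprs = list(), seed = 2)
  expect_equal(as.character(genSequence(cfg)), strrep("A", 20))
  # uniform composition: per-code frequency within 3 binomial sds pooled
  # across 100 seeds
  counts <- setNames(rep(0, 20), sort(topIdpOrder()))
  for (s in 1:100) {
    cfg <- simulationConfig(seed = s)
    res <- genSequence(cfg)@residues
    tb <- table(factor(res, levels = names(counts)))
    counts <- counts + as.numeric(tb)
  }
  n <- 100 * 543
  expect_true(all(abs(counts / n - 0.05) <= 3 * sqrt(0.05 * 0.95 / n)))
})

test_that("predictor tracks concentrate on the latent profile", {
  cfg0 <- simulationConfig(predictorNoiseSd = 0, seed = 5)
  d0 <- genDisorderTracks(cfg0)
  for (tr in d0$tracks)
    expect_equal(trackValues(tr), trackValues(d0$latent))

  # MDP approaches the latent as the number of predictors grows
  rmse <- sapply(c(1, 4, 16), function(k) {
    cfg <- simulationConfig(nPredictors = k, predictorNoiseSd = 0.1, seed = 7)
    d <- genDisorderTracks(cfg)
    m <- trackValues(computeMdp(d$tracks)$mdp)
    sqrt(mean((m - trackValues(d$latent))^2))
  })
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], rmse[1] / 2)
})

test_that("pathogenicity generator plants the decay exactly when noiseless", {
  cfg <- simulationConfig(variantNoiseSd = 0, seed = 11)
  sq <- genSequence(cfg)
  d <- genDisorderTracks(cfg)
  am <- genPathogenicity(cfg, d$latent, sq)
  e <- variantEntries(am)
  expect_equal(nrow(e), 19L * 543L)
  expect_equal(as.numeric(table(e$pos)), rep(19L, 543L))
  expect_true(all(e$ref != e$alt))
  # per-residue mean then fit recovers (a, b, c) to 1e-6
  pr <- perResidueMean(am, cfg$length)
  f <- fitExponentialDecay(d$latent, pr)
  expect_lt(abs(f@a - 0.6), 1e-6)
  expect_lt(abs(f@b - 4), 1e-6)
  expect_lt(abs(f@c - 0.2), 1e-6)

  # zero disorder everywhere gives the constant a + c
  cfgFlat <- simulationConfig(variantNoiseSd = 0, seed = 11)
  flat <- perResidueTrack(cfgFlat$proteinId, "latent", rep(0, 543))
  amFlat <- genPathogenicity(cfgFlat, flat, sq)
  expect_equal(unique(variantEntries(amFlat)$score), 0.8)
})

test_that("synthetic inputs round-trip through the readers", {
  cfg <- simulationConfig(length = 60, seed = 13,
                          plantedDprs = list(c(5L, 12L), c(40L, 50L)))
  dir <- tempfile("synth_")
  out <- writeSyntheticInputs(cfg, dir)
  expect_true(all(file.exists(out$paths)))

  sq <- readFasta(out$paths["sequence"])
  expect_equal(length(sq), 60L)
  expect_equal(as.character(sq), as.character(genSequence(cfg)))

  am <- readAlphaMissense(out$paths["amTable"], cfg$proteinId)
  amGen <- genPathogenicity(cfg, genDisorderTracks(cfg)$latent, sq)
  expect_equal(nrow(variantEntries(am)), nrow(variantEntries(amGen)))
  expect_equal(variantEntries(am)$score, variantEntries(amGen)$score,
               tolerance = 1e-12)

  tracks <- readDisorderCsv(out$paths["disorderCsv"], cfg$proteinId)
  expect_length(tracks, cfg$nPredictors)
  gen <- genDisorderTracks(cfg)$tracks
  for (k in seq_along(tracks))
    expect_equal(trackValues(tracks[[k]]), trackValues(gen[[k]]),
                 tolerance = 1e-12)

  fz <- readFuzdropProfile(out$paths["fuzdrop"], cfg$proteinId)
  expect_equal(fz$pLLPS, cfg$pLLPS, tolerance = 1e-6)
  expect_equal(regionTable(extractDprs(fz$track))$start, c(5, 40))

  g <- readStringEdges(out$paths["stringEdges"], 0.9)
  expect_equal(igraph::ecount(g), 268L)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulationConfig(plantedDprs = list(c(1L, 600L))),
               "<= length")
  expect_error(simulationConfig(plantedDprs = list(c(1L, 20L), c(15L, 30L))),
               "disjoint")
  expect_error(simulationConfig(graphSpec = c(nNodes = 5, nEdges = 11)),
               "infeasible")
  badComp <- setNames(rep(0.1, 20), topIdpOrder())
  expect_error(simulationConfig(composition = badComp), "sum to 1")
  expect_warning(simulationConfig(decayParams = c(a = 0.9, b = 1, c = 0.3)),
                 "clipped")
})

test_that("random graphs match the requested node and edge counts", {
  cfg <- simulationConfig(seed = 17)
  g <- genGraph(cfg)
  expect_equal(igraph::vcount(g), 56L)
  expect_equal(igraph::ecount(g), 268L)
  expect_true(all(igraph::E(g)$weight >= 900))
  expect_equal(graphSummary(g)@avgNodeDegree, 2 * 268 / 56)
  tri <- genGraph(simulationConfig(graphSpec = c(nNodes = 3, nEdges = 3),
                                   seed = 1))
  expect_equal(averageLocalClustering(tri), 1)
})
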