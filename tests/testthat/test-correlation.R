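test_that("moving mean follows the stated window convention", {
  const <- perResidueTrack("p", "x", rep(0.3, 50))
  expect_equal(trackValues(movingMean(const, 10)), rep(0.3, 50))

  # w = 2 covers offsets {0, +1}, truncated at the end
  tr <- perResidueTrack("p", "x", c(1, 2, 3, 4) / 4)
  expect_equal(trackValues(movingMean(tr, 2)),
               c(1.5, 2.5, 3.5, 4) / 4)

  # brute-force windowed averaging oracle, including missing values
  set.seed(29)
  v <- runif(120); v[sample(120, 8)] <- NA
  tr2 <- perResidueTrack("p", "x", v)
  for (w in c(1, 3, 10, 11)) {
    expect_equal(trackValues(movingMean(tr2, w)), bruteMovingMean(v, w))
  }
  # w = 1 is the identity
  expect_equal(trackValues(movingMean(tr2, 1)), v)
  expect_error(movingMean(tr2, 121), "exceeds")
  expect_error(movingMean(tr2, 0), ">= 1")

  # global mean preserved within O(w/L) at study-protein scale
  set.seed(30)
  v543 <- runif(543)
  sm <- trackValues(movingMean(perResidueTrack("p", "x", v543), 10))
  expect_lt(abs(mean(sm) - mean(v543)), 10 / 543)
})

test_that("rSquared matches the printed formula on hand-checked cases", {
  y <- c(1, 2, 3)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_equal(rSquared(y, c(1, 2, 2)), 0.5)
  # <= 1 always; 1 iff residuals all zero
  set.seed(41)
  for (i in 1:20) {
    yo <- rnorm(10); yh <- rnorm(10)
    expect_lte(rSquared(yo, yh), 1)
  }
  expect_error(rSquared(c(1, 1, 1), c(1, 1, 1)), "zero total variance")
  expect_error(rSquared(1:3, 1:4), "length")
})

test_that("noiseless exponential decay is recovered to machine precision", {
  x <- seq(0, 1, length.out = 100)
  y <- 0.8 * exp(-3 * x) + 0.1
  f <- fitExponentialDecay(x, y)
  expect_equal(f@a, 0.8, tolerance = 1e-6)
  expect_equal(f@b, 3.0, tolerance = 1e-6)
  expect_equal(f@c, 0.1, tolerance = 1e-6)
  expect_equal(f@rSquared, 1, tolerance = 1e-9)
  expect_true(f@converged)

  # 100 random (a, b, c) draws
  set.seed(43)
  for (i in 1:100) {
    a <- runif(1, 0.1, 1); b <- runif(1, 0.5, 10); c <- runif(1, 0, 0.3)
    f <- fitExponentialDecay(x, a * exp(-b * x) + c)
    expect_lt(max(abs(c(f@a - a, f@b - b, f@c - c))), 1e-6)
    expect_equal(f@rSquared, 1, tolerance = 1e-9)
  }
})

test_that("degenerate and deterministic fit behaviour", {
  x <- seq(0, 1, length.out = 20)
  expect_warning(f <- fitExponentialDecay(x, rep(0.5, 20)), "constant")
  expect_equal(f@c, 0.5)
  expect_equal(f@a, 0)
  expect_equal(f@b, 0)
  expect_equal(f@rSquared, 0)

  set.seed(47)
  y <- 0.6 * exp(-4 * x) + 0.2 + rnorm(20, 0, 0.05)
  f1 <- fitExponentialDecay(x, y)
  f2 <- fitExponentialDecay(x, y)
  expect_identical(f1, f2)  # bit-identical on identical inputs

  # two-parameter form pins c at 0
  y2 <- 0.7 * exp(-2 * x)
  f3 <- fitExponentialDecay(x, y2, offsetTerm = FALSE)
  expect_equal(f3@c, 0)
  expect_equal(f3@a, 0.7, tolerance = 1e-6)
  expect_equal(f3@b, 2, tolerance = 1e-6)
  expect_error(fitExponentialDecay(c(0.1, 0.2), c(1, 2)), "at least 3")
})

test_that("noisy fits approach the analytic noise-limited R^2", {
  set.seed(53)
  sigma <- 0.05
  r2s <- numeric(40)
  for (i in 1:40) {
    x <- runif(543)
    signal <- 0.6 * exp(-4 * x) + 0.2
    y <- signal + rnorm(543, 0, sigma)
    f <- fitExponentialDecay(x, y)
    r2s[i] <- f@rSquared
    expect_true(f@converged)
  }
  x <- runif(100000)
  varSig <- var(0.6 * exp(-4 * x) + 0.2)
  expect_equal(mean(r2s), varSig / (varSig + sigma^2), tolerance = 0.05)
})

test_that("correlateDisorderPathogenicity smooths y, keeps x raw, and pairs by position", {
  cfg <- simulationConfig(seed = 3)
  sq <- genSequence(cfg)
  dis <- genDisorderTracks(cfg)
  am <- genPathogenicity(cfg, dis$latent, sq)
  mdp <- computeMdp(dis$tracks)$mdp
  pr <- perResidueMean(am, cfg$length)
  res <- correlateDisorderPathogenicity(mdp, pr)
  expect_s4_class(res$fit, "FitResult")
  expect_equal(nrow(res$table), 543L)
  expect_equal(res$table$mdp, trackValues(mdp))  # x unsmoothed
  expect_equal(res$table$path_smoothed,
               trackValues(movingMean(pr, 10)))
  expect_equal(res$table$class, classifyScore(res$table$path_mean))
  # planted decay rate recovered within 20%
  expect_lt(abs(res$fit@b - 4) / 4, 0.2)

  # with window 1, jointly shuffling residue order leaves the fit unchanged
  set.seed(59)
  perm <- sample(543)
  mdpP <- perResidueTrack(proteinId(mdp), "MDP", trackValues(mdp)[perm])
  prP <- perResidueTrack(proteinId(pr), "mean_pathogenicity",
                         trackValues(pr)[perm])
  f1 <- correlateDisorderPathogenicity(mdp, pr, window = 1)$fit
  f2 <- correlateDisorderPathogenicity(mdpP, prP, window = 1)$fit
  expect_equal(c(f1@a, f1@b, f1@c), c(f2@a, f2@b, f2@c), tolerance = 1e-8)

  # constant y exercises the degenerate path
  prConst <- perResidueTrack(proteinId(pr), "mean_pathogenicity",
                             rep(0.5, 543))
  expect_warning(resC <- correlateDisorderPathogenicity(mdp, prConst),
                 "constant")
  expect_equal(resC$fit@rSquared, 0)
})
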