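test_that("computeMdp averages tracks and reports the spread band", {
  t1 <- perResidueTrack("p", "a", c(0.2, 0.5))
  t2 <- perResidueTrack("p", "b", c(0.4, 0.5))
  out <- computeMdp(list(t1, t2))
  expect_equal(trackValues(out$mdp), c(0.3, 0.5))
  expect_equal(trackValues(out$sd), c(sd(c(0.2, 0.4)), 0))
  expect_equal(trackName(out$mdp), "MDP")

  # single track: MDP equals it, band all zeros
  one <- computeMdp(list(t1))
  expect_equal(trackValues(one$mdp), trackValues(t1))
  expect_equal(trackValues(one$sd), c(0, 0))

  # brute-force oracle on six random tracks, with missing values excluded
  set.seed(11)
  trs <- lapply(1:6, function(k) randomTrack(50, name = paste0("t", k),
                                             naFrac = 0.1))
  got <- trackValues(computeMdp(trs)$mdp)
  mat <- sapply(trs, trackValues)
  want <- numeric(50)
  for (i in 1:50) {
    s <- 0; n <- 0
    for (k in 1:6) if (!is.na(mat[i, k])) { s <- s + mat[i, k]; n <- n + 1 }
    want[i] <- s / n
  }
  expect_equal(got, want)
  # bounded by per-residue min/max of inputs
  expect_true(all(got >= apply(mat, 1, min, na.rm = TRUE) - 1e-12))
  expect_true(all(got <= apply(mat, 1, max, na.rm = TRUE) + 1e-12))

  expect_error(computeMdp(list(t1, perResidueTrack("p", "c", 0.1))),
               "length")
  allNa <- perResidueTrack("p", "d", c(NA, 0.5))
  expect_error(computeMdp(list(allNa, perResidueTrack("p", "e", c(NA, 0.2)))),
               "missing in all tracks")
})

test_that("ppdr counts residues at or above the threshold", {
  expect_equal(ppdr(perResidueTrack("p", "d", c(0.6, 0.4, 0.5, 0.2))), 50)
  expect_equal(ppdr(perResidueTrack("p", "d", rep(0, 10))), 0)
  set.seed(3)
  v <- runif(1000)
  expect_equal(ppdr(perResidueTrack("p", "d", v)),
               100 * sum(v >= 0.5) / 1000)
  # permutation invariance and monotonicity in the threshold
  tr <- perResidueTrack("p", "d", v)
  trPerm <- perResidueTrack("p", "d", sample(v))
  expect_equal(ppdr(tr), ppdr(trPerm))
  ths <- sort(runif(10))
  pp <- sapply(ths, function(t) ppdr(tr, t))
  expect_true(all(diff(pp) <= 0))
  expect_error(ppdr(perResidueTrack("p", "d", c(NA_real_, NA_real_))),
               "no non-missing")
})

test_that("disorder categories partition [0, 100] at the stated boundaries", {
  expect_equal(classifyDisorder(8.47), "highly_ordered")
  expect_equal(classifyDisorder(15.65), "moderately_disordered")
  expect_equal(classifyDisorder(30), "highly_disordered")
  expect_equal(classifyDisorder(10), "moderately_disordered")
  set.seed(5)
  x <- c(runif(5000, 0, 100), 0, 10, 30, 100,
         9.9999999, 10.0000001, 29.9999999, 30.0000001)
  cls <- classifyDisorder(x)
  expect_true(all(cls %in% c("highly_ordered", "moderately_disordered",
                             "highly_disordered")))
  expect_equal(cls[x < 10], rep("highly_ordered", sum(x < 10)))
  expect_equal(cls[x >= 10 & x < 30],
               rep("moderately_disordered", sum(x >= 10 & x < 30)))
  expect_equal(cls[x >= 30], rep("highly_disordered", sum(x >= 30)))
  expect_error(classifyDisorder(101), "\\[0, 100\\]")
})

test_that("extractRegions finds maximal threshold runs", {
  tr <- perResidueTrack("p", "d", c(0.7, 0.7, 0.3, 0.9))
  tab <- regionTable(extractRegions(tr, 0.5, kind = "IDPR"))
  expect_equal(tab$start, c(1, 4))
  expect_equal(tab$end, c(2, 4))
  expect_equal(tab$kind, rep("IDPR", 2))

  low <- perResidueTrack("p", "d", rep(0.1, 5))
  expect_equal(nrow(regionTable(extractRegions(low, 0.5))), 0L)

  # missing values break runs
  gap <- perResidueTrack("p", "d", c(0.9, NA, 0.9))
  expect_equal(regionTable(extractRegions(gap, 0.5))$start, c(1, 3))
})

test_that("extractRegions agrees with the brute-force run oracle", {
  set.seed(21)
  for (rep in 1:50) {
    v <- runif(200)
    v[sample(200, 10)] <- NA
    minLen <- sample(1:4, 1)
    got <- regionTable(extractRegions(perResidueTrack("p", "d", v),
                                      0.6, minLen, "r"))
    want <- bruteRegions(v, 0.6, minLen)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want[, 1])
      expect_equal(got$end, want[, 2])
    }
    # maximality: extending any region by one residue breaks the condition
    if (nrow(got)) {
      ok <- !is.na(v) & v >= 0.6
      leftOk <- vapply(got$start, function(s) s == 1 || !ok[s - 1], TRUE)
      rightOk <- vapply(got$end, function(e) e == 200 || !ok[e + 1], TRUE)
      expect_true(all(leftOk) && all(rightOk))
    }
  }
})

test_that("disorderSummary ties PPDR, categories and the MDP together", {
  set.seed(9)
  trs <- list(perResidueTrack("p", "vlxt", runif(100, 0, 0.4)),
              perResidueTrack("p", "vsl2", runif(100)))
  ds <- disorderSummary(trs)
  expect_equal(ds$perPredictor$predictor, c("vlxt", "vsl2"))
  expect_equal(ds$perPredictor$ppdr[1], 0)
  expect_equal(ds$perPredictor$category,
               unname(classifyDisorder(ds$perPredictor$ppdr)))
  expect_equal(ds$mdpCategory, unname(classifyDisorder(ds$mdpPpdr)))
})

test_that("BED export converts 1-based inclusive to 0-based half-open", {
  rs <- regionSet("Q16678", c(1, 295), c(14, 322), "DPR")
  bed <- regionsToBed(rs)
  expect_equal(bed$chromStart, c(0, 294))
  expect_equal(bed$chromEnd, c(14, 322))
  expect_equal(bed$chromEnd - bed$chromStart, c(14, 28))
})
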