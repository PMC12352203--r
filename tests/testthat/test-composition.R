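test_that("composition frequencies count the 20 codes and sum to one", {
  expect_equal(unname(compositionFrequencies(proteinSequence("p", "AAAA"))["A"]),
               1)
  f <- compositionFrequencies(proteinSequence("p", "ACDE"))
  expect_equal(unname(f[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(f), 1)

  set.seed(2)
  res <- sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y"), 543, replace = TRUE)
  f2 <- compositionFrequencies(proteinSequence("p", res))
  counts <- sapply(names(f2), function(cc) sum(res == cc))
  expect_equal(unname(f2), unname(counts / 543))
  expect_equal(sum(f2), 1, tolerance = 1e-9)
})

test_that("fractional difference follows (Cx - Corder)/Corder", {
  expect_equal(fractionalDifference(0.10, 0.05), 1)
  expect_equal(fractionalDifference(0.05, 0.05), 0)
  expect_equal(fractionalDifference(0.025, 0.05), -0.5)
  expect_warning(out <- fractionalDifference(0.1, 0), "undefined")
  expect_true(is.na(out))
  expect_error(fractionalDifference(-0.1, 0.5), "non-negative")
  # reconstruction identity: sum(bg * (1 + fd)) == sum(query) == 1
  bg <- loadBackground()
  q <- compositionFrequencies(proteinSequence("p", strrep("ACDEFGHIKL", 10)))
  fd <- fractionalDifference(unname(q), unname(bg))
  expect_equal(sum(bg * (1 + fd)), 1, tolerance = 1e-9)
})

test_that("composition significance flags an extreme monocomposition", {
  bg <- rep(0.05, 20)
  names(bg) <- topIdpOrder()
  res <- compositionSignificance(proteinSequence("p", strrep("A", 543)),
                                 bg, iterations = 500, seed = 4)
  rowA <- res[res$code == "A", ]
  expect_true(rowA$significant)
  expect_equal(rowA$fracDiff, (1 - 0.05) / 0.05)  # 19
  # all other codes depleted to -1
  expect_true(all(res$fracDiff[res$code != "A"] == -1))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("planted two-fold enrichment is detected across seeds", {
  bg <- loadBackground()
  p <- bg; p["A"] <- 2 * bg["A"]; p <- p / sum(p)
  hits <- 0
  for (s in 1:25) {
    set.seed(7000 + s)
    q <- proteinSequence("e", sample(names(p), 500, TRUE, prob = p))
    res <- compositionSignificance(q, bg, iterations = 400, seed = s)
    rowA <- res[res$code == "A", ]
    if (isTRUE(rowA$significant) && rowA$fracDiff > 0) hits <- hits + 1
  }
  expect_gte(hits, 24)  # >= 95% of seeds
})

test_that("identity input is null-behaved and results are seed-reproducible", {
  bg <- loadBackground()
  set.seed(31)
  q <- proteinSequence("n", sample(names(bg), 543, TRUE, prob = bg))
  r1 <- compositionSignificance(q, bg, iterations = 400, seed = 5)
  r2 <- compositionSignificance(q, bg, iterations = 400, seed = 5)
  expect_identical(r1, r2)
  # identical composition to the background: fracDiff is exact and tiny p rare
  qbg <- proteinSequence("i", rep(names(bg), round(bg * 1000)))
  ri <- compositionSignificance(qbg, compositionFrequencies(qbg),
                                iterations = 400, seed = 6)
  expect_equal(ri$fracDiff, rep(0, 20))
  expect_false(any(ri$significant, na.rm = TRUE))
})

test_that("bootstrap_ci method agrees with the t method on clear calls", {
  bg <- rep(0.05, 20); names(bg) <- topIdpOrder()
  q <- proteinSequence("p", strrep("A", 300))
  rt <- compositionSignificance(q, bg, iterations = 500, seed = 1)
  rb <- compositionSignificance(q, bg, iterations = 500, seed = 1,
                                method = "bootstrap_ci")
  expect_true(rt[rt$code == "A", "significant"])
  expect_true(rb[rb$code == "A", "significant"])
})

test_that("TOP-IDP ordering is fixed and complete", {
  ord <- topIdpOrder()
  expect_equal(ord[1], "C")
  expect_equal(ord[20], "P")
  df <- data.frame(code = sample(ord), x = 1:20)
  out <- orderByTopIdp(df)
  expect_equal(out$code, ord)
  expect_equal(attr(out, "panel")$orderPromoting,
               c("C", "W", "I", "Y", "F", "L", "H", "V", "N", "M"))
  expect_equal(attr(out, "panel")$disorderPromoting,
               c("R", "T", "D", "G", "A", "K", "Q", "S", "E", "P"))
  expect_error(orderByTopIdp(df[1:19, ]), "20")
})
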