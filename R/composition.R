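#' TOP-IDP ordering of the amino acids
#'
#' The 20 amino acids ranked from most order-promoting (C) to most
#' disorder-promoting (P). The first ten form the order-promoting panel, the
#' last ten the disorder-promoting panel.
#'
#' @return character vector of length 20.
#' @export
topIdpOrder <- function() {
  c("C", "W", "I", "Y", "F", "L", "H", "V", "N", "M",
    "R", "T", "D", "G", "A", "K", "Q", "S", "E", "P")
}

#' Amino-acid composition frequencies
#'
#' Relative frequency of each of the 20 standard amino acids in a sequence
#' (zeros included). Positions carrying the unknown marker `X` are excluded
#' from the denominator.
#'
#' @param seq a [ProteinSequence-class].
#' @return named numeric vector over the 20 codes (alphabetical), summing to 1.
#' @export
compositionFrequencies <- function(seq) {
  res <- seq@residues[seq@residues %in% .AA20]
  if (length(res) == 0L) stop("sequence has no standard residues")
  counts <- table(factor(res, levels = .AA20))
  as.numeric(counts) / length(res) -> f
  names(f) <- .AA20
  f
}

#' Fractional compositional difference
#'
#' `(cQuery - cBackground) / cBackground`: the relative enrichment (positive)
#' or depletion (negative) of an amino acid in the query relative to a
#' background set. When the background frequency is 0 the difference is
#' undefined and returned as `NA` with a warning.
#'
#' @param cQuery,cBackground non-negative frequencies; vectorized.
#' @return numeric vector of fractional differences.
#' @examples
#' fractionalDifference(0.10, 0.05)   #  1
#' fractionalDifference(0.025, 0.05)  # -0.5
#' @export
fractionalDifference <- function(cQuery, cBackground) {
  if (any(cQuery < 0) || any(cBackground < 0))
    stop("frequencies must be non-negative")
  out <- (cQuery - cBackground) / cBackground
  zero <- cBackground == 0
  if (any(zero)) {
    warning("background frequency 0 for ", sum(zero),
            " code(s); fractional difference undefined (NA)")
    out[zero] <- NA_real_
  }
  out
}

#' Composition enrichment/depletion with resampling-based significance
#'
#' Compares the amino-acid composition of a query sequence against a
#' background composition. Per iteration, the query composition is
#' bootstrapped (resampling `length(seq)` residues with replacement, realised
#' as a multinomial draw from the observed frequencies) and a background
#' pseudo-sample of `backgroundN` residues is drawn from the background
#' frequencies. The two resulting sampling distributions of each code's
#' frequency are compared either by a t-type statistic (default) or by a
#' bootstrap percentile interval on the frequency difference. The t-type
#' statistic is
#' `t = (mean_q - mean_bg) / sqrt(var_bg * (1 + backgroundN / n_q))`
#' with a two-sided normal p-value: the null variance of the frequency
#' difference is estimated from the background bootstrap alone, scaled for
#' both sample sizes (`var_bg` estimates `p(1-p)/backgroundN`, so the scaled
#' form estimates `p(1-p) * (1/backgroundN + 1/n_q)`). Estimating the null
#' variance from the background rather than the query avoids the
#' mean-variance coupling of binomial frequencies (a query frequency that
#' drifts low by chance would otherwise shrink its own denominator), which
#' keeps the family-wise error at or below `alpha` under the null; so does
#' the bootstrap-distribution variance itself, which -- unlike the classic
#' per-observation t formula -- does not shrink with the iteration count.
#' Bonferroni correction uses m = 20 (one test per code).
#'
#' @param seq a [ProteinSequence-class] (the query).
#' @param backgroundFreqs named frequency vector over the 20 codes, summing
#'   to 1.
#' @param backgroundN size of the background pseudo-sample per iteration.
#' @param iterations bootstrap iterations (default 10000, minimum 100).
#' @param alpha family-wise significance level (default 0.05); per-code
#'   threshold is `alpha / 20`.
#' @param seed integer seed; the procedure is reproducible given it.
#' @param method `"ttest"` (default) or `"bootstrap_ci"`.
#' @return data.frame in TOP-IDP order with columns `code`, `cQuery`,
#'   `cBackground`, `fracDiff`, `p`, `significant`, plus attribute `panel`
#'   splitting codes into order- and disorder-promoting halves.
#' @export
compositionSignificance <- function(seq, backgroundFreqs, backgroundN = 3000L,
                                    iterations = 10000L, alpha = 0.05,
                                    seed = 1L,
                                    method = c("ttest", "bootstrap_ci")) {
  method <- match.arg(method)
  stopifnot(iterations >= 100L, backgroundN >= 1L)
  backgroundFreqs <- backgroundFreqs[.AA20]
  if (any(is.na(backgroundFreqs)))
    stop("backgroundFreqs must be named over the 20 standard codes")
  if (abs(sum(backgroundFreqs) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  fq <- compositionFrequencies(seq)
  nq <- sum(seq@residues %in% .AA20)
  set.seed(seed)
  Q <- stats::rmultinom(iterations, nq, fq) / nq
  B <- stats::rmultinom(iterations, backgroundN, backgroundFreqs) / backgroundN
  mq <- rowMeans(Q); mb <- rowMeans(B)
  vb <- apply(B, 1L, stats::var)
  if (method == "ttest") {
    denom <- sqrt(vb * (1 + backgroundN / nq))
    p <- ifelse(denom == 0, 1, 2 * stats::pnorm(-abs(mq - mb) / denom))
    if (any(denom == 0))
      warning("zero-variance code(s); p reported as 1 for: ",
              paste(.AA20[denom == 0], collapse = ", "))
  } else {
    d <- Q - B
    lo <- rowMeans(d <= 0); hi <- rowMeans(d >= 0)
    p <- pmin(1, 2 * pmin(lo, hi))
    degen <- apply(d, 1L, function(r) all(r == 0))
    if (any(degen)) {
      warning("zero-variance code(s); p reported as 1 for: ",
              paste(.AA20[degen], collapse = ", "))
      p[degen] <- 1
    }
  }
  out <- data.frame(code = .AA20,
                    cQuery = unname(fq),
                    cBackground = unname(backgroundFreqs),
                    fracDiff = suppressWarnings(
                      fractionalDifference(unname(fq),
                                           unname(backgroundFreqs))),
                    p = unname(p),
                    significant = unname(p < alpha / 20),
                    stringsAsFactors = FALSE)
  orderByTopIdp(out)
}

#' Order a composition result by the TOP-IDP scale
#'
#' Reorders a 20-row composition result from most order-promoting (C) to most
#' disorder-promoting (P) and attaches the panel split (first ten
#' order-promoting, last ten disorder-promoting).
#'
#' @param result data.frame with a `code` column covering all 20 codes.
#' @return the reordered data.frame with attribute `panel`.
#' @export
orderByTopIdp <- function(result) {
  ord <- topIdpOrder()
  if (!setequal(result$code, ord) || nrow(result) != 20L)
    stop("composition result must contain exactly the 20 standard codes")
  out <- result[match(ord, result$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel") <- list(orderPromoting = ord[1:10],
                             disorderPromoting = ord[11:20])
  out
}

#' Load a background composition shipped with the package
#'
#' The package ships a single stand-in background,
#' `"synthetic_globular"` (file `background_synthetic_globular.csv`): a
#' synthetic composition typical of well-folded globular proteins, constructed
#' in-package and labelled synthetic because the curated background sets used
#' by composition-profiling web services are not redistributable. Any
#' user-supplied CSV with columns `code`, `freq` can be loaded by path.
#'
#' @param name background name or path to a CSV with columns `code`, `freq`.
#' @return named frequency vector over the 20 codes, summing to 1.
#' @export
loadBackground <- function(name = "synthetic_globular") {
  path <- if (file.exists(name)) name
          else system.file("extdata",
                           paste0("background_", name, ".csv"),
                           package = "DisorderMap")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown background: ", name)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  f <- df$freq
  names(f) <- df$code
  f <- f[.AA20]
  if (any(is.na(f))) stop("background file must cover all 20 codes")
  f / sum(f)
}
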