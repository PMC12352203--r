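#' Centered moving mean of a per-residue track
#'
#' Moving mean with window `w`, covering offsets `-ceiling(w/2)+1` to
#' `floor(w/2)` around each residue (for the conventional `w = 10`:
#' offsets -4 to +5). The window truncates at the sequence ends, averaging
#' whatever residues are available; missing values are excluded from each
#' window mean (a window with no non-missing residue stays missing).
#'
#' @param track a [PerResidueTrack-class].
#' @param window window width in residues (default 10); must not exceed the
#'   track length.
#' @return a smoothed [PerResidueTrack-class] (same name with `_movmean`
#'   suffix).
#' @export
movingMean <- function(track, window = 10L) {
  v <- trackValues(track)
  if (window < 1L) stop("window must be >= 1")
  if (window > length(v))
    stop("window (", window, ") exceeds track length (", length(v), ")")
  out <- .runMean(v, window)
  perResidueTrack(proteinId(track), paste0(trackName(track), "_movmean"), out)
}

# moving mean on a bare numeric vector; offsets -ceiling(w/2)+1 .. floor(w/2)
.runMean <- function(v, window) {
  n <- length(v)
  lo <- -ceiling(window / 2) + 1L
  hi <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    w <- v[max(1L, i + lo):min(n, i + hi)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else mean(w)
  }, numeric(1))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with no
#' degrees-of-freedom correction. Equals 1 exactly when all residuals are
#' zero; can be negative for fits worse than the mean.
#'
#' @param yObs observed values.
#' @param yHat fitted values, same length.
#' @return numeric scalar, at most 1.
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 2))  # 0.5
#' @export
rSquared <- function(yObs, yHat) {
  if (length(yObs) != length(yHat))
    stop("observed and fitted values differ in length")
  if (length(yObs) < 2L) stop("need at least 2 values")
  ssTot <- sum((yObs - mean(yObs))^2)
  if (ssTot == 0) stop("zero total variance in observed values")
  1 - sum((yObs - yHat)^2) / ssTot
}

#' Fit an exponential decay between two per-residue tracks
#'
#' Least-squares fit of `y = a * exp(-b * x) + c` with the decay rate
#' constrained non-negative, using Levenberg-Marquardt with a deterministic
#' initialisation (`a0 = max(y) - min(y)`, `b0 = 1`, `c0 = min(y)`), so
#' identical inputs give identical fits. Pairs with a missing value on either
#' side are dropped. A constant `y` is a degenerate case: the fit collapses
#' to the offset (`a = 0`, `b = 0`, `c = mean(y)`, `R^2 = 0`) with a warning.
#' If the optimiser stops without meeting its tolerance the best iterate is
#' returned with `converged = FALSE`.
#'
#' @param x,y [PerResidueTrack-class] objects (or bare numeric vectors) of
#'   equal length; `x` in `[0, 1]`; at least 3 complete pairs.
#' @param offsetTerm fit the 3-parameter form with offset `c` (default); when
#'   `FALSE`, `c` is fixed at 0.
#' @return a [FitResult-class].
#' @export
fitExponentialDecay <- function(x, y, offsetTerm = TRUE) {
  xv <- if (is(x, "PerResidueTrack")) trackValues(x) else as.numeric(x)
  yv <- if (is(y, "PerResidueTrack")) trackValues(y) else as.numeric(y)
  if (length(xv) != length(yv)) stop("x and y differ in length")
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("need at least 3 complete (x, y) pairs")
  if (max(yv) - min(yv) < .Machine$double.eps^0.5) {
    warning("constant y: degenerate fit (a = 0, b = 0, c = mean(y), R^2 = 0)")
    return(fitResult(0, 0, mean(yv), 0, length(yv), TRUE))
  }
  a0 <- max(yv) - min(yv); b0 <- 1; c0 <- min(yv)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                     ptol = 1e-12, maxfev = 100000)
  fit <- tryCatch({
    if (offsetTerm)
      minpack.lm::nlsLM(yv ~ a * exp(-b * xv) + c,
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(-Inf, 0, -Inf), control = ctrl)
    else
      minpack.lm::nlsLM(yv ~ a * exp(-b * xv),
                        start = list(a = a0, b = b0),
                        lower = c(-Inf, 0), control = ctrl)
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to direct SS minimisation; report non-convergence honestly
    obj <- function(p) {
      cc <- if (offsetTerm) p[3] else 0
      sum((yv - (p[1] * exp(-max(p[2], 0) * xv) + cc))^2)
    }
    p0 <- if (offsetTerm) c(a0, b0, c0) else c(a0, b0)
    op <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    pa <- op$par
    cc <- if (offsetTerm) pa[3] else 0
    yhat <- pa[1] * exp(-max(pa[2], 0) * xv) + cc
    warning("Levenberg-Marquardt failed (", conditionMessage(fit),
            "); returning direct-search iterate")
    return(fitResult(pa[1], max(pa[2], 0), cc, rSquared(yv, yhat),
                     length(yv), FALSE))
  }
  cf <- stats::coef(fit)
  cc <- if (offsetTerm) unname(cf["c"]) else 0
  yhat <- unname(cf["a"]) * exp(-unname(cf["b"]) * xv) + cc
  fitResult(unname(cf["a"]), unname(cf["b"]), cc, rSquared(yv, yhat),
            length(xv), isTRUE(fit$convInfo$isConv))
}

#' Correlate consensus disorder with smoothed pathogenicity
#'
#' The headline analysis: the per-residue mean pathogenicity is smoothed with
#' a centered moving mean (window 10 by default) and regressed on the raw
#' (unsmoothed) consensus mean disorder profile via the exponential-decay
#' model. The paired table carries, per residue, the disorder value, the raw
#' and smoothed pathogenicity means, and the three-class call of the raw
#' residue mean (for plot colouring).
#'
#' @param mdp consensus disorder [PerResidueTrack-class] (x-axis).
#' @param pathMean per-residue mean pathogenicity [PerResidueTrack-class]
#'   (y-axis, smoothed before fitting).
#' @param window smoothing window (default 10).
#' @param smoothX also smooth the disorder track (sensitivity analysis;
#'   default `FALSE`).
#' @param offsetTerm passed to [fitExponentialDecay()].
#' @return list with `fit` (a [FitResult-class]) and `table` (data.frame:
#'   `res_index`, `mdp`, `path_mean`, `path_smoothed`, `class`).
#' @export
correlateDisorderPathogenicity <- function(mdp, pathMean, window = 10L,
                                           smoothX = FALSE,
                                           offsetTerm = TRUE) {
  if (!identical(proteinId(mdp), proteinId(pathMean)))
    stop("tracks are on different proteins")
  if (length(mdp) != length(pathMean))
    stop("tracks differ in length")
  ySm <- movingMean(pathMean, window)
  xTr <- if (smoothX) movingMean(mdp, window) else mdp
  fit <- fitExponentialDecay(xTr, ySm, offsetTerm = offsetTerm)
  tab <- data.frame(res_index = seq_len(length(mdp)),
                    mdp = trackValues(xTr),
                    path_mean = trackValues(pathMean),
                    path_smoothed = trackValues(ySm),
                    class = classifyScore(trackValues(pathMean)),
                    stringsAsFactors = FALSE)
  list(fit = fit, table = tab)
}
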