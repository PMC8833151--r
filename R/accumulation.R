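# Sample-based species accumulation: exact hypergeometric interpolation
# (rarefaction) over sampling units, Chao2-anchored extrapolation, and
# bootstrap uncertainty bands. The exact interpolation formula is the
# expectation of the usual randomised accumulation procedure, so the mean
# curve needs no resampling; the bootstrap only supplies spread.

#' Rarefaction: expected richness at t sampling units
#'
#' Hypergeometric expectation over unit subsets,
#' `S_t = sum_k (1 - choose(T - Y_k, t) / choose(T, t))`,
#' computed with log-space binomial coefficients. Exact: equals the average
#' observed richness over all t-unit subsets of the T units.
#'
#' @param incidence a [GridIncidence-class].
#' @param t integer vector of unit counts, 0 <= t <= T (use
#'   [extrapolateRichness()] beyond T).
#' @return numeric vector of expected richness values.
#' @examples
#' gi <- gridIncidence(matrix(c(1,1,0, 0,1,1), 2, byrow = TRUE))
#' rarefy(gi, 0:2)
#' @export
rarefy <- function(incidence, t) {
  stopifnot(is(incidence, "GridIncidence"))
  T <- nUnits(incidence)
  if (any(t < 0 | t > T | t != round(t)))
    abdStop("t must be integers in [0, T]; use extrapolateRichness beyond T",
            "arbodiv_range_error")
  Y <- incidenceFreq(incidence)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    sum(1 - exp(lchoose(T - Y, ti) - lchoose(T, ti)))
  }, numeric(1))
}

#' Extrapolation: expected richness at T + tExtra sampling units
#'
#' Chao2-anchored extrapolation
#' `S(T + t*) = S_obs + Q0 * (1 - (1 - Q1 / (Q1 + T * Q0))^t*)` with
#' `Q0 = Chao2 - S_obs`; monotone in t* with asymptote at the Chao2 point.
#' With no uniques (Q0 = 0) the curve continues flat at S_obs.
#'
#' @param incidence a [GridIncidence-class] (supplies S_obs and T).
#' @param estimate a [Chao2Estimate-class] for the same data (also accepts an
#'   [AdjustedChao2-class], giving the adjusted curve).
#' @param tExtra nonnegative numeric vector of additional units.
#' @return numeric vector of expected richness values.
#' @export
extrapolateRichness <- function(incidence, estimate, tExtra) {
  stopifnot(is(incidence, "GridIncidence"), is(estimate, "Chao2Estimate"))
  if (any(tExtra < 0)) abdStop("tExtra must be >= 0", "arbodiv_range_error")
  S <- sObs(incidence)
  T <- nUnits(incidence)
  Q0 <- estimate@point - S
  Q1 <- estimate@q1
  if (Q0 <= 0 || Q1 <= 0) return(rep(as.numeric(S), length(tExtra)))
  S + Q0 * (1 - (1 - Q1 / (Q1 + T * Q0))^tExtra)
}

#' Accumulation curve with bootstrap uncertainty bands
#'
#' Evaluates the interpolated (t <= T) and extrapolated (t > T) expected
#' richness on a log-spaced grid of unit counts, with percentile bands from
#' a seeded bootstrap over sampling units: T units are resampled with
#' replacement, the whole curve (tallies, Chao2 anchor and all) is
#' recomputed per replicate, and pointwise envelopes are taken.
#'
#' @param incidence a [GridIncidence-class].
#' @param tMax largest unit count evaluated (default 2T).
#' @param knots number of grid points (log-spaced; T itself is always
#'   included so the curve passes through S_obs).
#' @param nBoot bootstrap replicates (default 200).
#' @param seed seed for the bootstrap stream.
#' @param level band level.
#' @param adjusted use the adjusted Chao2 (true-unique correction) as the
#'   extrapolation anchor.
#' @param center bias-correct the bands (default): resampling units with
#'   replacement collapses distinct units, so raw replicate curves sit
#'   systematically below the exact curve; centering shifts the percentile
#'   envelope onto the exact curve, keeping only the bootstrap spread.
#'   `center = FALSE` gives the raw replicate envelope.
#' @return an [AccumulationCurve-class] object.
#' @export
accumulationCurve <- function(incidence, tMax = NULL, knots = 40L,
                              nBoot = 200L, seed = 1L, level = 0.95,
                              adjusted = FALSE, center = TRUE) {
  stopifnot(is(incidence, "GridIncidence"), nBoot >= 1)
  T <- nUnits(incidence)
  if (is.null(tMax)) tMax <- 2L * T
  stopifnot(tMax >= 1)
  tGrid <- sort(unique(c(
    pmin(round(exp(seq(0, log(tMax), length.out = knots))), tMax), T)))

  curveOf <- function(gi) {
    fc <- tallyFrequencies(gi)
    est <- if (adjusted) adjustedChao2(fc, estimateTrueUniques(fc), level)
           else chao2(fc, level)
    Tb <- nUnits(gi)
    inner <- tGrid[tGrid <= Tb]
    outer <- tGrid[tGrid > Tb]
    c(rarefy(gi, inner),
      if (length(outer)) extrapolateRichness(gi, est, outer - Tb))
  }

  meanCurve <- curveOf(incidence)
  boot <- withSeed(childSeed(seed, "accum_boot", incidence@region), {
    vapply(seq_len(nBoot), function(b) {
      curveOf(resampleUnits(incidence, sample.int(T, T, replace = TRUE)))
    }, numeric(length(tGrid)))
  })
  boot <- matrix(boot, nrow = length(tGrid))
  if (center) boot <- boot - rowMeans(boot) + meanCurve
  lo <- apply(boot, 1, stats::quantile, probs = (1 - level) / 2, names = FALSE)
  hi <- apply(boot, 1, stats::quantile, probs = 1 - (1 - level) / 2, names = FALSE)

  pts <- data.frame(
    t = tGrid,
    segment = ifelse(tGrid <= T, "interpolated", "extrapolated"),
    sT = meanCurve, lower = lo, upper = hi,
    stringsAsFactors = FALSE)
  new("AccumulationCurve", region = incidence@region, points = pts,
      nBoot = as.integer(nBoot), level = level, seed = as.integer(seed))
}

setMethod("show", "AccumulationCurve", function(object) {
  p <- object@points
  cat(sprintf("AccumulationCurve '%s': %d knots (t = %d..%d), %d interpolated\n",
              object@region, nrow(p), min(p$t), max(p$t),
              sum(p$segment == "interpolated")))
  cat(sprintf("  right end: S(%d) = %.1f [%.1f, %.1f]\n",
              max(p$t), p$sT[nrow(p)], p$lower[nrow(p)], p$upper[nrow(p)]))
})

#' Plot an accumulation curve
#'
#' Base-graphics rendering: mean curve with the interpolated segment solid,
#' the extrapolated segment dashed, and the bootstrap band shaded.
#'
#' @param x an [AccumulationCurve-class].
#' @param y unused.
#' @param ... passed to [plot()].
#' @export
setMethod("plot", signature(x = "AccumulationCurve", y = "missing"),
  function(x, y, ...) {
    p <- x@points
    graphics::plot(p$t, p$sT, type = "n", xlab = "sampling units",
                   ylab = "species", main = x@region,
                   ylim = range(c(p$lower, p$upper)), ...)
    graphics::polygon(c(p$t, rev(p$t)), c(p$lower, rev(p$upper)),
                      col = grDevices::grey(0.85), border = NA)
    ip <- p$segment == "interpolated"
    graphics::lines(p$t[ip], p$sT[ip], lwd = 2)
    graphics::lines(p$t[!ip | c(ip[-1], FALSE)], p$sT[!ip | c(ip[-1], FALSE)],
                    lty = 2)
    invisible(x)
  })
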