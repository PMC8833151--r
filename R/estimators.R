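# Nonparametric richness machinery: Good-Turing (Chao-Shen) sample coverage,
# the bias-corrected Chao2 estimator with its log-normal confidence interval,
# the estimated true number of uniques (false-singleton correction), and the
# adjusted Chao2 obtained by substituting that estimate for the observed
# unique count.

#' @describeIn sampleCoverage Chao-Shen bias-reduced sample completeness
#'
#'   `C_n = 1 - (f1/n) * (n-1) f1 / ((n-1) f1 + 2 f2)`, with (f1, f2, n)
#'   read as (singletons, doubletons, individuals) in abundance mode or
#'   (uniques, duplicates, total occurrences) in incidence mode. With no
#'   singletons the sample is judged complete (C_n = 1).
#' @export
setMethod("sampleCoverage", "FrequencyCounts", function(x, ...) {
  n <- x@total
  if (is.na(n) || n < 1)
    abdStop("coverage undefined: total count n is missing or zero",
            "arbodiv_undefined_coverage")
  f1 <- x@q[1]; f2 <- x@q[2]
  C <- if (f1 == 0) {
    1
  } else {
    den <- (n - 1) * f1 + 2 * f2
    if (den == 0) 1 - f1 / n else 1 - (f1 / n) * ((n - 1) * f1 / den)
  }
  C <- min(max(C, 0), 1)
  new("CoverageResult", coverage = C, deficit = 1 - C, mode = x@mode)
})

setMethod("show", "CoverageResult", function(object) {
  cat(sprintf("Sample coverage (%s mode): %.4f (deficit %.4f)\n",
              object@mode, object@coverage, object@deficit))
})

# Shared Chao2 core: point, variance and log-normal CI from (sObs, T, q1,
# q2). q1 may be non-integer (the adjusted unique count); a q1 below 1
# contributes no correction. Variance is the standard bias-corrected Chao2
# variance (Chao 1987, the EstimateS/iNEXT companion to the printed point
# formula), with A = (T-1)/T:
#   var = A q1(q1-1)/(2(q2+1)) + A^2 q1(2q1-1)^2/(4(q2+1)^2)
#       + A^2 q1^2 q2 (q1-1)^2 / (4 (q2+1)^4)
# The CI is S_obs + E/K .. S_obs + E*K with E = point - S_obs and
# K = exp(z * sqrt(log(1 + var/E^2))); z is the printed 1.96 at the default
# 95% level.
#' @noRd
chao2Core <- function(sObs, T, q1, q2, level = 0.95) {
  A <- if (T > 0) (T - 1) / T else 0
  corr <- if (q1 >= 1) A * q1 * (q1 - 1) / (2 * (q2 + 1)) else 0
  point <- sObs + corr
  v <- if (q1 >= 1) {
    A * q1 * (q1 - 1) / (2 * (q2 + 1)) +
      A^2 * q1 * (2 * q1 - 1)^2 / (4 * (q2 + 1)^2) +
      A^2 * q1^2 * q2 * (q1 - 1)^2 / (4 * (q2 + 1)^4)
  } else 0
  v <- max(v, 0)
  E <- point - sObs
  z <- if (abs(level - 0.95) < 1e-12) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  if (E > 0 && v > 0) {
    K <- exp(z * sqrt(log1p(v / E^2)))
    lower <- sObs + E / K
    upper <- sObs + E * K
  } else {
    K <- 1
    lower <- upper <- point
  }
  list(point = point, variance = v, excess = E, K = K,
       lower = lower, upper = upper)
}

#' @describeIn chao2 from incidence-mode frequency counts:
#'   `Chao2 = S_obs + ((T-1)/T) * Q1 (Q1 - 1) / (2 (Q2 + 1))` with the
#'   log-normal CI `S_obs + E/K .. S_obs + E*K`,
#'   `K = exp(z sqrt(log(1 + var/E^2)))`, `E = Chao2 - S_obs`. With no
#'   uniques the estimate and CI collapse to S_obs.
#' @param level confidence level (default 0.95, giving the printed z = 1.96).
#' @export
setMethod("chao2", "FrequencyCounts", function(x, level = 0.95, ...) {
  if (x@mode != "incidence")
    abdStop("chao2 requires incidence-mode counts", "arbodiv_mode_error")
  cc <- chao2Core(x@sObs, x@units, x@q[1], x@q[2], level)
  new("Chao2Estimate", sObs = x@sObs, nUnits = x@units,
      q1 = x@q[1], q2 = x@q[2],
      point = cc$point, variance = cc$variance, excess = cc$excess,
      K = cc$K, ciLower = cc$lower, ciUpper = cc$upper, level = level)
})

#' @describeIn chao2 convenience: tally a GridIncidence, then estimate.
#' @export
setMethod("chao2", "GridIncidence", function(x, level = 0.95, ...) {
  chao2(tallyFrequencies(x), level = level)
})

setMethod("show", "Chao2Estimate", function(object) {
  cat(sprintf("%s: %.2f (%.0f%% CI %.2f - %.2f)\n",
              if (is(object, "AdjustedChao2")) "Chao2_adj" else "Chao2",
              object@point, 100 * object@level, object@ciLower, object@ciUpper))
  cat(sprintf("  S_obs = %d, T = %g, Q1 = %g, Q2 = %g, var = %.4g\n",
              object@sObs, object@nUnits, object@q1, object@q2,
              object@variance))
  if (is(object, "AdjustedChao2"))
    cat(sprintf("  Q1-hat = %.3f%s\n", object@q1Hat,
                if (object@fallbackUsed) " (fallback: observed Q1 used)" else ""))
})

#' Estimated true number of uniques (false-singleton correction)
#'
#' Estimates how many uniques a dataset would contain without
#' misidentification-driven false uniques, from the relationship of
#' duplicates, triplicates and quadruplicates. With A = (T-1)/T:
#'
#' `Q1-hat = A * 2 Q2^2 / (3 Q3) + A^2 * Q2 * (Q2 / (2 Q3) - Q3 / (4 Q4))`
#'
#' The typeset source of the formula is ambiguous about the exponent of the
#' first A factor; `parse = "squared"` squares it (negligible difference for
#' T >> 1). Abundance-mode counts substitute (n, f2, f3, f4). When Q3 = 0 or
#' Q4 = 0 the formula is undefined and the observed Q1 is returned with
#' `fallback = TRUE` (no adjustment, conservative). Negative values clamp to
#' 0 with a warning.
#'
#' @param counts a [FrequencyCounts-class].
#' @param parse "linear" (default) or "squared" exponent of the leading A.
#' @return list with elements `q1Hat` (>= 0) and `fallback` (logical).
#' @examples
#' fc <- frequencyCounts(sObs = 200, q1 = 50, q2 = 30, q3 = 20, q4 = 10,
#'                       units = 100)
#' estimateTrueUniques(fc)
#' @export
estimateTrueUniques <- function(counts, parse = c("linear", "squared")) {
  parse <- match.arg(parse)
  stopifnot(is(counts, "FrequencyCounts"))
  q <- counts@q
  units <- if (counts@mode == "incidence") counts@units else counts@total
  if (q[3] == 0 || q[4] == 0)
    return(list(q1Hat = q[1], fallback = TRUE))
  A <- (units - 1) / units
  A1 <- if (parse == "linear") A else A^2
  q1Hat <- A1 * 2 * q[2]^2 / (3 * q[3]) +
    A^2 * q[2] * (q[2] / (2 * q[3]) - q[3] / (4 * q[4]))
  if (q1Hat < 0) {
    warning("estimated true uniques negative; clamped to 0")
    q1Hat <- 0
  }
  list(q1Hat = q1Hat, fallback = FALSE)
}

#' Adjusted Chao2: Chao2 with the estimated true unique count
#'
#' Substitutes Q1-hat for the observed Q1 in the Chao2 point formula and its
#' confidence interval. Q1-hat below 1 contributes no correction; Q1-hat is
#' deliberately not capped at the observed Q1 (the adjustment can raise an
#' estimate). With `q1Hat` equal to the observed Q1 the result reproduces
#' [chao2()] exactly.
#'
#' @param counts incidence-mode [FrequencyCounts-class].
#' @param q1Hat estimated true number of uniques (>= 0), e.g. from
#'   [estimateTrueUniques()]; a list as returned by that function is also
#'   accepted.
#' @param level confidence level.
#' @return an [AdjustedChao2-class] object.
#' @examples
#' fc <- frequencyCounts(sObs = 200, q1 = 50, q2 = 30, q3 = 20, q4 = 10,
#'                       units = 100)
#' adjustedChao2(fc, estimateTrueUniques(fc))
#' @export
adjustedChao2 <- function(counts, q1Hat, level = 0.95) {
  stopifnot(is(counts, "FrequencyCounts"))
  if (counts@mode != "incidence")
    abdStop("adjustedChao2 requires incidence-mode counts", "arbodiv_mode_error")
  fallback <- FALSE
  if (is.list(q1Hat)) {
    fallback <- isTRUE(q1Hat$fallback)
    q1Hat <- q1Hat$q1Hat
  }
  if (is.na(q1Hat) || q1Hat < 0)
    abdStop("q1Hat must be >= 0", "arbodiv_data_error")
  cc <- chao2Core(counts@sObs, counts@units, q1Hat, counts@q[2], level)
  new("AdjustedChao2", sObs = counts@sObs, nUnits = counts@units,
      q1 = q1Hat, q2 = counts@q[2],
      point = cc$point, variance = cc$variance, excess = cc$excess,
      K = cc$K, ciLower = cc$lower, ciUpper = cc$upper, level = level,
      q1Hat = q1Hat, fallbackUsed = fallback)
}
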