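# Fisher's log-series: alpha fitting, the classical richness equation, and a
# Kolmogorov-Smirnov goodness-of-fit check of the log-series assumption.

#' Fit Fisher's alpha to a species-abundance vector
#'
#' Solves Fisher's identity `S_obs = alpha * log(1 + n / alpha)` for alpha by
#' a bracketed root search (relative tolerance 1e-9), where n is the total
#' number of individuals. Optionally attaches a bootstrap confidence
#' interval (resampling individuals with replacement and refitting) and the
#' log-series goodness-of-fit test.
#'
#' @param abundances positive integer vector of per-species abundances.
#' @param nBoot bootstrap replicates for the alpha CI (0 = skip; the
#'   reported intervals in comparable analyses use 1000).
#' @param seed seed for the bootstrap stream.
#' @param level CI level.
#' @param gof run [logseriesGof()] (skipped silently when the data have
#'   fewer than 3 distinct abundance values).
#' @return a [FisherFit-class] object.
#' @examples
#' fit <- fisherAlphaFit(c(10, 4, 2, 1, 1, 1))
#' fit@alpha
#' @export
fisherAlphaFit <- function(abundances, nBoot = 0L, seed = 1L, level = 0.95,
                           gof = TRUE) {
  if (length(abundances) < 1 || any(abundances < 1 | abundances != round(abundances)))
    abdStop("abundances must be positive integers", "arbodiv_data_error")
  n <- sum(abundances)
  S <- length(abundances)
  alpha <- solveFisherAlpha(S, n)
  ksD <- ksP <- NA_real_
  if (gof && length(unique(abundances)) >= 3) {
    ks <- logseriesGof(abundances, alpha)
    ksD <- ks$D; ksP <- ks$p
  }
  ciL <- ciU <- NA_real_
  if (nBoot > 0) {
    individuals <- rep.int(seq_len(S), abundances)
    boots <- withSeed(childSeed(seed, "fisher_boot"), {
      vapply(seq_len(nBoot), function(b) {
        ab <- tabulate(sample(individuals, n, replace = TRUE), nbins = S)
        ab <- ab[ab > 0]
        if (length(ab) == sum(ab)) NA_real_ else solveFisherAlpha(length(ab), sum(ab))
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    ciL <- qs[1]; ciU <- qs[2]
  }
  new("FisherFit", alpha = alpha, n = as.numeric(n), sObs = as.integer(S),
      ksD = ksD, ksP = ksP, ciLower = ciL, ciUpper = ciU,
      nBoot = as.integer(nBoot))
}

# bracketed solve of S = alpha log(1 + n/alpha); alpha unbounded when every
# species is a singleton (S = n)
#' @noRd
solveFisherAlpha <- function(S, n) {
  if (S >= n)
    abdStop("all species are singletons (S = n): Fisher's alpha is unbounded",
            "arbodiv_alpha_unbounded")
  f <- function(a) a * log1p(n / a) - S
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(f, c(1e-9, hi), tol = 1e-10)$root
  # Newton polish to the stated relative tolerance
  for (i in 1:4) {
    fp <- log1p(n / root) - n / (root + n)
    root <- root - f(root) / fp
  }
  root
}

#' Fisher's classical richness equation
#'
#' `S = alpha * log(1 + N / alpha)`: the expected species count when a
#' log-series community with the given alpha is sampled to N individuals.
#' Applied at a continental or global total stem count, it extrapolates the
#' fitted alpha to total richness.
#'
#' @param alpha Fisher's alpha (> 0).
#' @param N total number of individuals (> 0).
#' @return expected species richness.
#' @examples
#' fisherRichness(3040, 3.04e12)
#' @export
fisherRichness <- function(alpha, N) {
  stopifnot(alpha > 0, N > 0)
  alpha * log1p(N / alpha)
}

#' Kolmogorov-Smirnov goodness of fit to the fitted log-series
#'
#' Sup distance between the empirical CDF of the per-species abundances and
#' the log-series CDF implied by the fitted alpha (x = n / (n + alpha)),
#' with the p value from the asymptotic Kolmogorov distribution. Both are
#' acknowledged approximations for discrete data; the test mirrors common
#' practice for checking the log-series assumption before using Fisher's
#' equation.
#'
#' @param abundances positive integer abundances.
#' @param alpha fitted Fisher's alpha.
#' @return list with `D` and `p`.
#' @export
logseriesGof <- function(abundances, alpha) {
  if (length(unique(abundances)) < 3)
    abdStop("goodness-of-fit test refused: fewer than 3 distinct abundance values",
            "arbodiv_gof_refused")
  n <- sum(abundances)
  S <- length(abundances)
  x <- n / (n + alpha)
  kmax <- max(abundances)
  k <- seq_len(kmax)
  fitted <- plogseries(k, x)
  emp <- cumsum(tabulate(abundances, nbins = kmax)) / S
  D <- max(abs(emp - fitted))
  t <- sqrt(S) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  list(D = D, p = min(max(p, 0), 1))
}

setMethod("show", "FisherFit", function(object) {
  cat(sprintf("Fisher log-series fit: alpha = %.4g (S_obs = %d, n = %g)\n",
              object@alpha, object@sObs, object@n))
  if (!is.na(object@ciLower))
    cat(sprintf("  bootstrap %d-replicate CI: %.4g - %.4g\n",
                object@nBoot, object@ciLower, object@ciUpper))
  if (!is.na(object@ksD))
    cat(sprintf("  log-series GoF: D = %.3g, p = %.3g\n", object@ksD, object@ksP))
})
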