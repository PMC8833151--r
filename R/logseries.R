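# Fisher's log-series distribution on k = 1, 2, ...:
#   P(k) = x^k / (k * L),  L = -log(1 - x),  0 < x < 1.
# Under Fisher's sampling theory a community with parameters (alpha, x)
# shows the identities S = -alpha log(1 - x) and n = alpha x / (1 - x),
# i.e. S = alpha log(1 + n / alpha).

#' Log-series parameter x from pool size and Fisher's alpha
#'
#' Solves S = -alpha log(1 - x) for x, the closed-form inverse of Fisher's
#' species-count identity.
#'
#' @param S number of species in the pool.
#' @param alpha Fisher's alpha.
#' @return x in (0, 1).
#' @export
logseriesX <- function(S, alpha) {
  stopifnot(S > 0, alpha > 0)
  -expm1(-S / alpha)
}

# Probability table of the log-series truncated where the cumulative mass
# reaches 1 - tol (spec'd truncation: tol = 1e-12), renormalised.
#' @noRd
logseriesTable <- function(x, tol = 1e-12, kcap = 1e7) {
  stopifnot(x > 0, x < 1)
  L <- -log1p(-x)
  # analytic bound for the needed support: tail_K ~ x^K / (K (1-x) L)
  kmax <- 64
  while (kmax < kcap) {
    tail <- exp(kmax * log(x)) / (kmax * (1 - x) * L)
    if (tail < tol) break
    kmax <- kmax * 2
  }
  k <- seq_len(min(kmax, kcap))
  p <- exp(k * log(x) - log(k)) / L
  cs <- cumsum(p)
  keep <- min(which(cs >= 1 - tol), length(k))
  list(k = k[seq_len(keep)], cdf = cs[seq_len(keep)] / cs[keep])
}

#' Log-series density, CDF and random draws
#'
#' `dlogseries` and `plogseries` evaluate the (untruncated) log-series pmf
#' and CDF; `rlogseries` draws by inverse CDF on support truncated at
#' cumulative mass 1 - 1e-12.
#'
#' @param k,q positive integer values / quantiles.
#' @param n number of draws.
#' @param x log-series parameter in (0, 1).
#' @return numeric vector.
#' @export
dlogseries <- function(k, x) {
  stopifnot(x > 0, x < 1)
  out <- numeric(length(k))
  ok <- k >= 1 & k == round(k)
  out[ok] <- exp(k[ok] * log(x) - log(k[ok])) / (-log1p(-x))
  out
}

#' @rdname dlogseries
#' @export
plogseries <- function(q, x) {
  stopifnot(x > 0, x < 1)
  qmax <- max(1, floor(max(q)))
  k <- seq_len(qmax)
  cs <- cumsum(exp(k * log(x) - log(k))) / (-log1p(-x))
  ifelse(q < 1, 0, cs[pmin(floor(q), qmax)])
}

#' @rdname dlogseries
#' @export
rlogseries <- function(n, x) {
  tab <- logseriesTable(x)
  u <- stats::runif(n)
  tab$k[findInterval(u, tab$cdf) + 1L]
}
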