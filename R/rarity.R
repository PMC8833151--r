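# Rarity indices: rare species are the sum of adjusted singletons (or
# uniques) and doubletons (or duplicates); reported as a count, as a
# fraction of observed richness, and as the adjusted-singleton to doubleton
# ratio.

#' Rarity indices from frequency counts
#'
#' @param counts a [FrequencyCounts-class] (abundance mode gives
#'   within-sample rarity, incidence mode among-sample rarity).
#' @param adjustedSingletons the adjusted singleton/unique count (>= 0);
#'   pass the observed count for unadjusted indices, or the result of
#'   [estimateTrueUniques()].
#' @return a [RarityResult-class]: rare count, rarity fraction of S_obs, and
#'   the singleton/doubleton ratio (flagged undefined when there are no
#'   doubletons).
#' @examples
#' rarityMetrics(frequencyCounts(10, q1 = 3, q2 = 2, units = 6), 3)
#' @export
rarityMetrics <- function(counts, adjustedSingletons) {
  stopifnot(is(counts, "FrequencyCounts"))
  if (is.list(adjustedSingletons)) adjustedSingletons <- adjustedSingletons$q1Hat
  if (counts@sObs == 0) abdStop("S_obs is zero", "arbodiv_data_error")
  if (adjustedSingletons < 0)
    abdStop("adjustedSingletons must be >= 0", "arbodiv_data_error")
  q2 <- counts@q[2]
  rare <- adjustedSingletons + q2
  defined <- q2 > 0
  new("RarityResult",
      mode = if (counts@mode == "incidence") "occurrence" else "abundance",
      adjustedSingletons = adjustedSingletons, doubletons = q2,
      rareCount = rare, rarityFraction = rare / counts@sObs,
      ratio = if (defined) adjustedSingletons / q2 else NA_real_,
      ratioDefined = defined, sObs = counts@sObs)
}

setMethod("show", "RarityResult", function(object) {
  cat(sprintf("Rarity (%s-based): %.1f rare of %d observed (%.1f%%)\n",
              object@mode, object@rareCount, object@sObs,
              100 * object@rarityFraction))
  cat(if (object@ratioDefined)
        sprintf("  singleton/doubleton ratio: %.3f\n", object@ratio)
      else "  singleton/doubleton ratio undefined (no doubletons)\n")
})

#' Species still to be discovered
#'
#' The adjusted asymptotic estimate minus the observed richness, rounded to
#' the nearest integer; a negative difference reports 0 and sets the
#' `"clamped"` attribute.
#'
#' @param adjustedPoint adjusted asymptotic richness (Chao2_adj point).
#' @param sObs observed richness.
#' @return integer vector (attribute `clamped`: logical vector).
#' @examples
#' toBeDiscovered(73274, 64088)
#' @export
toBeDiscovered <- function(adjustedPoint, sObs) {
  stopifnot(all(adjustedPoint >= 0))
  d <- roundHalfUp(adjustedPoint - sObs)
  clamped <- d < 0
  d[clamped] <- 0
  structure(as.integer(d), clamped = clamped)
}
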