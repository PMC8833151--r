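#' @importClassesFrom Matrix CsparseMatrix dgCMatrix
NULL

# ---------------------------------------------------------------------------
# Synthetic-world classes
# ---------------------------------------------------------------------------

#' Configuration of a synthetic multi-region world
#'
#' Holds everything [generateWorld()] needs: per-region species-pool sizes,
#' Fisher's alpha values controlling the log-series abundance structure,
#' survey sizes, the pairwise species-sharing matrix, the square grid extent
#' (number of 1-degree cells along each axis), plot density, the spatial
#' range-clustering coefficient, presence-only detection probability, the
#' misidentification rate, and the root seed from which all stochastic
#' operations derive child streams.
#'
#' @slot regions character vector of region labels.
#' @slot poolSize integer, true species per region.
#' @slot fisherAlpha positive numeric, log-series shape per region.
#' @slot totalIndividuals integer, individuals drawn by the abundance survey
#'   per region.
#' @slot sharing symmetric numeric matrix in \[0,1\] with unit diagonal; entry
#'   (i, j) is the fraction of the smaller pool shared between regions i, j.
#' @slot gridExtent integer, cells per axis of each region's square grid.
#' @slot plotsPerCell integer, forest plots placed in every grid cell.
#' @slot rangeClustering positive numeric; species range size (cells) grows
#'   as `rangeClustering * log1p(abundance weight)`, so smaller values give
#'   spatially rarer species.
#' @slot detectionProb probability in (0,1\] that an occupied cell yields a
#'   presence record in the occurrence survey.
#' @slot misidRate fraction in \[0,1) of multi-unit species whose records in
#'   one unit are relabelled to a spurious name.
#' @slot seed integer root seed.
#' @seealso [worldConfig()] for the validated constructor.
#' @export
setClass("WorldConfig",
  representation(
    regions = "character",
    poolSize = "integer",
    fisherAlpha = "numeric",
    totalIndividuals = "integer",
    sharing = "matrix",
    gridExtent = "integer",
    plotsPerCell = "integer",
    rangeClustering = "numeric",
    detectionProb = "numeric",
    misidRate = "numeric",
    seed = "integer"
  )
)

setValidity("WorldConfig", function(object) {
  R <- length(object@regions)
  msg <- character()
  if (R < 1) msg <- c(msg, "at least one region required")
  if (anyDuplicated(object@regions)) msg <- c(msg, "region labels must be unique")
  per <- c(poolSize = length(object@poolSize),
           fisherAlpha = length(object@fisherAlpha),
           totalIndividuals = length(object@totalIndividuals),
           gridExtent = length(object@gridExtent),
           plotsPerCell = length(object@plotsPerCell))
  if (any(per != R)) msg <- c(msg, "per-region fields must have one entry per region")
  if (any(object@poolSize < 1)) msg <- c(msg, "poolSize must be positive")
  if (any(object@fisherAlpha <= 0)) msg <- c(msg, "fisherAlpha must be positive")
  if (any(object@totalIndividuals < 1)) msg <- c(msg, "totalIndividuals must be positive")
  if (any(object@gridExtent < 1)) msg <- c(msg, "gridExtent must be positive")
  if (any(object@plotsPerCell < 0)) msg <- c(msg, "plotsPerCell must be >= 0")
  if (object@rangeClustering <= 0) msg <- c(msg, "rangeClustering must be positive")
  if (object@detectionProb <= 0 || object@detectionProb > 1)
    msg <- c(msg, "detectionProb must be in (0, 1]")
  if (object@misidRate < 0 || object@misidRate >= 1)
    msg <- c(msg, "misidRate must be in [0, 1)")
  sh <- object@sharing
  if (!is.numeric(sh) || nrow(sh) != R || ncol(sh) != R) {
    msg <- c(msg, "sharing must be an R x R numeric matrix")
  } else {
    if (any(sh < 0 | sh > 1)) msg <- c(msg, "sharing entries must be in [0, 1]")
    if (!isTRUE(all.equal(sh, t(sh)))) msg <- c(msg, "sharing must be symmetric")
    if (any(abs(diag(sh) - 1) > 1e-12)) msg <- c(msg, "sharing diagonal must be 1")
  }
  if (length(msg)) msg else TRUE
})

#' A generated synthetic world
#'
#' Ground truth produced by [generateWorld()]: per-region species pools with
#' log-series abundance weights, spatially clustered cell ranges on each
#' region's grid, and the grid origins placing regions on disjoint blocks of
#' the lat/lon plane. Every downstream recovery test compares estimates
#' against [trueRichness()] of this object.
#'
#' @slot config the [WorldConfig-class] that generated the world.
#' @slot species list, region -> character vector of species names.
#' @slot weights list, region -> named numeric log-series abundance weights.
#' @slot ranges list, region -> list mapping species to integer cell indices.
#' @slot origins data.frame with columns region, lat0, lon0, extent.
#' @export
setClass("SyntheticWorld",
  representation(
    config = "WorldConfig",
    species = "list",
    weights = "list",
    ranges = "list",
    origins = "data.frame"
  )
)

setValidity("SyntheticWorld", function(object) {
  for (r in object@config@regions) {
    rg <- object@ranges[[r]]
    if (any(lengths(rg) < 1)) return(sprintf("region %s: every species must occupy >= 1 cell", r))
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Incidence containers
# ---------------------------------------------------------------------------

#' Species-by-cell incidence for one region (or pooled regions)
#'
#' The central data object: a sparse presence matrix with one row per species
#' and one column per occupied ~1-degree grid-cell sampling unit. The number
#' of units T is `nUnits(x)`; per-species incidence frequencies Y_k are
#' `incidenceFreq(x)`. Built from survey records by [buildIncidence()] or
#' directly from a matrix with [gridIncidence()]; pooled across regions with
#' [poolSubset()].
#'
#' @slot region character label ("A+B" style for pooled objects).
#' @slot incidence sparse numeric matrix (species x cells) of 0/1 entries;
#'   every row and column sum is at least 1.
#' @export
setClass("GridIncidence",
  representation(
    region = "character",
    incidence = "CsparseMatrix"
  )
)

setValidity("GridIncidence", function(object) {
  m <- object@incidence
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("incidence matrix must carry species rownames and cell colnames")
  if (nrow(m) > 0 && any(Matrix::rowSums(m) < 1))
    return("every species must occur in at least one unit (Y_k >= 1)")
  if (ncol(m) > 0 && any(Matrix::colSums(m) < 1))
    return("every unit must contain at least one species")
  if (length(m@x) && any(m@x != 1))
    return("incidence entries must be 0/1")
  TRUE
})

#' Frequency counts consumed by the estimators
#'
#' In incidence mode: S_obs, the number of sampling units T, the total number
#' of species-by-cell occurrences n, and Q1..Q4 (uniques, duplicates,
#' triplicates, quadruplicates). In abundance mode: S_obs, total individuals
#' n, and f1..f4 (singletons, doubletons, tripletons, quadrupletons).
#'
#' @slot mode "incidence" or "abundance".
#' @slot sObs integer observed richness.
#' @slot units numeric: T (incidence) or NA (abundance).
#' @slot total numeric: total occurrences or total individuals n.
#' @slot q numeric length-4 vector of the frequency counts.
#' @seealso [frequencyCounts()], [tallyFrequencies()]
#' @export
setClass("FrequencyCounts",
  representation(
    mode = "character",
    sObs = "integer",
    units = "numeric",
    total = "numeric",
    q = "numeric"
  )
)

setValidity("FrequencyCounts", function(object) {
  msg <- character()
  if (!object@mode %in% c("incidence", "abundance"))
    msg <- c(msg, "mode must be 'incidence' or 'abundance'")
  if (length(object@q) != 4 || any(object@q < 0) || any(object@q != round(object@q)))
    msg <- c(msg, "q must be 4 nonnegative integer counts")
  if (object@sObs < 0) msg <- c(msg, "sObs must be >= 0")
  if (sum(object@q) > object@sObs)
    msg <- c(msg, "Q1+Q2+Q3+Q4 cannot exceed S_obs")
  if (object@mode == "incidence" && (is.na(object@units) || object@units < 1))
    msg <- c(msg, "incidence mode requires units (T) >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Estimate containers
# ---------------------------------------------------------------------------

#' Estimated sample coverage
#'
#' @slot coverage estimated completeness C_n in \[0,1\].
#' @slot deficit 1 - coverage (equals, in expectation, the terminal slope of
#'   the species accumulation curve).
#' @slot mode "incidence" or "abundance".
#' @export
setClass("CoverageResult",
  representation(coverage = "numeric", deficit = "numeric", mode = "character"))

#' Bias-corrected Chao2 estimate with log-normal confidence interval
#'
#' @slot sObs observed richness.
#' @slot nUnits number of sampling units T.
#' @slot q1,q2 unique and duplicate counts that entered the formula (q1 is
#'   the adjusted count in [AdjustedChao2-class] objects).
#' @slot point the Chao2 point estimate (>= sObs).
#' @slot variance estimator variance (Chao 1987 bias-corrected form).
#' @slot excess point - sObs.
#' @slot K log-normal CI scale factor.
#' @slot ciLower,ciUpper confidence bounds (lower >= sObs).
#' @slot level confidence level.
#' @export
setClass("Chao2Estimate",
  representation(
    sObs = "integer", nUnits = "numeric",
    q1 = "numeric", q2 = "numeric",
    point = "numeric", variance = "numeric", excess = "numeric",
    K = "numeric", ciLower = "numeric", ciUpper = "numeric",
    level = "numeric"
  )
)

setValidity("Chao2Estimate", function(object) {
  msg <- character()
  if (object@point < object@sObs - 1e-9) msg <- c(msg, "point must be >= sObs")
  if (object@ciLower < object@sObs - 1e-9) msg <- c(msg, "ciLower must be >= sObs")
  if (object@ciLower > object@point + 1e-9 || object@point > object@ciUpper + 1e-9)
    msg <- c(msg, "need ciLower <= point <= ciUpper")
  if (length(msg)) msg else TRUE
})

#' Chao2 recomputed with the estimated true number of uniques
#'
#' Identical structure to [Chao2Estimate-class]; `q1` holds the estimated
#' true unique count Q1-hat that replaced the observed Q1.
#'
#' @slot q1Hat the estimated true number of uniques used.
#' @slot fallbackUsed TRUE when degenerate tallies (Q3 = 0 or Q4 = 0) forced
#'   the observed Q1 to be used unadjusted.
#' @export
setClass("AdjustedChao2",
  contains = "Chao2Estimate",
  representation(q1Hat = "numeric", fallbackUsed = "logical"))

#' Fisher log-series fit
#'
#' @slot alpha fitted Fisher's alpha (solves S_obs = alpha log(1 + n/alpha)).
#' @slot n total individuals.
#' @slot sObs observed richness.
#' @slot ksD,ksP Kolmogorov-Smirnov sup distance and asymptotic p value of
#'   the log-series goodness-of-fit test (NA when the test was not run).
#' @slot ciLower,ciUpper bootstrap CI for alpha (NA when nBoot = 0).
#' @slot nBoot bootstrap replicates used.
#' @export
setClass("FisherFit",
  representation(
    alpha = "numeric", n = "numeric", sObs = "integer",
    ksD = "numeric", ksP = "numeric",
    ciLower = "numeric", ciUpper = "numeric", nBoot = "integer"
  )
)

#' Rarity indices
#'
#' @slot mode "abundance" (singletons within cells) or "occurrence" (uniques
#'   across cells).
#' @slot adjustedSingletons the adjusted singleton/unique count used.
#' @slot doubletons observed doubleton/duplicate count.
#' @slot rareCount adjusted singletons + doubletons.
#' @slot rarityFraction rareCount / S_obs.
#' @slot ratio adjusted singletons / doubletons (NA and `ratioDefined` FALSE
#'   when there are no doubletons).
#' @slot ratioDefined logical.
#' @slot sObs observed richness.
#' @export
setClass("RarityResult",
  representation(
    mode = "character", adjustedSingletons = "numeric", doubletons = "numeric",
    rareCount = "numeric", rarityFraction = "numeric",
    ratio = "numeric", ratioDefined = "logical", sObs = "integer"
  )
)

#' Sample-based accumulation curve with uncertainty bands
#'
#' @slot region region label.
#' @slot points data.frame with columns t, segment ("interpolated" or
#'   "extrapolated"), sT (expected richness), lower, upper.
#' @slot nBoot bootstrap replicates behind the bands.
#' @slot level band level.
#' @slot seed seed used for the bootstrap.
#' @export
setClass("AccumulationCurve",
  representation(
    region = "character", points = "data.frame",
    nBoot = "integer", level = "numeric", seed = "integer"
  )
)

#' Richness partition over all nonempty region subsets
#'
#' @slot regions the R region labels.
#' @slot estimator "chao2" or "chao2adj".
#' @slot subsets data.frame with one row per nonempty subset (2^R - 1 rows):
#'   mask, labels, size, nUnits, sObs, estimate, ciLower, ciUpper.
#' @slot endemics data.frame per region: endemic estimate (full-set estimate
#'   minus the estimate without that region), clamped value, percentage of
#'   the region's own estimate, and display (half-up integer) percentage.
#' @slot sharedAll inclusion-exclusion estimate of richness shared by all
#'   regions, clamped at 0.
#' @slot sharedAllRaw the pre-clamp value (estimator non-linearity can make
#'   it slightly negative; the residual is surfaced, not hidden).
#' @export
setClass("PartitionTable",
  representation(
    regions = "character", estimator = "character",
    subsets = "data.frame", endemics = "data.frame",
    sharedAll = "numeric", sharedAllRaw = "numeric"
  )
)
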