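#' @import methods
NULL

#' Number of sampling units
#'
#' Number of grid-cell sampling units behind an incidence object (the
#' quantity usually written T, or m in some presentations of the Chao2
#' formula).
#'
#' @param x a [GridIncidence-class] or [FrequencyCounts-class] object.
#' @return integer (or numeric) count of sampling units.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Observed species richness
#'
#' @param x an object holding observed species (incidence matrix, frequency
#'   tallies, or an estimate).
#' @return the number of distinct species observed.
#' @export
setGeneric("sObs", function(x) standardGeneric("sObs"))

#' Per-species incidence frequencies
#'
#' @param x a [GridIncidence-class] object.
#' @return named integer vector Y_k: for each species, the number of distinct
#'   sampling units it occurs in.
#' @export
setGeneric("incidenceFreq", function(x) standardGeneric("incidenceFreq"))

#' Region label of an object
#'
#' @param x an object carrying a region label.
#' @return character label (pooled objects use "A+B" style labels).
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' Tally frequency counts
#'
#' Tallies the low-order frequency counts every richness estimator consumes:
#' in incidence mode the numbers of uniques, duplicates, triplicates and
#' quadruplicates (Q1..Q4); in abundance mode the numbers of singletons,
#' doubletons, tripletons and quadrupletons (f1..f4).
#'
#' @param x a [GridIncidence-class] object (incidence mode) or a numeric
#'   vector of per-species abundances (abundance mode).
#' @param ... unused.
#' @return a [FrequencyCounts-class] object.
#' @export
setGeneric("tallyFrequencies", function(x, ...) standardGeneric("tallyFrequencies"))

#' Bias-corrected Chao2 asymptotic richness
#'
#' @param x a [FrequencyCounts-class] object in incidence mode, or a
#'   [GridIncidence-class] object (tallied internally).
#' @param ... passed on to methods (notably `level`).
#' @return a [Chao2Estimate-class] object.
#' @export
setGeneric("chao2", function(x, ...) standardGeneric("chao2"))

#' Good-Turing sample coverage
#'
#' @param x a [FrequencyCounts-class] object (either mode).
#' @param ... unused.
#' @return a [CoverageResult-class] object.
#' @export
setGeneric("sampleCoverage", function(x, ...) standardGeneric("sampleCoverage"))

#' True richness of a synthetic world
#'
#' Ground-truth richness of the union of the species pools of the given
#' regions; used by recovery tests.
#'
#' @param x a [SyntheticWorld-class] object.
#' @param regions character vector of region labels (default: all).
#' @return integer count of distinct true species.
#' @export
setGeneric("trueRichness", function(x, regions = NULL) standardGeneric("trueRichness"))
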