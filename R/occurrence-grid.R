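# Grid-cell aggregation of survey records into incidence structures.
# Cells are exact 1 x 1 degree lat/lon blocks (the ~100 x 100 km sampling
# unit), lower-left closed / upper-right open: cell id = (floor(lat),
# floor(lon)). Abundance records are degraded to presence; a species-by-cell
# pair counts once however many records support it.

#' Assign records to 1-degree grid cells
#'
#' Adds `cell`, `cellLat`, `cellLon` columns. Records with out-of-range
#' coordinates (lat outside \[-90, 90\], lon outside \[-180, 180)) or blank
#' species names are rejected, never silently dropped: a message reports the
#' counts and the `"rejected"` attribute carries the tally by reason.
#'
#' @param records data.frame with at least species, lat, lon columns.
#' @param quiet suppress the ingest message.
#' @return the accepted records with cell columns; attribute `rejected` is a
#'   named integer vector of rejection counts.
#' @examples
#' r <- data.frame(species = "a", lat = 5.3, lon = -72.8,
#'                 region = "SA", source = "occurrence")
#' assignCells(r)[, c("cellLat", "cellLon")]  # cell (5, -73)
#' @export
assignCells <- function(records, quiet = FALSE) {
  badLat <- is.na(records$lat) | records$lat < -90 | records$lat > 90
  badLon <- is.na(records$lon) | records$lon < -180 | records$lon >= 180
  badSp <- is.na(records$species) | !nzchar(trimws(records$species))
  keep <- !(badLat | badLon | badSp)
  rejected <- c(bad_latitude = sum(badLat), bad_longitude = sum(badLon & !badLat),
                blank_species = sum(badSp & !badLat & !badLon))
  out <- records[keep, , drop = FALSE]
  out$cellLat <- as.integer(floor(out$lat))
  out$cellLon <- as.integer(floor(out$lon))
  out$cell <- sprintf("%d:%d", out$cellLat, out$cellLon)
  if (!quiet && sum(rejected) > 0)
    message("assignCells: rejected ", sum(rejected), " record(s) [",
            paste(names(rejected)[rejected > 0], rejected[rejected > 0],
                  sep = "=", collapse = ", "), "]")
  attr(out, "rejected") <- rejected
  rownames(out) <- NULL
  out
}

#' Build a per-region incidence structure from records
#'
#' Pools abundance- and occurrence-source records of one region into a
#' species-by-cell presence matrix. Species names are compared after
#' whitespace trimming and case folding only. T is the number of distinct
#' cells containing at least one record.
#'
#' @param records cell-assigned records (see [assignCells()]; called
#'   automatically when the cell column is absent).
#' @param region region label to select; records carry region membership in
#'   their `region` column (never inferred from geometry).
#' @return a [GridIncidence-class] object.
#' @examples
#' r <- data.frame(species = c("a", "a", "b"), lat = c(1.1, 1.2, 2.5),
#'                 lon = c(3.3, 3.4, 3.9), region = "X", source = "occurrence")
#' gi <- buildIncidence(r, "X")
#' nUnits(gi); incidenceFreq(gi)
#' @export
buildIncidence <- function(records, region) {
  if (is.null(records$cell)) records <- assignCells(records, quiet = TRUE)
  rec <- records[records$region == region, , drop = FALSE]
  if (nrow(rec) == 0L)
    abdStop(sprintf("no records for region '%s'", region), "arbodiv_empty_region")
  sp <- normalizeSpecies(rec$species)
  pairs <- unique(data.frame(species = sp, cell = rec$cell,
                             stringsAsFactors = FALSE))
  species <- sort(unique(pairs$species))
  cells <- sort(unique(pairs$cell))
  m <- Matrix::sparseMatrix(
    i = match(pairs$species, species),
    j = match(pairs$cell, cells),
    x = 1,
    dims = c(length(species), length(cells)),
    dimnames = list(species, cells)
  )
  new("GridIncidence", region = region, incidence = m)
}

#' Construct a GridIncidence from a presence matrix
#'
#' Convenience constructor for toy fixtures and resampling: any matrix with
#' species rownames and cell colnames; entries > 0 are presences. All-zero
#' rows and columns are dropped.
#'
#' @param mat matrix or Matrix, species x cells.
#' @param region label.
#' @return a [GridIncidence-class].
#' @export
gridIncidence <- function(mat, region = "toy") {
  m <- Matrix::Matrix(as(mat > 0, "matrix") * 1, sparse = TRUE)
  if (is.null(rownames(m))) rownames(m) <- sprintf("sp%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("u%03d", seq_len(ncol(m)))
  m <- m[Matrix::rowSums(m) > 0, Matrix::colSums(m) > 0, drop = FALSE]
  new("GridIncidence", region = region, incidence = as(m, "CsparseMatrix"))
}

#' @describeIn GridIncidence-class number of sampling units T
#' @param x a GridIncidence
#' @export
setMethod("nUnits", "GridIncidence", function(x) ncol(x@incidence))

#' @describeIn GridIncidence-class observed richness
#' @export
setMethod("sObs", "GridIncidence", function(x) nrow(x@incidence))

#' @describeIn GridIncidence-class named incidence frequencies Y_k
#' @export
setMethod("incidenceFreq", "GridIncidence",
          function(x) round(Matrix::rowSums(x@incidence)))

#' @describeIn GridIncidence-class region label
#' @export
setMethod("regionLabel", "GridIncidence", function(x) x@region)

setMethod("show", "GridIncidence", function(object) {
  cat(sprintf("GridIncidence '%s': %d species x %d sampling units (%d presences)\n",
              object@region, nrow(object@incidence), ncol(object@incidence),
              as.integer(sum(object@incidence))))
})

# internal: resample sampling units with replacement (bootstrap)
#' @noRd
resampleUnits <- function(gi, idx) {
  m <- gi@incidence[, idx, drop = FALSE]
  colnames(m) <- sprintf("b%05d", seq_along(idx))
  m <- m[Matrix::rowSums(m) > 0, , drop = FALSE]
  new("GridIncidence", region = gi@region, incidence = as(m, "CsparseMatrix"))
}

#' Construct FrequencyCounts directly
#'
#' For toy tallies and printed-table inputs where the full incidence matrix
#' is unavailable.
#'
#' @param sObs observed richness.
#' @param q1,q2,q3,q4 frequency counts (uniques/singletons ... ).
#' @param units number of sampling units T (incidence mode).
#' @param total total occurrences/individuals n (needed for coverage).
#' @param mode "incidence" or "abundance".
#' @return a [FrequencyCounts-class].
#' @examples
#' frequencyCounts(sObs = 5, q1 = 2, q2 = 1, units = 10)
#' @export
frequencyCounts <- function(sObs, q1, q2 = 0, q3 = 0, q4 = 0,
                            units = NA_real_, total = NA_real_,
                            mode = "incidence") {
  new("FrequencyCounts", mode = mode, sObs = as.integer(sObs),
      units = as.numeric(units), total = as.numeric(total),
      q = as.numeric(c(q1, q2, q3, q4)))
}

#' @describeIn tallyFrequencies incidence-mode tallies (Q1..Q4) from a
#'   GridIncidence; `units` is T and `total` the number of species-by-cell
#'   presences.
#' @export
setMethod("tallyFrequencies", "GridIncidence", function(x, ...) {
  Y <- incidenceFreq(x)
  tab <- tabulate(Y, nbins = max(4L, max(Y)))
  frequencyCounts(sObs = length(Y), q1 = tab[1], q2 = tab[2], q3 = tab[3],
                  q4 = tab[4], units = nUnits(x), total = sum(Y),
                  mode = "incidence")
})

#' @describeIn tallyFrequencies abundance-mode tallies (f1..f4) from a
#'   vector of per-species abundances; `total` is the number of individuals.
#' @export
setMethod("tallyFrequencies", "numeric", function(x, ...) {
  if (length(x) == 0L) abdStop("empty abundance vector", "arbodiv_data_error")
  if (any(x < 1 | x != round(x)))
    abdStop("abundances must be positive integers", "arbodiv_data_error")
  tab <- tabulate(x, nbins = max(4L, max(x)))
  frequencyCounts(sObs = length(x), q1 = tab[1], q2 = tab[2], q3 = tab[3],
                  q4 = tab[4], units = NA_real_, total = sum(x),
                  mode = "abundance")
})

#' @describeIn FrequencyCounts-class observed richness
#' @param x a FrequencyCounts
#' @export
setMethod("sObs", "FrequencyCounts", function(x) x@sObs)

#' @describeIn FrequencyCounts-class sampling units T (NA in abundance mode)
#' @export
setMethod("nUnits", "FrequencyCounts", function(x) x@units)

setMethod("show", "FrequencyCounts", function(object) {
  lab <- if (object@mode == "incidence") c("Q1", "Q2", "Q3", "Q4")
         else c("f1", "f2", "f3", "f4")
  cat(sprintf("FrequencyCounts (%s): S_obs = %d, %s\n", object@mode,
              object@sObs,
              paste(lab, object@q, sep = " = ", collapse = ", ")))
  if (object@mode == "incidence")
    cat(sprintf("  T = %g sampling units, n = %g total presences\n",
                object@units, object@total))
  else cat(sprintf("  n = %g individuals\n", object@total))
})

#' Frequency counts Q1..Q4 / f1..f4
#'
#' @param x a [FrequencyCounts-class].
#' @return named numeric vector of the four counts.
#' @export
qCounts <- function(x) {
  stopifnot(is(x, "FrequencyCounts"))
  stats::setNames(x@q, if (x@mode == "incidence") c("Q1", "Q2", "Q3", "Q4")
                       else c("f1", "f2", "f3", "f4"))
}
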