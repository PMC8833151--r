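# Synthetic multi-continent tree communities with the statistical structure
# the estimators assume: log-series regional abundances, spatially clustered
# species ranges on 1-degree grids (producing long-tailed incidence
# frequencies), configurable cross-region species sharing, and an injectable
# misidentification process that turns duplicates into pairs of false
# uniques.

#' Build a validated WorldConfig
#'
#' Per-region arguments are recycled to the number of regions. The defaults
#' describe a small two-region world suitable for examples and tests.
#'
#' @param regions character region labels.
#' @param poolSize true species per region.
#' @param fisherAlpha Fisher's alpha of the regional log-series abundance
#'   structure.
#' @param totalIndividuals individuals drawn by the abundance survey.
#' @param sharing R x R symmetric matrix of pairwise shared-species
#'   fractions (fraction of the smaller of the two pools); default identity
#'   (fully endemic regions).
#' @param gridExtent cells per axis of the square 1-degree regional grid.
#' @param plotsPerCell forest plots per grid cell.
#' @param rangeClustering spatial clustering coefficient: target range size
#'   is `rangeClustering * log1p(abundance weight)` cells (minimum 1).
#' @param detectionProb per-cell detection probability of the presence-only
#'   survey.
#' @param misidRate fraction of multi-unit species split by
#'   [injectMisidentification()].
#' @param seed root seed; every stochastic operation derives a child stream
#'   from (seed, operation, region).
#' @return a [WorldConfig-class] object.
#' @examples
#' cfg <- worldConfig(c("A", "B"), poolSize = 100, fisherAlpha = 20,
#'                    totalIndividuals = 5000, gridExtent = 6, seed = 1)
#' @export
worldConfig <- function(regions, poolSize, fisherAlpha, totalIndividuals,
                        sharing = diag(length(regions)),
                        gridExtent = 10L, plotsPerCell = 1L,
                        rangeClustering = 2, detectionProb = 1,
                        misidRate = 0, seed = 1L) {
  R <- length(regions)
  dimnames(sharing) <- list(regions, regions)
  new("WorldConfig",
      regions = as.character(regions),
      poolSize = rep_len(as.integer(poolSize), R),
      fisherAlpha = rep_len(as.numeric(fisherAlpha), R),
      totalIndividuals = rep_len(as.integer(totalIndividuals), R),
      sharing = sharing,
      gridExtent = rep_len(as.integer(gridExtent), R),
      plotsPerCell = rep_len(as.integer(plotsPerCell), R),
      rangeClustering = as.numeric(rangeClustering),
      detectionProb = as.numeric(detectionProb),
      misidRate = as.numeric(misidRate),
      seed = as.integer(seed))
}

# cell index <-> lattice coordinates for a G x G grid (column-major)
#' @noRd
cellRowCol <- function(idx, G) {
  cbind(row = (idx - 1L) %% G + 1L, col = (idx - 1L) %/% G + 1L)
}

# the `size` nearest cells to a center cell, ties broken by index order
#' @noRd
nearestCells <- function(center, size, G) {
  rc <- cellRowCol(seq_len(G * G), G)
  c0 <- cellRowCol(center, G)
  d2 <- (rc[, 1] - c0[1])^2 + (rc[, 2] - c0[2])^2
  order(d2, seq_len(G * G))[seq_len(size)]
}

#' Generate a synthetic world
#'
#' Draws per-region species pools with log-series abundance weights at the
#' configured Fisher's alpha (parameter x solved from pool size and alpha,
#' inverse-CDF sampling truncated at cumulative mass 1 - 1e-12), allocates
#' shared species across region pairs per the sharing matrix, and assigns
#' each species a spatially clustered range: a uniformly drawn center cell
#' plus its nearest lattice cells, with range size increasing with the
#' species' regional abundance weight.
#'
#' @param config a [WorldConfig-class].
#' @return a [SyntheticWorld-class] object.
#' @examples
#' w <- generateWorld(worldConfig("A", 50, 10, 2000, gridExtent = 5, seed = 7))
#' trueRichness(w)
#' @export
generateWorld <- function(config) {
  validObject(config)
  regions <- config@regions
  R <- length(regions)
  G <- config@gridExtent

  # regions tile disjoint longitude blocks at lat [0, G)
  if (-180 + R * (max(G) + 2) > 180 || max(G) > 89)
    abdStop("regional grids do not fit on the lat/lon plane", "arbodiv_config_error")
  origins <- data.frame(
    region = regions,
    lat0 = 0,
    lon0 = -180 + (seq_len(R) - 1L) * (max(G) + 2L),
    extent = G,
    stringsAsFactors = FALSE
  )

  # pairwise shared-species allocation: a dedicated block per region pair
  nShare <- matrix(0L, R, R, dimnames = list(regions, regions))
  for (i in seq_len(R)) for (j in seq_len(R)) if (i < j) {
    nShare[i, j] <- as.integer(round(config@sharing[i, j] *
                                       min(config@poolSize[i], config@poolSize[j])))
  }
  endemic <- config@poolSize - (rowSums(nShare) + colSums(nShare))
  if (any(endemic < 0))
    abdStop("requested shared species exceed a region's pool size",
            "arbodiv_config_error")

  counter <- 0L
  newSpecies <- function(n) {
    ids <- sprintf("sp%06d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  pools <- stats::setNames(replicate(R, character(0), simplify = FALSE), regions)
  for (i in seq_len(R)) for (j in seq_len(R)) if (i < j && nShare[i, j] > 0) {
    sh <- newSpecies(nShare[i, j])
    pools[[i]] <- c(pools[[i]], sh)
    pools[[j]] <- c(pools[[j]], sh)
  }
  for (i in seq_len(R)) pools[[i]] <- c(pools[[i]], newSpecies(endemic[i]))

  weights <- ranges <- stats::setNames(vector("list", R), regions)
  for (i in seq_len(R)) {
    r <- regions[i]
    S <- config@poolSize[i]
    x <- logseriesX(S, config@fisherAlpha[i])
    w <- withSeed(childSeed(config@seed, "weights", r), rlogseries(S, x))
    names(w) <- pools[[i]]
    weights[[r]] <- w
    nc <- G[i] * G[i]
    sizes <- pmin(nc, pmax(1L, as.integer(round(config@rangeClustering * log1p(w)))))
    ranges[[r]] <- withSeed(childSeed(config@seed, "ranges", r), {
      centers <- sample.int(nc, S, replace = TRUE)
      out <- vector("list", S)
      for (s in seq_len(S)) out[[s]] <- nearestCells(centers[s], sizes[s], G[i])
      stats::setNames(out, pools[[i]])
    })
  }

  new("SyntheticWorld", config = config, species = pools,
      weights = weights, ranges = ranges, origins = origins)
}

#' @describeIn generateWorld ground-truth richness of a region subset
#'   (size of the union of the regional species pools).
#' @param x a [SyntheticWorld-class].
#' @param regions region labels (default all).
#' @export
setMethod("trueRichness", "SyntheticWorld", function(x, regions = NULL) {
  if (is.null(regions)) regions <- x@config@regions
  stopifnot(all(regions %in% x@config@regions))
  length(unique(unlist(x@species[regions], use.names = FALSE)))
})

#' @noRd
emptyRecords <- function() {
  data.frame(species = character(), lat = numeric(), lon = numeric(),
             stems = integer(), plot_id = character(), region = character(),
             source = character(), stringsAsFactors = FALSE)
}

#' Simulate the plot-based abundance survey
#'
#' Places `plotsPerCell` plots uniformly inside every grid cell of each
#' region, then draws `totalIndividuals` stems per region by weighted
#' sampling of the regional species pool; each individual lands in a plot
#' drawn uniformly among the plots inside its species' occupied cells.
#' Individuals are conserved: total stems equal the configured count.
#'
#' @param world a [SyntheticWorld-class].
#' @return records data.frame (species, lat, lon, stems, plot_id, region,
#'   source = "abundance"), one row per species-by-plot.
#' @export
sampleAbundanceSurvey <- function(world) {
  cfg <- world@config
  out <- list()
  for (i in seq_along(cfg@regions)) {
    r <- cfg@regions[i]
    ppc <- cfg@plotsPerCell[i]
    if (ppc == 0L) next
    G <- cfg@gridExtent[i]
    nc <- G * G
    org <- world@origins[world@origins$region == r, ]
    rc <- cellRowCol(seq_len(nc), G)

    plots <- withSeed(childSeed(cfg@seed, "plots", r), {
      cell <- rep(seq_len(nc), each = ppc)
      p <- rep(seq_len(ppc), times = nc)
      data.frame(
        cell = cell,
        lat = org$lat0 + (rc[cell, 1] - 1L) + stats::runif(nc * ppc),
        lon = org$lon0 + (rc[cell, 2] - 1L) + stats::runif(nc * ppc),
        plot_id = sprintf("%s.c%04d.p%03d", r, cell, p),
        stringsAsFactors = FALSE
      )
    })
    plotsByCell <- split(seq_len(nrow(plots)), plots$cell)

    w <- world@weights[[r]]
    recs <- withSeed(childSeed(cfg@seed, "abundance", r), {
      counts <- as.vector(stats::rmultinom(1, cfg@totalIndividuals[i], w))
      rows <- list()
      for (s in which(counts > 0L)) {
        idx <- unlist(plotsByCell[as.character(world@ranges[[r]][[s]])],
                      use.names = FALSE)
        alloc <- as.vector(stats::rmultinom(1, counts[s], rep(1, length(idx))))
        hit <- which(alloc > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          species = names(w)[s],
          lat = plots$lat[idx[hit]], lon = plots$lon[idx[hit]],
          stems = alloc[hit], plot_id = plots$plot_id[idx[hit]],
          region = r, source = "abundance", stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
    out[[r]] <- recs
  }
  if (!length(out)) return(emptyRecords())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the presence-only occurrence survey
#'
#' Emits, for every species-by-occupied-cell pair, a presence record with
#' probability `detectionProb`; records carry the cell-center coordinate and
#' no stem counts.
#'
#' @param world a [SyntheticWorld-class].
#' @return records data.frame (species, lat, lon, stems = NA, plot_id = NA,
#'   region, source = "occurrence").
#' @export
sampleOccurrenceSurvey <- function(world) {
  cfg <- world@config
  out <- list()
  for (i in seq_along(cfg@regions)) {
    r <- cfg@regions[i]
    G <- cfg@gridExtent[i]
    org <- world@origins[world@origins$region == r, ]
    rg <- world@ranges[[r]]
    sp <- rep(names(rg), lengths(rg))
    cell <- unlist(rg, use.names = FALSE)
    keep <- withSeed(childSeed(cfg@seed, "occurrence", r),
                     stats::runif(length(cell)) <= cfg@detectionProb)
    if (!any(keep)) next
    rc <- cellRowCol(cell[keep], G)
    out[[r]] <- data.frame(
      species = sp[keep],
      lat = org$lat0 + (rc[, 1] - 1L) + 0.5,
      lon = org$lon0 + (rc[, 2] - 1L) + 0.5,
      stems = NA_integer_, plot_id = NA_character_,
      region = r, source = "occurrence", stringsAsFactors = FALSE)
  }
  if (!length(out)) return(emptyRecords())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inject species misidentification (false uniques)
#'
#' Emulates the error process the true-uniques adjustment targets: for a
#' fraction `misidRate` of the species occurring in at least two sampling
#' units, all records of that species in one uniformly chosen unit are
#' relabelled to a new spurious name. A duplicate species (Y = 2) thereby
#' becomes a pair of false uniques. The spurious-to-true mapping is retained
#' as ground truth in the `"misidMap"` attribute.
#'
#' @param records a records data.frame (any mix of sources).
#' @param misidRate fraction in \[0, 1).
#' @param seed integer seed for the selection stream.
#' @return the records with relabelled species names; attribute `misidMap`
#'   is a data.frame (spurious, true, unit).
#' @export
injectMisidentification <- function(records, misidRate, seed = 1L) {
  if (misidRate < 0 || misidRate > 1)
    abdStop("misidRate must be in [0, 1]", "arbodiv_config_error")
  if (nrow(records) == 0L)
    abdStop("records must be nonempty", "arbodiv_data_error")
  emptyMap <- data.frame(spurious = character(), true = character(),
                         unit = character(), stringsAsFactors = FALSE)
  if (misidRate == 0) {
    attr(records, "misidMap") <- emptyMap
    return(records)
  }
  unit <- paste(records$region, floor(records$lat), floor(records$lon), sep = ":")
  su <- unique(data.frame(species = records$species, unit = unit,
                          stringsAsFactors = FALSE))
  Y <- table(su$species)
  eligible <- names(Y)[Y >= 2L]
  nPick <- as.integer(round(misidRate * length(eligible)))
  if (nPick == 0L) {
    attr(records, "misidMap") <- emptyMap
    return(records)
  }
  map <- withSeed(childSeed(seed, "misid"), {
    picked <- if (length(eligible) == 1L) eligible else sample(eligible, nPick)
    chosen <- vapply(picked, function(s) {
      us <- su$unit[su$species == s]
      us[sample.int(length(us), 1L)]
    }, character(1))
    data.frame(spurious = paste0(picked, "_spur"), true = picked,
               unit = unname(chosen), stringsAsFactors = FALSE)
  })
  for (m in seq_len(nrow(map))) {
    hit <- records$species == map$true[m] & unit == map$unit[m]
    records$species[hit] <- map$spurious[m]
  }
  attr(records, "misidMap") <- map
  records
}

setMethod("show", "WorldConfig", function(object) {
  cat("WorldConfig:", length(object@regions), "region(s):",
      paste(object@regions, collapse = ", "), "\n")
  cat("  pool sizes:", paste(object@poolSize, collapse = ", "),
      "| alpha:", paste(object@fisherAlpha, collapse = ", "), "\n")
  cat("  grid:", paste(object@gridExtent, collapse = ", "),
      "cells/axis | plots/cell:", paste(object@plotsPerCell, collapse = ", "), "\n")
  cat("  detectionProb:", object@detectionProb,
      "| misidRate:", object@misidRate, "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", length(object@config@regions), "region(s),",
      trueRichness(object), "true species overall\n")
  for (r in object@config@regions)
    cat(sprintf("  %s: %d species on a %dx%d grid\n", r,
                length(object@species[[r]]),
                object@config@gridExtent[match(r, object@config@regions)],
                object@config@gridExtent[match(r, object@config@regions)]))
})
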