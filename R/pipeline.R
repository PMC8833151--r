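# End-to-end runner: synthesize or ingest survey data, aggregate to grid
# cells, estimate coverage / Chao2 / adjusted Chao2 per region and for the
# independently pooled whole, and assemble the report table, rarity table,
# accumulation curves and partition table, with a JSON run manifest.

#' Share of the global estimate held by one region
#'
#' `100 * regionAdjusted / globalAdjusted`, unrounded; reports apply
#' half-up integer rounding for display.
#'
#' @param regionAdjusted region-level adjusted richness estimate.
#' @param globalAdjusted global adjusted richness estimate (> 0).
#' @return numeric percentage.
#' @examples
#' roundHalfUp(reportShare(16264, 73274))  # 22
#' @export
reportShare <- function(regionAdjusted, globalAdjusted) {
  stopifnot(globalAdjusted > 0)
  100 * regionAdjusted / globalAdjusted
}

#' Percentage increase of an estimate over the observed richness
#'
#' `100 * (adjusted - observed) / observed`: how much larger the asymptotic
#' estimate is than the species count already encountered.
#'
#' @param adjusted asymptotic (adjusted) estimate.
#' @param observed observed richness (> 0).
#' @return numeric percentage.
#' @examples
#' roundHalfUp(richnessIncreasePct(73274, 64088), 1)  # 14.3
#' @export
richnessIncreasePct <- function(adjusted, observed) {
  stopifnot(observed > 0)
  100 * (adjusted - observed) / observed
}

# one report row from an incidence object
#' @noRd
reportRowFor <- function(gi, level, parse) {
  fc <- tallyFrequencies(gi)
  cov <- sampleCoverage(fc)
  est <- chao2(fc, level)
  tu <- estimateTrueUniques(fc, parse)
  adj <- adjustedChao2(fc, tu, level)
  list(fc = fc, coverage = cov, chao2 = est, trueUniques = tu, adjusted = adj,
       row = data.frame(
         region = regionLabel(gi),
         samplingUnits = nUnits(gi),
         speciesObserved = sObs(gi),
         coveragePct = 100 * cov@coverage,
         chao2 = est@point, chao2Lower = est@ciLower, chao2Upper = est@ciUpper,
         chao2Adj = adj@point, adjLower = adj@ciLower, adjUpper = adj@ciUpper,
         q1Hat = adj@q1Hat, fallbackUsed = adj@fallbackUsed,
         toBeDiscovered = as.integer(toBeDiscovered(adj@point, sObs(gi))),
         stringsAsFactors = FALSE))
}

#' Run the full estimation pipeline
#'
#' Either synthesises a survey from a [WorldConfig-class] (abundance +
#' occurrence surveys, optional misidentification per the config) or ingests
#' survey tables, then: assigns records to 1-degree cells, builds per-region
#' incidence and the pooled global incidence (the global estimate is
#' computed independently, never by summing regional estimates), and
#' computes coverage, Chao2 with CI, the true-unique adjustment, adjusted
#' Chao2 with CI, to-be-discovered counts and share-of-global percentages,
#' plus rarity tables (both modes), accumulation curves, the 2^R - 1 subset
#' partition, and a Fisher log-series fit of the abundance data.
#'
#' Deterministic given the seed: running twice writes byte-identical numeric
#' outputs.
#'
#' @param world a [WorldConfig-class] (synthetic mode); exclusive with the
#'   file arguments.
#' @param abundanceFile,occurrenceFile CSV paths (files mode; at least one).
#' @param outputDir directory for report.csv, rarity.csv, curves.csv,
#'   partition_subsets.csv, partition_endemics.csv and manifest.json (NULL:
#'   nothing written).
#' @param level CI level.
#' @param parse Q1-hat exponent parse (see [estimateTrueUniques()]).
#' @param curves compute accumulation curves.
#' @param curveBoot bootstrap replicates per curve.
#' @param fisherTotal external total tree count N for Fisher's richness
#'   equation (default the published global estimate of 3.04e12 stems).
#' @param verbose log progress and ingest statistics.
#' @return invisibly, a list: report (data.frame), regional (per-region
#'   estimate objects), global, rarity, partition ([PartitionTable-class] or
#'   NULL), curves, fisher, records, manifest.
#' @export
runPipeline <- function(world = NULL, abundanceFile = NULL,
                        occurrenceFile = NULL, outputDir = NULL,
                        level = 0.95, parse = "linear", curves = TRUE,
                        curveBoot = 50L, fisherTotal = 3.04e12,
                        verbose = TRUE) {
  synthetic <- !is.null(world)
  files <- !is.null(abundanceFile) || !is.null(occurrenceFile)
  if (synthetic == files)
    abdStop("supply exactly one input mode: a WorldConfig or file path(s)",
            "arbodiv_config_error")
  say <- function(...) if (verbose) message("[arbodiv] ", ...)
  t0 <- proc.time()[["elapsed"]]

  misidMap <- NULL
  if (synthetic) {
    stopifnot(is(world, "WorldConfig"))
    say("generating synthetic world (seed ", world@seed, ")")
    sw <- generateWorld(world)
    records <- rbind(sampleAbundanceSurvey(sw), sampleOccurrenceSurvey(sw))
    if (world@misidRate > 0) {
      records <- injectMisidentification(records, world@misidRate, world@seed)
      misidMap <- attr(records, "misidMap")
      say("injected misidentification: ", nrow(misidMap), " species split")
    }
    seed <- world@seed
  } else {
    sw <- NULL
    parts <- list()
    if (!is.null(abundanceFile)) parts$ab <- readAbundanceTable(abundanceFile)
    if (!is.null(occurrenceFile)) parts$oc <- readOccurrenceTable(occurrenceFile)
    records <- do.call(rbind, parts)
    seed <- 1L
  }
  if (nrow(records) == 0L)
    abdStop("no survey records", "arbodiv_data_error")

  records <- assignCells(records, quiet = !verbose)
  regions <- sort(unique(records$region))
  say(nrow(records), " records accepted across ", length(regions), " region(s)")

  incidences <- lapply(regions, function(r) buildIncidence(records, r))
  names(incidences) <- regions
  globalInc <- if (length(regions) > 1) poolSubset(incidences, regions)
               else incidences[[1]]
  globalInc@region <- "Global"

  say("estimating per region and globally")
  regional <- lapply(incidences, reportRowFor, level = level, parse = parse)
  global <- reportRowFor(globalInc, level = level, parse = parse)
  report <- do.call(rbind, c(lapply(regional, `[[`, "row"), list(global$row)))
  report$shareOfGlobalPct <- reportShare(report$chao2Adj,
                                         global$adjusted@point)
  report$increasePct <- richnessIncreasePct(report$chao2Adj,
                                            report$speciesObserved)
  rownames(report) <- NULL

  # rarity, both modes where the data allow
  rar <- list()
  for (r in regions) {
    fc <- regional[[r]]$fc
    rr <- rarityMetrics(fc, regional[[r]]$trueUniques)
    rar[[length(rar) + 1L]] <- data.frame(
      region = r, mode = rr@mode, adjustedSingletons = rr@adjustedSingletons,
      doubletons = rr@doubletons, rareCount = rr@rareCount,
      rarityFraction = rr@rarityFraction, ratio = rr@ratio,
      stringsAsFactors = FALSE)
    abRec <- records[records$source == "abundance" & records$region == r, ]
    if (nrow(abRec)) {
      ab <- tapply(abRec$stems, normalizeSpecies(abRec$species), sum)
      fa <- tallyFrequencies(as.numeric(ab))
      ra <- withCallingHandlers(
        rarityMetrics(fa, estimateTrueUniques(fa, parse)),
        warning = function(w) {
          say("region ", r, " (abundance rarity): ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      rar[[length(rar) + 1L]] <- data.frame(
        region = r, mode = ra@mode, adjustedSingletons = ra@adjustedSingletons,
        doubletons = ra@doubletons, rareCount = ra@rareCount,
        rarityFraction = ra@rarityFraction, ratio = ra@ratio,
        stringsAsFactors = FALSE)
    }
  }
  rarity <- do.call(rbind, rar)

  # Fisher fit on pooled abundance data
  fisher <- NULL
  abRec <- records[records$source == "abundance", ]
  if (nrow(abRec)) {
    ab <- as.numeric(tapply(abRec$stems, normalizeSpecies(abRec$species), sum))
    fisher <- tryCatch(fisherAlphaFit(ab, nBoot = 0L), error = function(e) NULL)
    if (!is.null(fisher))
      attr(fisher, "sPredicted") <- fisherRichness(fisher@alpha, fisherTotal)
  }

  curveList <- NULL
  if (curves) {
    say("accumulation curves (", curveBoot, " bootstrap replicates)")
    curveList <- lapply(c(incidences, list(Global = globalInc)),
                        accumulationCurve, nBoot = curveBoot,
                        seed = seed, level = level)
  }

  partition <- NULL
  if (length(regions) >= 2) {
    say("partitioning richness over ", 2^length(regions) - 1, " subsets")
    partition <- partitionRichness(incidences, "chao2adj", level = level,
                                   parse = parse)
  }

  manifest <- list(
    package = "arbodiv",
    version = as.character(utils::packageVersion("arbodiv")),
    seed = seed,
    mode = if (synthetic) "synthetic" else "files",
    level = level, parse = parse,
    regions = regions,
    elapsedSec = round(proc.time()[["elapsed"]] - t0, 3))
  if (synthetic) manifest$worldConfig <- list(
    regions = world@regions, poolSize = world@poolSize,
    fisherAlpha = world@fisherAlpha, totalIndividuals = world@totalIndividuals,
    gridExtent = world@gridExtent, plotsPerCell = world@plotsPerCell,
    rangeClustering = world@rangeClustering, detectionProb = world@detectionProb,
    misidRate = world@misidRate, sharing = world@sharing)

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(outputDir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(rarity, file.path(outputDir, "rarity.csv"),
                     row.names = FALSE)
    if (!is.null(partition)) {
      utils::write.csv(partition@subsets,
                       file.path(outputDir, "partition_subsets.csv"),
                       row.names = FALSE)
      utils::write.csv(partition@endemics,
                       file.path(outputDir, "partition_endemics.csv"),
                       row.names = FALSE)
    }
    if (!is.null(curveList)) {
      cdf <- do.call(rbind, lapply(names(curveList), function(nm) {
        cbind(region = nm, curveList[[nm]]@points)
      }))
      utils::write.csv(cdf, file.path(outputDir, "curves.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("artifacts written to ", outputDir)
  }

  invisible(list(report = report, regional = regional, global = global,
                 rarity = rarity, partition = partition, curves = curveList,
                 fisher = fisher, records = records, world = sw,
                 misidMap = misidMap, manifest = manifest))
}

#' Format a report table for display
#'
#' Table-style presentation: integer species counts, one-decimal coverage
#' and percentage columns, all rounded half-up. The underlying report keeps
#' full precision.
#'
#' @param report the `report` data.frame from [runPipeline()].
#' @return a data.frame of formatted columns.
#' @export
formatReportTable <- function(report) {
  data.frame(
    Region = report$region,
    `Sampling units` = report$samplingUnits,
    `Species (observed)` = report$speciesObserved,
    `Sample coverage, %` = roundHalfUp(report$coveragePct, 1),
    `Chao2 (asymptotic)` = roundHalfUp(report$chao2),
    `95% CI` = sprintf("%d - %d", as.integer(roundHalfUp(report$chao2Lower)),
                       as.integer(roundHalfUp(report$chao2Upper))),
    Chao2_adj = roundHalfUp(report$chao2Adj),
    `95% CI adj` = sprintf("%d - %d", as.integer(roundHalfUp(report$adjLower)),
                           as.integer(roundHalfUp(report$adjUpper))),
    `To be discovered` = report$toBeDiscovered,
    `Share of global, %` = roundHalfUp(report$shareOfGlobalPct),
    check.names = FALSE)
}
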