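# Delimited-text interfaces: the two survey-table dialects (abundance:
# species,lat,lon,stems,plot_id,region; occurrence: species,lat,lon,region),
# a JSON ground-truth sidecar for synthetic worlds, and readers that
# normalise either table into the common records layout.

#' Write the survey tables of a record set
#'
#' Splits records by source and writes `abundance.csv` and `occurrence.csv`
#' in the standard column dialects.
#'
#' @param records combined records data.frame.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeSurveyTables <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  ab <- records[records$source == "abundance", , drop = FALSE]
  if (nrow(ab)) {
    p <- file.path(dir, "abundance.csv")
    utils::write.csv(ab[, c("species", "lat", "lon", "stems", "plot_id", "region")],
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  oc <- records[records$source == "occurrence", , drop = FALSE]
  if (nrow(oc)) {
    p <- file.path(dir, "occurrence.csv")
    utils::write.csv(oc[, c("species", "lat", "lon", "region")], p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the ground-truth sidecar of a synthetic world
#'
#' JSON with the true richness of every nonempty region subset and, when
#' supplied, the misidentification map retained by
#' [injectMisidentification()].
#'
#' @param world a [SyntheticWorld-class].
#' @param file output path.
#' @param misidMap optional data.frame (spurious, true, unit).
#' @return invisibly, `file`.
#' @export
writeGroundTruth <- function(world, file, misidMap = NULL) {
  regions <- world@config@regions
  R <- length(regions)
  masks <- seq_len(2^R - 1)
  truth <- lapply(masks, function(m) {
    lab <- regions[bitwAnd(m, 2^(seq_len(R) - 1)) > 0]
    list(regions = lab, trueRichness = trueRichness(world, lab))
  })
  payload <- list(seed = world@config@seed, subsets = truth)
  if (!is.null(misidMap)) payload$misidMap <- misidMap
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read survey tables
#'
#' `readAbundanceTable` expects columns species,lat,lon,stems,plot_id,region;
#' `readOccurrenceTable` expects species,lat,lon,region. Both return the
#' common records layout (source column set accordingly).
#'
#' @param path CSV path.
#' @return records data.frame.
#' @export
readAbundanceTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lat", "lon", "stems", "plot_id", "region")
  if (!all(need %in% names(d)))
    abdStop(paste("abundance table must have columns:", paste(need, collapse = ",")),
            "arbodiv_data_error")
  d <- d[, need]
  d$source <- "abundance"
  d
}

#' @rdname readAbundanceTable
#' @export
readOccurrenceTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lat", "lon", "region")
  if (!all(need %in% names(d)))
    abdStop(paste("occurrence table must have columns:", paste(need, collapse = ",")),
            "arbodiv_data_error")
  d <- d[, need]
  d$stems <- NA_integer_
  d$plot_id <- NA_character_
  d <- d[, c("species", "lat", "lon", "stems", "plot_id", "region")]
  d$source <- "occurrence"
  d
}
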