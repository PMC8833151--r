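# Fixtures and independent brute-force oracles shared across the suite.

# GridIncidence with prescribed incidence frequencies Y on T units:
# species i occupies Y[i] distinct cells drawn under the given seed.
incidenceFromY <- function(Y, T, seed = 1) {
  stopifnot(all(Y >= 1), all(Y <= T))
  m <- matrix(0, length(Y), T,
              dimnames = list(sprintf("sp%03d", seq_along(Y)),
                              sprintf("u%03d", seq_len(T))))
  withr::with_seed(seed, {
    for (i in seq_along(Y)) m[i, sample.int(T, Y[i])] <- 1
  })
  # ensure no empty unit (re-seat one presence deterministically)
  empty <- which(colSums(m) == 0)
  for (j in empty) {
    i <- which.max(rowSums(m))
    from <- which(m[i, ] > 0)[1]
    m[i, from] <- 0
    m[i, j] <- 1
  }
  gridIncidence(m, "toy")
}

# brute-force rarefaction: average observed richness over all t-unit subsets
exhaustiveRarefy <- function(gi, t) {
  m <- as.matrix(gi@incidence)
  T <- ncol(m)
  if (t == 0) return(0)
  subsets <- utils::combn(T, t)
  mean(apply(subsets, 2, function(ix) {
    sum(rowSums(m[, ix, drop = FALSE]) > 0)
  }))
}

# independent floor for the cell-assignment oracle
naiveFloor <- function(x) {
  tr <- trunc(x)
  ifelse(x < 0 & x != tr, tr - 1, tr)
}

# naive frequency recount oracle
naiveTally <- function(values) {
  vapply(1:4, function(k) sum(values == k), numeric(1))
}

# records data.frame shorthand
mkRecords <- function(species, lat, lon, region = "X", source = "occurrence",
                      stems = NA_integer_, plot_id = NA_character_) {
  data.frame(species = species, lat = lat, lon = lon, stems = stems,
             plot_id = plot_id, region = region, source = source,
             stringsAsFactors = FALSE)
}

# small default world used by several tests
testWorldConfig <- function(seed = 1, ...) {
  args <- list(regions = c("A", "B"), poolSize = 120, fisherAlpha = 20,
               totalIndividuals = 4000, gridExtent = 7, plotsPerCell = 1,
               detectionProb = 0.9, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(worldConfig, args)
}
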