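test_that("worldConfig validates its invariants", {
  expect_s4_class(testWorldConfig(), "WorldConfig")
  bad <- diag(2); bad[1, 2] <- 0.5            # asymmetric
  expect_error(testWorldConfig(sharing = bad), "symmetric")
  nod <- matrix(c(0.5, 0, 0, 1), 2)           # diagonal not 1
  expect_error(testWorldConfig(sharing = nod), "diagonal")
  expect_error(testWorldConfig(detectionProb = 0), "detectionProb")
  expect_error(testWorldConfig(misidRate = 1), "misidRate")
})

test_that("sharing structure controls union richness", {
  # identity sharing: fully endemic, union = sum of pools
  w <- generateWorld(testWorldConfig(poolSize = c(60, 40)))
  expect_identical(trueRichness(w), 100L)
  expect_identical(trueRichness(w, "A"), 60L)

  # full sharing of equal pools: union = single pool
  sh <- matrix(1, 2, 2)
  w2 <- generateWorld(testWorldConfig(poolSize = 50, sharing = sh))
  expect_identical(trueRichness(w2), 50L)
  expect_identical(w2@species[["A"]], w2@species[["B"]])

  # oversubscribed sharing is a configuration error
  cfg <- worldConfig(c("A", "B", "C"), poolSize = 10, fisherAlpha = 5,
                     totalIndividuals = 100, sharing = matrix(0.9, 3, 3) +
                       diag(3) * 0.1, gridExtent = 4, seed = 1)
  expect_error(generateWorld(cfg), class = "arbodiv_config_error")
})

test_that("every species occupies at least one cell and ranges are clustered", {
  w <- generateWorld(testWorldConfig())
  for (r in c("A", "B")) {
    expect_true(all(lengths(w@ranges[[r]]) >= 1))
    # range size increases with abundance weight (weak monotone via rank corr)
    sz <- lengths(w@ranges[[r]])
    expect_gt(cor(rank(w@weights[[r]]), rank(sz)), 0.7)
  }
})

test_that("mean distinct species drawn matches Fisher's equation", {
  # oracle: S_expected = alpha log(1 + n/alpha) evaluated independently
  alpha <- 50; n <- 50000
  expected <- alpha * log(1 + n / alpha)
  obs <- vapply(1:100, function(s) {
    w <- generateWorld(worldConfig("A", poolSize = 500, fisherAlpha = alpha,
                                   totalIndividuals = n, gridExtent = 8,
                                   plotsPerCell = 1, seed = s))
    rec <- sampleAbundanceSurvey(w)
    length(unique(rec$species))
  }, numeric(1))
  expect_lt(abs(mean(obs) - expected) / expected, 0.02)
})

test_that("abundance survey conserves individuals and respects ranges", {
  w <- generateWorld(testWorldConfig())
  rec <- sampleAbundanceSurvey(w)
  for (r in c("A", "B"))
    expect_identical(sum(rec$stems[rec$region == r]), 4000L)

  # plotsPerCell = 0 gives an empty record set
  w0 <- generateWorld(testWorldConfig(plotsPerCell = 0))
  expect_identical(nrow(sampleAbundanceSurvey(w0)), 0L)

  # one species, one cell: all records one species, stems conserved
  w1 <- generateWorld(worldConfig("A", poolSize = 1, fisherAlpha = 2,
                                  totalIndividuals = 100, gridExtent = 1,
                                  plotsPerCell = 3, seed = 5))
  r1 <- sampleAbundanceSurvey(w1)
  expect_identical(unique(r1$species), w1@species[["A"]])
  expect_identical(sum(r1$stems), 100L)
})

test_that("pooled abundance tallies have a long left tail (f1 > f2 > f3)", {
  ok <- vapply(1:100, function(s) {
    w <- generateWorld(worldConfig("A", poolSize = 1500, fisherAlpha = 150,
                                   totalIndividuals = 60000, gridExtent = 6,
                                   seed = s))
    rec <- sampleAbundanceSurvey(w)
    ab <- tapply(rec$stems, rec$species, sum)
    f <- naiveTally(as.numeric(ab))
    f[1] > f[2] && f[2] > f[3]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("occurrence survey detection behaves binomially", {
  # detectionProb = 1: incidence frequency equals true range size
  w <- generateWorld(testWorldConfig(detectionProb = 1))
  rec <- sampleOccurrenceSurvey(w)
  gi <- buildIncidence(rec, "A")
  Y <- incidenceFreq(gi)
  truth <- lengths(w@ranges[["A"]])
  names(truth) <- names(w@ranges[["A"]])
  expect_identical(unname(Y[names(truth)]), unname(as.numeric(truth)))

  # detectionProb = 0.5: mean detected incidence ~ half the range size
  # (oracle: binomial mean over 1000 seeded draws)
  tot <- 0; det <- 0
  for (s in 1:1000) {
    w5 <- generateWorld(worldConfig("A", poolSize = 30, fisherAlpha = 8,
                                    totalIndividuals = 500, gridExtent = 6,
                                    detectionProb = 0.5, seed = s))
    det <- det + nrow(sampleOccurrenceSurvey(w5))
    tot <- tot + sum(lengths(w5@ranges[["A"]]))
  }
  expect_lt(abs(det / tot - 0.5), 0.01)

  # all ranges of size 1 with perfect detection: Q1 = pool size, Q2 = 0
  w1 <- generateWorld(worldConfig("A", poolSize = 40, fisherAlpha = 10,
                                  totalIndividuals = 500, gridExtent = 7,
                                  rangeClustering = 1e-6, detectionProb = 1,
                                  seed = 3))
  fc <- tallyFrequencies(buildIncidence(sampleOccurrenceSurvey(w1), "A"))
  expect_identical(unname(qCounts(fc)[1:2]), c(40, 0))
})

test_that("same seed gives bit-identical surveys; seeds are stream-local", {
  cfg <- testWorldConfig(seed = 99)
  w1 <- generateWorld(cfg); w2 <- generateWorld(cfg)
  expect_identical(sampleAbundanceSurvey(w1), sampleAbundanceSurvey(w2))
  expect_identical(sampleOccurrenceSurvey(w1), sampleOccurrenceSurvey(w2))
  w3 <- generateWorld(testWorldConfig(seed = 100))
  expect_false(identical(sampleOccurrenceSurvey(w1), sampleOccurrenceSurvey(w3)))
  # drawing the abundance survey does not perturb the occurrence stream
  o1 <- sampleOccurrenceSurvey(w1)
  invisible(sampleAbundanceSurvey(w1))
  expect_identical(sampleOccurrenceSurvey(w1), o1)
})

test_that("misidentification splits duplicates into false uniques", {
  rec <- mkRecords(c("dup", "dup"), lat = c(0.5, 1.5), lon = 0.5)

  # identity at rate 0
  r0 <- injectMisidentification(rec, 0, seed = 1)
  expect_identical(r0$species, rec$species)
  expect_identical(nrow(attr(r0, "misidMap")), 0L)

  # forced split of the single duplicate: observed richness +1
  r1 <- injectMisidentification(rec, 1, seed = 1)
  expect_identical(length(unique(r1$species)), 2L)
  map <- attr(r1, "misidMap")
  expect_identical(map$true, "dup")

  expect_error(injectMisidentification(rec, -0.1), class = "arbodiv_config_error")
  expect_error(injectMisidentification(rec[0, ], 0.5), class = "arbodiv_data_error")
})

test_that("observed Q1 inflation matches the exact count from the misid map", {
  w <- generateWorld(testWorldConfig(seed = 11, detectionProb = 1))
  rec <- sampleOccurrenceSurvey(w)
  cleanQ <- qCounts(tallyFrequencies(buildIncidence(rec, "A")))
  # clean per-species unit counts, for classifying mapped species
  cleanY <- incidenceFreq(buildIncidence(rec, "A"))

  dirty <- injectMisidentification(rec, 0.3, seed = 7)
  map <- attr(dirty, "misidMap")
  dirtyQ <- qCounts(tallyFrequencies(buildIncidence(dirty, "A")))

  mapA <- map[map$true %in% names(cleanY), ]
  expectedInflation <- nrow(mapA) + sum(cleanY[mapA$true] == 2)
  expect_identical(unname(dirtyQ[1] - cleanQ[1]), as.numeric(expectedInflation))
  # and the rough rate relation: inflation ~ 2 * rate * Q2 contribution from
  # duplicates alone is a lower bound
  expect_gte(dirtyQ[1] - cleanQ[1], sum(cleanY[mapA$true] == 2))
})

test_that("richness observed never exceeds truth without misidentification", {
  for (s in 1:10) {
    w <- generateWorld(testWorldConfig(seed = s))
    rec <- rbind(sampleAbundanceSurvey(w), sampleOccurrenceSurvey(w))
    expect_lte(length(unique(rec$species)), trueRichness(w))
  }
})

test_that("higher detection weakly increases richness and coverage", {
  sLo <- cLo <- sHi <- cHi <- numeric(8)
  for (s in 1:8) {
    wL <- generateWorld(testWorldConfig(seed = s, detectionProb = 0.4))
    wH <- generateWorld(testWorldConfig(seed = s, detectionProb = 0.95))
    fL <- tallyFrequencies(buildIncidence(sampleOccurrenceSurvey(wL), "A"))
    fH <- tallyFrequencies(buildIncidence(sampleOccurrenceSurvey(wH), "A"))
    sLo[s] <- sObs(fL); sHi[s] <- sObs(fH)
    cLo[s] <- sampleCoverage(fL)@coverage
    cHi[s] <- sampleCoverage(fH)@coverage
  }
  expect_gte(mean(sHi), mean(sLo))
  expect_gte(mean(cHi), mean(cLo))
})

test_that("survey tables and ground truth round-trip through disk", {
  w <- generateWorld(testWorldConfig(seed = 2))
  rec <- rbind(sampleAbundanceSurvey(w), sampleOccurrenceSurvey(w))
  dir <- withr::local_tempdir()
  writeSurveyTables(rec, dir)
  ab <- readAbundanceTable(file.path(dir, "abundance.csv"))
  oc <- readOccurrenceTable(file.path(dir, "occurrence.csv"))
  expect_identical(sum(ab$stems), sum(rec$stems, na.rm = TRUE))
  expect_setequal(unique(oc$species),
                  unique(rec$species[rec$source == "occurrence"]))

  gt <- file.path(dir, "truth.json")
  writeGroundTruth(w, gt)
  truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  expect_identical(length(truth$subsets$trueRichness), 3L)  # 2^2 - 1 subsets
  expect_identical(max(truth$subsets$trueRichness), trueRichness(w))
})

test_that("log-series draws follow the target distribution", {
  x <- logseriesX(100, 25)                      # S = -alpha log(1-x)
  expect_equal(-25 * log1p(-x), 100, tolerance = 1e-12)
  draws <- withr::with_seed(4, rlogseries(20000, 0.9))
  expect_equal(mean(draws == 1), dlogseries(1, 0.9), tolerance = 0.02)
  expect_equal(mean(draws <= 5), plogseries(5, 0.9), tolerance = 0.02)
})
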