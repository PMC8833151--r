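# Frozen expected values below were computed with independent scripts
# (hand arithmetic on the printed formulas, standalone bisection) before the
# estimators were implemented.

test_that("sample coverage matches the Chao-Shen formula", {
  # hand oracle: n = 10, f1 = 2, f2 = 1 -> 1 - 0.2 * (18/20) = 0.82
  fc <- frequencyCounts(5, q1 = 2, q2 = 1, units = 4, total = 10)
  cov <- sampleCoverage(fc)
  expect_equal(cov@coverage, 0.82, tolerance = 1e-12)
  expect_identical(cov@deficit, 1 - cov@coverage)

  # no singletons: complete
  expect_equal(sampleCoverage(frequencyCounts(5, 0, 3, units = 4,
                                              total = 100))@coverage, 1)
  # all singletons: zero coverage
  expect_equal(sampleCoverage(frequencyCounts(5, 5, 0, units = 5,
                                              total = 5))@coverage, 0)
  # undefined without a total
  expect_error(sampleCoverage(frequencyCounts(5, 2, 1, units = 4)),
               class = "arbodiv_undefined_coverage")
})

test_that("coverage stays in [0,1] and decreases in f1", {
  prev <- 1.01
  for (f1 in 0:20) {
    C <- sampleCoverage(frequencyCounts(40, f1, 5, units = 30,
                                        total = 200))@coverage
    expect_gte(C, 0); expect_lte(C, 1)
    expect_lt(C, prev + 1e-12)
    prev <- C
  }
})

test_that("chao2 point estimate matches hand arithmetic", {
  # 5 + (9/10) * (2*1 / 4) = 5.45
  e1 <- chao2(frequencyCounts(5, 2, 1, units = 10))
  expect_equal(e1@point, 5.45, tolerance = 1e-12)
  # Q2 = 0 is guarded: 10 + 0.99 * (6/2) = 12.97
  e2 <- chao2(frequencyCounts(10, 3, 0, units = 100))
  expect_equal(e2@point, 12.97, tolerance = 1e-12)
  # no uniques, no correction
  e3 <- chao2(frequencyCounts(7, 0, 2, units = 10))
  expect_identical(e3@point, 7)
  expect_identical(c(e3@ciLower, e3@ciUpper), c(7, 7))
  # incidence-only estimator
  expect_error(chao2(tallyFrequencies(c(1, 2, 3))), class = "arbodiv_mode_error")
})

test_that("chao2 log-normal CI matches the standalone oracle", {
  # frozen from the pre-build script: Sobs=5, T=10, Q1=2, Q2=1
  est <- chao2(frequencyCounts(5, 2, 1, units = 10))
  expect_equal(est@variance, 1.411875, tolerance = 1e-10)
  expect_equal(est@K, 16.8442252597491, tolerance = 1e-10)
  expect_equal(est@ciLower, 5.02671538720604, tolerance = 1e-10)
  expect_equal(est@ciUpper, 12.5799013668871, tolerance = 1e-10)
  expect_gte(est@ciLower, est@sObs)
  expect_lte(est@ciLower, est@point)
  expect_gte(est@ciUpper, est@point)
})

test_that("chao2 is a lower-bound estimator on arbitrary tallies", {
  for (s in 1:50) {
    q <- withr::with_seed(s, stats::rpois(2, 5))
    T <- withr::with_seed(s + 100, sample(2:50, 1))
    est <- chao2(frequencyCounts(20 + sum(q), q[1], q[2], units = T))
    expect_gte(est@point, est@sObs)
    expect_gte(est@ciLower, est@sObs)
  }
})

test_that("true-uniques estimator matches hand arithmetic and falls back", {
  # frozen: T=100, Q2=30, Q3=20, Q4=10 -> 29.7 + 7.35075 = 37.05075
  fc <- frequencyCounts(200, 50, 30, 20, 10, units = 100)
  tu <- estimateTrueUniques(fc)
  expect_equal(tu$q1Hat, 37.05075, tolerance = 1e-10)
  expect_false(tu$fallback)

  # alternative exponent parse differs only in the leading factor
  tu2 <- estimateTrueUniques(fc, parse = "squared")
  expect_equal(tu2$q1Hat, 37.05075 - 29.7 + 0.99 * 29.7, tolerance = 1e-10)

  # Q3 = 0: observed Q1 returned, flagged
  tu0 <- estimateTrueUniques(frequencyCounts(100, 12, 5, 0, 2, units = 50))
  expect_identical(tu0$q1Hat, 12)
  expect_true(tu0$fallback)

  # negative intermediate clamps to zero with a warning
  expect_warning(
    tun <- estimateTrueUniques(frequencyCounts(100, 5, 1, 10, 1, units = 50)),
    "clamped")
  expect_identical(tun$q1Hat, 0)
})

test_that("adjusted Chao2 substitutes Q1-hat exactly", {
  # hand oracle: 5 + 0.9 * (1.2*0.2 / 4) = 5.054
  fc <- frequencyCounts(5, 2, 1, units = 10)
  adj <- adjustedChao2(fc, 1.2)
  expect_equal(adj@point, 5.054, tolerance = 1e-12)

  # Q1-hat below 1 contributes nothing
  expect_identical(adjustedChao2(fc, 0)@point, 5)
  expect_identical(adjustedChao2(fc, 0.6)@point, 5)

  # Q1-hat equal to observed Q1 reproduces chao2 bit for bit
  plain <- chao2(fc)
  same <- adjustedChao2(fc, 2)
  for (sl in c("point", "variance", "excess", "K", "ciLower", "ciUpper"))
    expect_identical(slot(same, sl), slot(plain, sl))

  # uncapped above observed Q1 (adjustment can raise an estimate)
  up <- adjustedChao2(fc, 5)
  expect_gt(up@point, plain@point)

  expect_error(adjustedChao2(fc, -1), class = "arbodiv_data_error")
  expect_error(adjustedChao2(tallyFrequencies(c(1, 2, 3)), 1),
               class = "arbodiv_mode_error")
})

test_that("misidentified data: adjustment moves Chao2 in the right direction", {
  w <- generateWorld(testWorldConfig(seed = 77, detectionProb = 1))
  rec <- sampleOccurrenceSurvey(w)
  dirty <- injectMisidentification(rec, 0.3, seed = 77)
  fc <- tallyFrequencies(buildIncidence(dirty, "A"))
  raw <- chao2(fc)
  adj <- adjustedChao2(fc, estimateTrueUniques(fc))
  expect_lt(adj@point, raw@point)
})

test_that("Fisher's alpha solves its defining equation", {
  for (s in 1:20) {
    ab <- withr::with_seed(s, 1 + stats::rpois(50, stats::rexp(50, 1/8)))
    fit <- fisherAlphaFit(ab, gof = FALSE)
    expect_lt(abs(fit@sObs - fit@alpha * log1p(fit@n / fit@alpha)),
              1e-6 * fit@sObs)
  }
  # frozen bisection oracle: S = 1, n = 1000
  one <- fisherAlphaFit(c(1000))
  expect_equal(one@alpha, 0.109671614569177, tolerance = 1e-9)
  # all singletons: unbounded alpha is a distinct condition
  expect_error(fisherAlphaFit(c(1, 1, 1)), class = "arbodiv_alpha_unbounded")
})

test_that("Fisher's alpha agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    ab <- withr::with_seed(s, 1 + stats::rpois(80, stats::rexp(80, 1/15)))
    expect_equal(fisherAlphaFit(ab, gof = FALSE)@alpha,
                 unname(vegan::fisher.alpha(ab)), tolerance = 1e-6)
  }
})

test_that("Fisher's richness equation behaves at its anchors", {
  # N = alpha (e - 1) collapses the log to 1
  expect_equal(fisherRichness(37, 37 * (exp(1) - 1)), 37, tolerance = 1e-12)
  # alpha -> infinity: S -> N
  N <- 1000
  expect_equal(fisherRichness(1e9 * N, N), N, tolerance = 1e-6)
  # frozen extended-precision evaluation at the published global inputs
  expect_equal(fisherRichness(3040, 3.04e12), 62998.7281473571,
               tolerance = 1e-10)
})

test_that("alpha is recovered from its own log-series draws", {
  fits <- vapply(1:20, function(s) {
    w <- generateWorld(worldConfig("A", poolSize = 500, fisherAlpha = 50,
                                   totalIndividuals = 50000, gridExtent = 8,
                                   seed = s))
    rec <- sampleAbundanceSurvey(w)
    ab <- as.numeric(tapply(rec$stems, rec$species, sum))
    fisherAlphaFit(ab, gof = FALSE)@alpha
  }, numeric(1))
  expect_lt(abs(mean(fits) - 50) / 50, 0.1)
})

test_that("bootstrap CI for alpha is ordered, positive and seeded", {
  ab <- withr::with_seed(9, 1 + stats::rpois(100, stats::rexp(100, 1/10)))
  fit <- fisherAlphaFit(ab, nBoot = 200, seed = 3)
  expect_lt(fit@ciLower, fit@ciUpper)
  expect_gt(fit@ciLower, 0)
  # resampling individuals discards species, so the replicate fits sit
  # below the point estimate on average; the interval need not bracket it
  expect_lt(fit@ciLower, fit@alpha)
  # seeded: identical on rerun
  fit2 <- fisherAlphaFit(ab, nBoot = 200, seed = 3)
  expect_identical(c(fit@ciLower, fit@ciUpper), c(fit2@ciLower, fit2@ciUpper))
})

test_that("log-series goodness of fit accepts the null and flags alternatives", {
  # null: abundances drawn from the fitted family itself
  ps <- vapply(1:30, function(s) {
    ab <- withr::with_seed(s, rlogseries(300, 0.995))
    fit <- fisherAlphaFit(as.numeric(ab), gof = TRUE)
    fit@ksP
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.10)   # conservative for discrete data

  # geometric abundances: visibly worse fit than the null on average
  dNull <- vapply(1:15, function(s) {
    ab <- as.numeric(withr::with_seed(s, rlogseries(300, 0.995)))
    logseriesGof(ab, fisherAlphaFit(ab, gof = FALSE)@alpha)$D
  }, numeric(1))
  dGeom <- vapply(1:15, function(s) {
    ab <- as.numeric(1 + withr::with_seed(s, stats::rgeom(300, 1/40)))
    logseriesGof(ab, fisherAlphaFit(ab, gof = FALSE)@alpha)$D
  }, numeric(1))
  expect_gt(mean(dGeom), mean(dNull))

  expect_error(logseriesGof(c(1, 1, 2, 2), 5), class = "arbodiv_gof_refused")
})

test_that("estimators are pure functions of the tallies", {
  fc <- frequencyCounts(120, 30, 12, 6, 3, units = 60, total = 400)
  expect_identical(chao2(fc), chao2(fc))
  expect_identical(sampleCoverage(fc)@coverage, sampleCoverage(fc)@coverage)
  expect_identical(estimateTrueUniques(fc), estimateTrueUniques(fc))
})

test_that("Chao2 sits between observed and true richness without misid", {
  pts <- sobs <- numeric(15)
  truth <- numeric(15)
  for (s in 1:15) {
    w <- generateWorld(testWorldConfig(seed = s, detectionProb = 0.5,
                                       rangeClustering = 3))
    gi <- buildIncidence(sampleOccurrenceSurvey(w), "A")
    est <- chao2(gi)
    pts[s] <- est@point; sobs[s] <- sObs(gi); truth[s] <- trueRichness(w, "A")
  }
  expect_gte(mean(pts), mean(sobs))
  expect_lte(mean(pts), mean(truth) * 1.05)
})
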