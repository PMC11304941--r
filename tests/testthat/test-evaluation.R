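mkEvents <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], homolog = r[[2]], start_bp = r[[3]],
               end_bp = r[[4]], stringsAsFactors = FALSE)
  }))
}

mkTruth <- function(...) {
  rows <- list(...)
  list(breakpoints = do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], homolog = r[[2]], bp = r[[3]],
               stringsAsFactors = FALSE)
  })))
}

test_that("event matching is per-meiosis with closed intervals", {
  tr <- mkTruth(list("a", "P", 35))
  m <- matchEvents(mkEvents(list("a", "P", 30, 40)), tr, "a")
  expect_equal(m$n_matched, 1L)
  # boundary positions count as inside
  m2 <- matchEvents(mkEvents(list("a", "P", 35, 40)), tr, "a")
  expect_equal(m2$n_matched, 1L)
  # same individual, other homolog: no match
  m3 <- matchEvents(mkEvents(list("a", "M", 30, 40)), tr, "a")
  expect_equal(m3$n_matched, 0L)
  expect_equal(m3$n_true, 1L)
  # one event containing two breakpoints counts once, both stay in n_true
  tr2 <- mkTruth(list("a", "P", 32), list("a", "P", 38))
  m4 <- matchEvents(mkEvents(list("a", "P", 30, 40)), tr2, "a")
  expect_equal(m4$n_matched, 1L)
  expect_equal(m4$n_true, 2L)
  # events outside the evaluation scope are an error
  expect_error(matchEvents(mkEvents(list("b", "P", 1, 2)), tr, "a"), "scope")
})

test_that("precision, recall and F1 follow their formulas", {
  prf <- precisionRecallF1(2, 2, 3)
  expect_equal(unname(prf), c(1, 2 / 3, 0.8))
  expect_equal(unname(precisionRecallF1(0, 5, 3)), c(0, 0, 0))
  # harmonic-mean identity when precision equals recall
  prf2 <- precisionRecallF1(3, 4, 4)
  expect_equal(prf2[["f1"]], prf2[["precision"]])
  expect_equal(unname(precisionRecallF1(0, 0, 0)), c(0, 0, 0))
  expect_error(precisionRecallF1(5, 4, 6), "exceeds")
})

test_that("resolution is the inverse median interval count", {
  r <- adjustedResolution(0.8, c(4, 4, 4))
  expect_equal(unname(r), c(0.25, 0.2))
  expect_equal(adjustedResolution(1, c(1, 1))[["resolution"]], 1)
  expect_equal(adjustedResolution(0.5, c(2, 4, 6))[["resolution"]], 0.25)
  expect_true(is.na(adjustedResolution(1, integer(0))[["resolution"]]))
})

test_that("filtered percentage compares against the raw run", {
  expect_equal(pctFiltered(100, 40), 60)
  expect_equal(pctFiltered(10, 10), 0)
  expect_equal(pctFiltered(10, 0), 100)
  expect_true(is.na(pctFiltered(0, 0)))
})

test_that("Mendelian-error rates count trio violations per scope", {
  # 2 founders, 1 child, 10 loci; one violating locus
  ped <- data.frame(id = c("F1", "F2", "K"), father = c(NA, NA, "F1"),
                    mother = c(NA, NA, "F2"), stringsAsFactors = FALSE)
  a1 <- rbind(F1 = rep(1L, 10), F2 = rep(1L, 10), K = rep(1L, 10))
  a2 <- a1
  a1["K", 4] <- 1L; a2["K", 4] <- 2L  # het child of two 1/1 parents
  g <- magicGeno(ped, a1, a2, mkMap(10))
  expect_equal(meRate(g, "global"), 0.1)
  pm <- meRate(g, "per-marker")
  expect_equal(pm[4], 1)
  expect_equal(sum(pm), 1)
  pg <- meRate(g, "per-generation")
  expect_equal(unname(pg["1"]), 0.1)
  # missing genotypes drop out of the denominator
  a1["K", 10] <- 0L; a2["K", 10] <- 0L
  g2 <- magicGeno(ped, a1, a2, mkMap(10))
  expect_equal(meRate(g2, "global"), 1 / 9)
})

test_that("marker filtering drops only rates strictly above the threshold", {
  # 10 children so per-marker rates are multiples of 0.1
  ids <- c("F1", "F2", paste0("K", 1:10))
  ped <- data.frame(id = ids,
                    father = c(NA, NA, rep("F1", 10)),
                    mother = c(NA, NA, rep("F2", 10)),
                    stringsAsFactors = FALSE)
  a1 <- matrix(1L, 12, 5, dimnames = list(ids, NULL))
  a2 <- a1
  a2[paste0("K", 1:2), 2] <- 2L  # marker 2: 20% ME rate
  a2["K1", 3] <- 2L              # marker 3: exactly 10%
  g <- magicGeno(ped, a1, a2, mkMap(5))
  out <- filterMarkersByMe(g, 0.10)
  expect_equal(markerMap(out)$marker, mkMap(5)$marker[-2])
  # error-free markers all retained
  expect_identical(filterMarkersByMe(magicGeno(ped, a1, a1, mkMap(5))),
                   magicGeno(ped, a1, a1, mkMap(5)))
  a2k <- a1; a2k[paste0("K", 1:5), ] <- 2L
  expect_error(filterMarkersByMe(magicGeno(ped, a1, a2k, mkMap(5))), "all markers")
})

test_that("crossover map distributes each event across its gap and conserves weight", {
  map <- mkMap(6)
  ev <- data.frame(start_idx = c(1L, 2L), end_idx = c(2L, 6L))
  cm <- coCountMap(ev, map)
  expect_equal(nrow(cm), 5L)
  expect_equal(cm$count, c(1, 0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(cm$count), nrow(ev))
  # conservation on simulated data
  sim <- simulatePopulation(seed = 21, depth = 3, nLoci = 150)
  res <- phasePopulation(sim$geno, magicConfig(2, "imputeTHonly"))
  cm2 <- coCountMap(events(res), markerMap(res))
  expect_equal(sum(cm2$count), nrow(events(res)))
})

test_that("GE/ME calibration is linear, invertible and anchored near zero", {
  cal <- calibrateGeFromMe(c(0, 0.02, 0.05, 0.08, 0.12), nReps = 2, seed = 31,
                           simArgs = list(depth = 3, nLoci = 150))
  expect_s4_class(cal, "CalibrationCurve")
  expect_gt(cal@slope, 0)
  expect_lt(abs(cal@intercept), 0.01)  # no errors, (almost) no MEs
  # round trip through the fitted line is exact
  ge <- c(0.01, 0.05, 0.1)
  expect_equal(invertCalibration(cal, cal@slope * ge + cal@intercept), ge)
  # measured MEs invert back near the generating rates
  me <- vapply(split(cal@grid$me, cal@grid$ge), mean, 0)
  back <- invertCalibration(cal, me)
  expect_lt(max(abs(back - c(0, 0.02, 0.05, 0.08, 0.12))), 0.012)
  expect_error(calibrateGeFromMe(c(0.1, 0.1, 0.1)), "degenerate|3 rates")
  expect_error(calibrateGeFromMe(c(0.1, 0.2)), "3 rates")
})
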