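test_that("window maxima use first occurrence and the protocol windows", {
  # single spike at t = 70 s: peak 4.23, 50 s after the stimulus
  fold <- rep(1, 501); fold[71] <- 4.23
  m <- cellMetrics(tsFromFold(fold))
  expect_equal(m$max_rmr_fold, 4.23)
  expect_equal(m$time_to_max_rmr, 50)

  # equal maxima at t = 60 and t = 80: first occurrence wins
  tie <- rep(1, 501); tie[c(61, 81)] <- 3
  expect_equal(cellMetrics(tsFromFold(tie))$time_to_max_rmr, 40)

  # ionomycin window: peak 3.89 at t = 250 is 50 s after ionomycin
  io <- rep(1, 501); io[251] <- 3.89
  mi <- cellMetrics(tsFromFold(io))
  expect_equal(mi$max_iono_fold, 3.89)
  expect_equal(mi$time_to_max_iono, 50)

  # flat after ionomycin: max 1 at the window's first frame
  flat <- rep(1, 501)
  mf <- cellMetrics(tsFromFold(flat))
  expect_equal(mf$max_iono_fold, 1)
  expect_equal(mf$time_to_max_iono, 0)
})

test_that("a noise-free alpha pulse closes the generate-extract loop", {
  preset <- noiselessPreset(nCells = 1L)
  ts <- generateTrace(KineticShape(2.55, 15.57), preset)
  m <- cellMetrics(normalizeTraces(subtractBackground(ts)))
  expect_equal(m$max_rmr_fold, 2.55, tolerance = 1e-6)
  expect_lte(abs(m$time_to_max_rmr - 15.57), 1)
})

test_that("responder classification is a boundary-inclusive threshold", {
  expect_true(classifyResponders(2.0))
  expect_false(classifyResponders(1.9999))
  expect_equal(classifyResponders(c(1.2, 2.5, 2.0), threshold = 2),
               c(FALSE, TRUE, TRUE))
})

test_that("metrics confine themselves to their windows", {
  fold <- rep(1, 501)
  fold[61] <- 3          # RMR peak at t = 60
  fold[251] <- 4         # ionomycin peak at t = 250
  m0 <- cellMetrics(tsFromFold(fold))
  # perturbing the ionomycin and EGTA windows leaves RMR metrics unchanged
  pert <- fold; pert[300] <- 9; pert[450] <- 9
  m1 <- cellMetrics(tsFromFold(pert))
  expect_equal(m1$max_rmr_fold, m0$max_rmr_fold)
  expect_equal(m1$time_to_max_rmr, m0$time_to_max_rmr)
  # and perturbing the RMR window leaves ionomycin metrics unchanged
  pert2 <- fold; pert2[100] <- 9
  m2 <- cellMetrics(tsFromFold(pert2))
  expect_equal(m2$max_iono_fold, m0$max_iono_fold)
  expect_equal(m2$time_to_max_iono, m0$time_to_max_iono)
})

test_that("delaying a pulse shifts the time-to-max equivariantly", {
  preset <- noiselessPreset(nCells = 1L)
  base <- cellMetrics(normalizeTraces(subtractBackground(
    generateTrace(KineticShape(3, 40), preset))))
  for (k in c(5, 17, 60)) {
    shifted <- cellMetrics(normalizeTraces(subtractBackground(
      generateTrace(KineticShape(3, 40 + k), preset))))
    expect_equal(shifted$time_to_max_rmr - base$time_to_max_rmr, k)
  }
})

test_that("responder fraction is non-increasing in the threshold", {
  preset <- CohortPreset("ASD", "Diff4wk", "KCl", muPeak = 3.3, muTtp = 14,
                         responderFrac = 0.86, nCellsPerReplicate = 25L)
  m <- extractMetrics(generateCohort(preset, seed = 9))
  fr <- vapply(seq(1.2, 4, by = 0.2), function(th)
    mean(classifyResponders(m$max_rmr_fold, th)), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("summaries pool cells and report replicate-level doubling", {
  # three replicates with known responder fractions 50%, 57%, 65%
  mk <- function(rep, frac, n = 100) {
    data.frame(cell_id = sprintf("%s_c%d", rep, 1:n), line_id = "ASD1",
               group = "ASD", stage = "Diff1wk", replicate_id = rep,
               stimulus = "KCl",
               max_rmr_fold = c(rep(2.5, round(frac * n)),
                                rep(1.5, n - round(frac * n))),
               time_to_max_rmr = 20, max_iono_fold = 3,
               time_to_max_iono = 40,
               responder = c(rep(TRUE, round(frac * n)),
                             rep(FALSE, n - round(frac * n))))
  }
  m <- rbind(mk("r1", 0.50), mk("r2", 0.57), mk("r3", 0.65))
  s <- summarizeCells(m)
  pd <- s[s$metric == "pct_doubling", ]
  expect_equal(pd$mean, mean(c(50, 57, 65)), tolerance = 1e-12)
  expect_equal(pd$sem, sd(c(50, 57, 65)) / sqrt(3), tolerance = 1e-12)
  expect_equal(pd$n, 3)

  # identical cells give zero SEM (single replicate, so doubling SEM warns)
  s2 <- suppressWarnings(summarizeCells(mk("r1", 1)))
  expect_equal(s2$sem[s2$metric == "max_rmr_fold"], 0)

  # balanced pooling: the pooled mean is the average of the line means
  a <- mk("r1", 0.5); a$max_rmr_fold <- 2
  b <- mk("r1", 0.5); b$line_id <- "ASD2"; b$max_rmr_fold <- 4
  s3 <- summarizeCells(rbind(a, b))
  expect_equal(s3$mean[s3$metric == "max_rmr_fold"], 3)

  # a single replicate leaves the replicate-level SEM undefined
  expect_warning(s4 <- summarizeCells(mk("r1", 0.5)), "single replicate")
  expect_true(is.na(s4$sem[s4$metric == "pct_doubling"]))
})

test_that("the optional rise slope reflects the rise steepness", {
  preset <- noiselessPreset(nCells = 1L)
  cfg <- AnalysisConfig(includeRiseSlope = TRUE)
  fast <- cellMetrics(normalizeTraces(subtractBackground(
    generateTrace(KineticShape(3, 10), preset))), cfg)
  slow <- cellMetrics(normalizeTraces(subtractBackground(
    generateTrace(KineticShape(3, 120), preset))), cfg)
  expect_gt(fast$rise_slope_rmr, slow$rise_slope_rmr)
  expect_gt(slow$rise_slope_rmr, 0)
})
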