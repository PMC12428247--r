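makeRawTs <- function(raw, background = NULL, protocol = StimulusProtocol()) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  cd <- data.frame(cell_id = paste0("c", seq_len(nrow(raw))),
                   line_id = "ASD1", group = "ASD", stage = "iPSC",
                   replicate_id = "r1")
  if (!is.null(background)) cd$background <- background
  TraceSet(raw, cd, protocol,
           times = protocolTimes(protocol)[seq_len(ncol(raw))])
}

test_that("background subtraction clips at zero and records its method", {
  ts <- makeRawTs(rep(1050, 501), background = 50)
  out <- subtractBackground(ts)
  expect_equal(unname(intensities(out)[1, ]), rep(1000, 501))
  expect_equal(metadata(out)$background_method, "column")

  ts2 <- makeRawTs(rep(1050, 501))
  out2 <- subtractBackground(ts2, method = "scalar", value = 50)
  expect_equal(unname(intensities(out2)[1, ]), rep(1000, 501))
  expect_equal(metadata(out2)$background_method, "scalar")

  # a carried background column wins over a scalar argument
  expect_warning(out3 <- subtractBackground(ts, method = "scalar", value = 999),
                 "takes precedence")
  expect_equal(unname(intensities(out3)[1, 1]), 1000)

  # background at or above the whole trace is degenerate
  expect_error(subtractBackground(makeRawTs(rep(40, 501), background = 50)),
               "degenerate")
})

test_that("rolling-percentile background tracks a known offset", {
  set.seed(1)
  raw <- 200 + c(rep(0, 100), rep(3000, 50), rep(0, 351))
  out <- subtractBackground(makeRawTs(raw), method = "rolling")
  # flat segments are fully explained by the rolling baseline
  expect_lt(max(abs(intensities(out)[1, 1:80])), 1e-9)
  expect_equal(max(intensities(out)[1, ]), 3000, tolerance = 1e-9)
})

test_that("normalization divides by the mean of the first baseline frames", {
  raw <- c(1000, 1000, 1000, rep(1000, 17), rep(4000, 481))
  nt <- normalizeTraces(makeRawTs(raw))
  expect_equal(unname(rowData(nt)$f0), 1000)
  expect_equal(unname(folds(nt)[1, c(1, 30)]), c(1, 4))

  cst <- normalizeTraces(makeRawTs(rep(777, 501)))
  expect_equal(unname(folds(cst)[1, ]), rep(1, 501), tolerance = 1e-12)

  expect_error(normalizeTraces(makeRawTs(rep(0, 501))), "F0 <= 0")
  # a recording that starts at t = 18 s has only two pre-stimulus frames
  cd <- data.frame(cell_id = "c1", line_id = "ASD1", group = "ASD",
                   stage = "iPSC", replicate_id = "r1")
  late <- TraceSet(matrix(1000, 1, 483), cd, StimulusProtocol(),
                   times = 18:500)
  expect_error(normalizeTraces(late), "pre-stimulus frames")
})

test_that("baseline anchors agree on flat baselines and differ on drifts", {
  flat <- makeRawTs(c(rep(1000, 20), rep(3000, 481)))
  a <- normalizeTraces(flat, anchor = "first")
  b <- normalizeTraces(flat, anchor = "prestimulus")
  expect_equal(rowData(a)$f0, rowData(b)$f0)

  drift <- makeRawTs(c(seq(1000, 1190, by = 10), rep(3000, 481)))
  a2 <- normalizeTraces(drift, anchor = "first")
  b2 <- normalizeTraces(drift, anchor = "prestimulus")
  expect_equal(unname(rowData(a2)$f0), 1010)   # frames at t = 0, 1, 2
  expect_equal(unname(rowData(b2)$f0), 1180)   # frames at t = 17, 18, 19
})

test_that("normalized baselines average exactly one and are scale invariant", {
  preset <- CohortPreset("ASD", "iPSC", "ATP", muPeak = 4.23, muTtp = 80,
                         nCellsPerReplicate = 10L)
  ts <- generateCohort(preset, seed = 2)
  nt <- normalizeTraces(subtractBackground(ts))
  base <- rowMeans(folds(nt)[, 1:3])
  expect_equal(base, setNames(rep(1, nrow(nt)), rownames(nt)),
               tolerance = 1e-12)

  # scaling raw intensities leaves fold unchanged
  sub <- subtractBackground(ts)
  scaled <- sub
  assay(scaled, "intensity") <- intensities(sub) * 3.7
  expect_equal(folds(normalizeTraces(scaled)), folds(normalizeTraces(sub)),
               tolerance = 1e-12)

  # adding a common offset to raw and background commutes with subtraction
  shifted <- makeRawTs(c(rep(1050, 20), rep(4050, 481)) + 111,
                       background = 50 + 111)
  plain <- makeRawTs(c(rep(1050, 20), rep(4050, 481)), background = 50)
  expect_equal(folds(normalizeTraces(subtractBackground(shifted))),
               folds(normalizeTraces(subtractBackground(plain))),
               tolerance = 1e-12)
})

test_that("ROI extraction recovers single pixels and flags empty masks", {
  dir <- withr::local_tempdir()
  p <- StimulusProtocol(tEnd = 9, tStimulus = 3, tIonomycin = 5, tEgta = 7,
                        nBaselineFrames = 2L)
  vals <- matrix(0L, nrow = 4, ncol = 4)
  frames <- lapply(1:10, function(j) {
    fr <- vals; fr[2, 2] <- 100L * j; fr / 65535
  })
  stack <- file.path(dir, "s.tif"); mask <- file.path(dir, "m.tif")
  tiff::writeTIFF(frames, stack, bits.per.sample = 16)

  onePix <- vals; onePix[2, 2] <- 1L
  tiff::writeTIFF(onePix / 65535, mask, bits.per.sample = 16)
  rt <- extractRoiTraces(stack, mask, p)
  expect_equal(unname(intensities(rt)[1, ]), 100 * (1:10))

  # labels with no pixels are skipped with a warning
  gappy <- vals; gappy[2, 2] <- 1L; gappy[3, 3] <- 3L
  tiff::writeTIFF(gappy / 65535, mask, bits.per.sample = 16)
  expect_warning(rt2 <- extractRoiTraces(stack, mask, p), "label 2")
  expect_equal(nrow(rt2), 2)

  tiff::writeTIFF(vals / 65535, mask, bits.per.sample = 16)
  expect_warning(rt3 <- extractRoiTraces(stack, mask, p), "no labels")
  expect_equal(nrow(rt3), 0)

  big <- matrix(0L, nrow = 6, ncol = 6)
  tiff::writeTIFF(big / 65535, mask, bits.per.sample = 16)
  expect_error(extractRoiTraces(stack, mask, p), "dimensions differ")
})
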