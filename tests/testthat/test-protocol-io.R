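test_that("protocol validity enforces event ordering and baseline fit", {
  p <- StimulusProtocol()
  expect_equal(c(p@tStimulus, p@tIonomycin, p@tEgta, p@tEnd,
                 p@frameInterval, as.numeric(p@nBaselineFrames)),
               c(20, 200, 400, 500, 1, 3))
  expect_error(StimulusProtocol(tIonomycin = 10), "tStimulus < tIonomycin")
  expect_error(StimulusProtocol(tEgta = 600), "tEgta <= tEnd")
  expect_error(StimulusProtocol(nBaselineFrames = 30), "before the stimulus")
  expect_error(StimulusProtocol(frameInterval = 0), "frameInterval")
  expect_error(StimulusProtocol(stimulusName = "NMDA"), "stimulusName")
})

test_that("trace CSV parses into one trace per cell", {
  p <- StimulusProtocol()
  tm <- 0:249
  df <- data.frame(cell_id = rep(c("a", "b"), each = 250),
                   line_id = "ASD1", group = "ASD", stage = "iPSC",
                   replicate_id = "r1", time_s = rep(tm, 2),
                   intensity = c(1000 + tm, 2000 + tm))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ts <- readTraces(path, p)
  expect_s4_class(ts, "TraceSet")
  expect_equal(dim(ts), c(2L, 250L))
  expect_equal(unname(intensities(ts)[2, 1:3]), c(2000, 2001, 2002))
})

test_that("malformed trace CSVs are rejected", {
  p <- StimulusProtocol()
  path <- withr::local_tempfile(fileext = ".csv")
  base <- data.frame(cell_id = "a", line_id = "L", group = "ASD",
                     stage = "iPSC", replicate_id = "r1",
                     time_s = 0:99, intensity = 1000)

  write.csv(base[, setdiff(colnames(base), "intensity")], path,
            row.names = FALSE)
  expect_error(readTraces(path, p), "missing required columns")

  gap <- base[-c(50, 51), ]
  write.csv(gap, path, row.names = FALSE)
  expect_error(readTraces(path, p), "gap")

  shuffled <- base[c(2, 1, 3:100), ]
  write.csv(shuffled, path, row.names = FALSE)
  expect_error(readTraces(path, p), "strictly increasing")

  writeLines("cell_id,line_id,group,stage,replicate_id,time_s,intensity", path)
  expect_error(readTraces(path, p), "empty")

  off <- base
  off$time_s <- off$time_s + 450   # frames run past the end of the grid
  write.csv(off, path, row.names = FALSE)
  expect_error(readTraces(path, p), "grid")
})

test_that("write/read round trip preserves a generated cohort exactly", {
  preset <- CohortPreset("ASD", "iPSC", "ATP", muPeak = 3, muTtp = 40,
                         nCellsPerReplicate = 3L, nReplicates = 1L,
                         nLines = 2L)
  ts <- generateCohort(preset, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTraces(ts, path)
  back <- readTraces(path, protocol(ts))
  expect_equal(unname(intensities(back)), unname(intensities(ts)),
               tolerance = 1e-12)
  expect_equal(rowData(back)$background, rowData(ts)$background)
  expect_equal(rowData(back)$cell_id, rowData(ts)$cell_id)
})

test_that("identical seeds give byte-identical trace CSVs", {
  preset <- CohortPreset("ASD", "iPSC", "ATP", muPeak = 3, muTtp = 40,
                         nCellsPerReplicate = 2L, nReplicates = 1L,
                         nLines = 1L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeTraces(generateCohort(preset, seed = 7), p1)
  writeTraces(generateCohort(preset, seed = 7), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("reports carry two summary rows and one test row per comparison", {
  preset <- CohortPreset("ASD", "Diff1wk", "KCl", muPeak = 2.6, muTtp = 16,
                         responderFrac = 0.6, nCellsPerReplicate = 10L)
  ctl <- CohortPreset("control", "Diff1wk", "KCl", muPeak = 2.2, muTtp = 37,
                      responderFrac = 0.45, nCellsPerReplicate = 10L)
  m <- rbind(extractMetrics(generateCohort(preset, seed = 1)),
             extractMetrics(generateCohort(ctl, seed = 2)))
  cmp <- compareConditions(m)
  prefix <- file.path(withr::local_tempdir(), "report")
  paths <- writeReport(cmp, prefix, seeds = list(asd = 1, control = 2))
  rep <- readReport(prefix)
  expect_equal(nrow(rep$summary), 2 * nrow(cmp))
  expect_equal(nrow(rep$tests), nrow(cmp))
  expect_equal(rep$tests$p_two_tailed, cmp$p_two_tailed, tolerance = 1e-9)
  expect_equal(rep$tests$U, cmp$U, tolerance = 1e-9)
  expect_equal(sort(unique(rep$summary$group)), c("ASD", "control"))
  expect_equal(rep$meta$seeds$asd, 1)
})

test_that("an empty comparison table cannot be written", {
  expect_error(writeReport(data.frame(), withr::local_tempfile()), "no comparison")
})

test_that("protocol and analysis configs load from YAML", {
  dir <- withr::local_tempdir()
  pPath <- file.path(dir, "protocol.yaml")
  writeLines(c("frame_interval: 0.5", "t_stimulus: 10", "t_ionomycin: 100",
               "t_egta: 200", "t_end: 250", "stimulus_name: KCl"), pPath)
  p <- readProtocol(pPath)
  expect_equal(p@frameInterval, 0.5)
  expect_equal(p@stimulusName, "KCl")
  aPath <- file.path(dir, "analysis.yaml")
  writeLines(c("doubling_threshold: 1.8", "test_unit: replicate"), aPath)
  a <- readAnalysisConfig(aPath)
  expect_equal(a@doublingThreshold, 1.8)
  expect_equal(a@testUnit, "replicate")
  expect_equal(a@baselineAnchor, "first")
})
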