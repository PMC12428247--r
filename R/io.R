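TRACE_COLUMNS <- c("cell_id", "line_id", "group", "stage", "replicate_id",
                   "time_s", "intensity")

#' Read per-cell traces from a long CSV
#'
#' The on-disk format is long/tidy: one row per frame per cell with columns
#' `cell_id, line_id, group, stage, replicate_id, time_s, intensity` and an
#' optional `background` column (scalar per cell or per frame). Times are
#' seconds with `.` as decimal separator. Each cell's frame times must be
#' strictly increasing, gap-free (no step larger than 1.5 x the protocol
#' frame interval) and must land on the protocol grid within half a frame
#' interval; all cells must share one grid.
#'
#' @param path CSV file path.
#' @param protocol the [StimulusProtocol-class] the recording follows.
#' @return a [TraceSet-class].
#' @export
readTraces <- function(path, protocol = StimulusProtocol()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("trace file is empty: ", path)
  miss <- setdiff(TRACE_COLUMNS, colnames(df))
  if (length(miss))
    stop("trace file is missing required columns: ", paste(miss, collapse = ", "))
  hasBg <- "background" %in% colnames(df)

  dt <- protocol@frameInterval
  cells <- unique(df$cell_id)
  tm <- df$time_s[df$cell_id == cells[1]]
  steps <- diff(tm)
  if (any(steps <= 0))
    stop("frame times are not strictly increasing within cell ", cells[1])
  if (any(steps > 1.5 * dt))
    stop("time gap larger than 1.5 x frame interval within cell ", cells[1])
  grid <- protocolTimes(protocol)
  near <- round(tm / dt) + 1
  if (any(near < 1 | near > length(grid)) ||
      any(abs(tm - grid[near]) > dt / 2))
    stop("frame times do not match the protocol grid within frameInterval/2")

  nT <- length(tm)
  mat <- matrix(NA_real_, nrow = length(cells), ncol = nT)
  bg <- if (hasBg) matrix(NA_real_, nrow = length(cells), ncol = nT) else NULL
  meta <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    sub <- df[df$cell_id == cells[i], , drop = FALSE]
    if (nrow(sub) != nT)
      stop("cell ", cells[i], " has ", nrow(sub), " frames; expected ", nT)
    ti <- sub$time_s
    if (any(diff(ti) <= 0))
      stop("frame times are not strictly increasing within cell ", cells[i])
    if (any(diff(ti) > 1.5 * dt))
      stop("time gap larger than 1.5 x frame interval within cell ", cells[i])
    if (max(abs(ti - tm)) > dt / 2)
      stop("cells do not share a common frame grid")
    mat[i, ] <- sub$intensity
    if (hasBg) bg[i, ] <- sub$background
    meta[[i]] <- sub[1, c("cell_id", "line_id", "group", "stage", "replicate_id")]
  }
  cd <- do.call(rbind, meta)
  if (hasBg) {
    perCellConst <- apply(bg, 1, function(v) diff(range(v)) == 0)
    if (all(perCellConst)) {
      cd$background <- bg[, 1]
      bg <- NULL
    }
  }
  ts <- TraceSet(mat, cd, protocol, times = tm)
  if (hasBg && !is.null(bg)) assay(ts, "background") <- bg
  ts
}

#' Write a TraceSet to the long CSV format
#'
#' Inverse of [readTraces()]; the round trip preserves intensities exactly
#' (values are written with full precision).
#'
#' @param x a [TraceSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(x, path) {
  rd <- rowData(x)
  tm <- traceTimes(x)
  nT <- length(tm)
  idx <- rep(seq_len(nrow(x)), each = nT)
  df <- data.frame(
    cell_id = rd$cell_id[idx],
    line_id = rd$line_id[idx],
    group = rd$group[idx],
    stage = rd$stage[idx],
    replicate_id = rd$replicate_id[idx],
    time_s = rep(tm, nrow(x)),
    intensity = as.vector(t(intensities(x))))
  if ("background" %in% assayNames(x)) {
    df$background <- as.vector(t(assay(x, "background")))
  } else if ("background" %in% colnames(rd)) {
    df$background <- rd$background[idx]
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a comparison report
#'
#' Writes three files under a common prefix: `<prefix>_summary.csv` with one
#' tidy row per (stage, stimulus, metric, group) carrying mean, SEM and n;
#' `<prefix>_tests.csv` with one row per comparison carrying the Mann-Whitney
#' U and two-tailed p; and `<prefix>_meta.json` recording the analysis
#' configuration and seed.
#'
#' @param comparisons a data.frame from [compareConditions()].
#' @param prefix output path prefix (directories must exist).
#' @param config the [AnalysisConfig-class] used.
#' @param seeds named list/vector of RNG seeds to record.
#' @return named character vector of the written paths, invisibly.
#' @export
writeReport <- function(comparisons, prefix, config = AnalysisConfig(),
                        seeds = NULL) {
  if (is.null(comparisons) || nrow(comparisons) == 0)
    stop("no comparison results to report")
  long <- do.call(rbind, lapply(c("ASD", "control"), function(g) {
    data.frame(stage = comparisons$stage, stimulus = comparisons$stimulus,
               metric = comparisons$metric, group = g,
               mean = comparisons[[paste0("mean_", g)]],
               sem = comparisons[[paste0("sem_", g)]],
               n = comparisons[[paste0("n_", g)]])
  }))
  long <- long[order(long$stage, long$stimulus, long$metric, long$group), ]
  tests <- comparisons[, c("stage", "stimulus", "metric", "U", "p_two_tailed",
                           "n_ASD", "n_control", "test_unit")]
  paths <- c(summary = paste0(prefix, "_summary.csv"),
             tests = paste0(prefix, "_tests.csv"),
             meta = paste0(prefix, "_meta.json"))
  utils::write.csv(format(long, digits = 17, trim = TRUE), paths["summary"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format(tests, digits = 17, trim = TRUE), paths["tests"],
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    config = list(doubling_threshold = config@doublingThreshold,
                  amplitude_sem_unit = config@amplitudeSemUnit,
                  fraction_sem_unit = config@fractionSemUnit,
                  test_unit = config@testUnit,
                  baseline_anchor = config@baselineAnchor),
    seeds = seeds)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' @rdname writeReport
#' @return `readReport` returns `list(summary, tests, meta)`.
#' @export
readReport <- function(prefix) {
  list(summary = utils::read.csv(paste0(prefix, "_summary.csv")),
       tests = utils::read.csv(paste0(prefix, "_tests.csv")),
       meta = jsonlite::read_json(paste0(prefix, "_meta.json")))
}
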