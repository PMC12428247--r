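# First-occurrence window maximum for each row of a fold matrix.
windowPeak <- function(foldMat, times, idx, tEvent) {
  if (length(idx) == 0) stop("response window contains no frames")
  sub <- foldMat[, idx, drop = FALSE]
  j <- apply(sub, 1, which.max)       # which.max returns the first maximum
  data.frame(max_fold = sub[cbind(seq_len(nrow(sub)), j)],
             time_to_max = times[idx][j] - tEvent)
}

#' Per-cell receptor-mediated response maximum
#'
#' Maximum fold over the RMR window `[tStimulus, tIonomycin)` and the time
#' from stimulus delivery to that maximum (first occurrence on ties).
#'
#' @param x a normalized [TraceSet-class].
#' @return data.frame with `cell_id`, `max_fold`, `time_to_max` (s).
#' @export
rmrPeak <- function(x) {
  p <- protocol(x)
  w <- protocolWindows(p, traceTimes(x))
  out <- windowPeak(folds(x), traceTimes(x), w$rmr, p@tStimulus)
  cbind(cell_id = rowData(x)$cell_id, out)
}

#' Per-cell ionomycin response maximum
#'
#' As [rmrPeak()] over the ionomycin window `[tIonomycin, tEgta)`, with time
#' measured from ionomycin addition.
#'
#' @param x a normalized [TraceSet-class].
#' @return data.frame with `cell_id`, `max_fold`, `time_to_max` (s).
#' @export
ionomycinPeak <- function(x) {
  p <- protocol(x)
  w <- protocolWindows(p, traceTimes(x))
  out <- windowPeak(folds(x), traceTimes(x), w$iono, p@tIonomycin)
  cbind(cell_id = rowData(x)$cell_id, out)
}

#' Classify responder cells
#'
#' A cell is a responder when its maximum RMR fold reaches at least the
#' doubling threshold; the boundary value itself counts as a responder.
#'
#' @param maxRmrFold numeric vector of per-cell maximum RMR folds (or a
#'   [cellMetrics()] data.frame with a `max_rmr_fold` column).
#' @param threshold fold threshold (default 2).
#' @return logical vector.
#' @export
classifyResponders <- function(maxRmrFold, threshold = 2.0) {
  if (is.data.frame(maxRmrFold)) maxRmrFold <- maxRmrFold$max_rmr_fold
  maxRmrFold >= threshold
}

# 10-90% rise slope (fold/s) from window start to the window maximum;
# frame-level threshold crossings, NA when the rise spans a single frame.
riseSlope <- function(fold, times, idx, jmax) {
  seg <- fold[idx[seq_len(jmax)]]
  tseg <- times[idx[seq_len(jmax)]]
  mx <- seg[jmax]
  if (mx <= 1) return(NA_real_)
  f10 <- 1 + 0.1 * (mx - 1)
  f90 <- 1 + 0.9 * (mx - 1)
  i10 <- which(seg >= f10)[1]
  i90 <- which(seg >= f90)[1]
  if (is.na(i10) || is.na(i90) || i90 == i10) return(NA_real_)
  (seg[i90] - seg[i10]) / (tseg[i90] - tseg[i10])
}

#' Per-cell kinetic features
#'
#' Computes, for every cell of a normalized `TraceSet`, the maximum RMR fold
#' and its time from stimulus delivery, the maximum ionomycin fold and its
#' time from ionomycin addition, and the responder flag at the doubling
#' threshold. With `includeRiseSlope` the 10-90% RMR rise slope (fold/s) is
#' added as a secondary metric.
#'
#' @param x a normalized [TraceSet-class].
#' @param config an [AnalysisConfig-class].
#' @return data.frame with one row per cell: identifiers, `stimulus`,
#'   `max_rmr_fold`, `time_to_max_rmr`, `max_iono_fold`, `time_to_max_iono`,
#'   `responder` (and optionally `rise_slope_rmr`).
#' @examples
#' ts <- generateCohort(studyPresets()[["iPSC.ATP.ASD"]], seed = 1)
#' m <- cellMetrics(normalizeTraces(subtractBackground(ts)))
#' mean(m$max_rmr_fold)
#' @export
cellMetrics <- function(x, config = AnalysisConfig()) {
  p <- protocol(x)
  tm <- traceTimes(x)
  w <- protocolWindows(p, tm)
  fm <- folds(x)
  rmr <- windowPeak(fm, tm, w$rmr, p@tStimulus)
  iono <- windowPeak(fm, tm, w$iono, p@tIonomycin)
  rd <- rowData(x)
  out <- data.frame(
    cell_id = rd$cell_id, line_id = rd$line_id, group = rd$group,
    stage = rd$stage, replicate_id = rd$replicate_id,
    stimulus = p@stimulusName,
    max_rmr_fold = rmr$max_fold, time_to_max_rmr = rmr$time_to_max,
    max_iono_fold = iono$max_fold, time_to_max_iono = iono$time_to_max)
  out$responder <- classifyResponders(out$max_rmr_fold,
                                      config@doublingThreshold)
  if (config@includeRiseSlope) {
    jmax <- apply(fm[, w$rmr, drop = FALSE], 1, which.max)
    out$rise_slope_rmr <- vapply(seq_len(nrow(fm)), function(i)
      riseSlope(fm[i, ], tm, w$rmr, jmax[i]), numeric(1))
  }
  out
}

semOf <- function(v) stats::sd(v) / sqrt(length(v))

#' Summarize per-cell metrics by condition and group
#'
#' Produces one row per (group, stage, stimulus, metric) with the pooled
#' mean, SEM and n. Amplitude and time metrics are averaged over all pooled
#' cells with the SEM at the configured unit (cell-level `sd/sqrt(n)` by
#' default). The percent-doubling metric (`pct_doubling`) is summarized at
#' replicate level by default: the mean and SEM of per-replicate responder
#' percentages, replicates being line x run combinations. A single replicate
#' makes a replicate-level SEM undefined; it is reported as `NA` with a
#' warning.
#'
#' @param metrics a [cellMetrics()] data.frame (may pool several cohorts).
#' @param config an [AnalysisConfig-class].
#' @return data.frame with columns `group, stage, stimulus, metric, mean,
#'   sem, n, sem_unit`.
#' @export
summarizeCells <- function(metrics, config = AnalysisConfig()) {
  stopifnot(nrow(metrics) >= 1)
  amplitude <- c("max_rmr_fold", "time_to_max_rmr", "max_iono_fold",
                 "time_to_max_iono")
  keys <- unique(metrics[, c("group", "stage", "stimulus")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- metrics$group == keys$group[i] & metrics$stage == keys$stage[i] &
      metrics$stimulus == keys$stimulus[i]
    m <- metrics[sel, , drop = FALSE]
    repId <- interaction(m$line_id, m$replicate_id, drop = TRUE)
    for (metric in amplitude) {
      v <- m[[metric]]
      sem <- if (config@amplitudeSemUnit == "cell") semOf(v) else {
        rm <- tapply(v, repId, mean)
        if (length(rm) < 2) {
          warning("single replicate: replicate-level SEM undefined for ",
                  metric)
          NA_real_
        } else semOf(as.numeric(rm))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = keys$group[i], stage = keys$stage[i],
        stimulus = keys$stimulus[i], metric = metric,
        mean = mean(v), sem = sem, n = length(v),
        sem_unit = config@amplitudeSemUnit)
    }
    pct <- 100 * as.numeric(m$responder)
    if (config@fractionSemUnit == "replicate") {
      rf <- as.numeric(tapply(pct, repId, mean))
      if (length(rf) < 2) {
        warning("single replicate: replicate-level SEM undefined for ",
                "pct_doubling")
        mu <- mean(rf); sem <- NA_real_; n <- length(rf)
      } else {
        mu <- mean(rf); sem <- semOf(rf); n <- length(rf)
      }
    } else {
      mu <- mean(pct); sem <- semOf(pct); n <- length(pct)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = keys$group[i], stage = keys$stage[i],
      stimulus = keys$stimulus[i], metric = "pct_doubling",
      mean = mu, sem = sem, n = n, sem_unit = config@fractionSemUnit)
  }
  do.call(rbind, rows)
}
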