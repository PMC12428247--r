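#' Subtract background fluorescence
#'
#' Subtracts a background estimate from every trace and clips negative
#' values to zero (`raw' = max(raw - background, 0)`). The background comes
#' from, in order of precedence: a per-cell `background` column (or per-frame
#' `background` assay) carried by the `TraceSet`; a user-supplied scalar; or
#' a per-cell rolling-percentile estimate computed from the trace itself.
#' The method used is recorded in `metadata(x)$background_method`.
#'
#' @param x a [TraceSet-class].
#' @param method `"auto"` (use the carried background column, else require
#'   `value`), `"scalar"`, or `"rolling"` (rolling percentile).
#' @param value scalar background in counts (for `method = "scalar"`).
#' @param percentile,window rolling-percentile parameters: quantile level and
#'   odd window length in frames.
#' @return the `TraceSet` with subtracted intensities.
#' @export
subtractBackground <- function(x, method = c("auto", "scalar", "rolling"),
                               value = NULL, percentile = 0.1, window = 101L) {
  method <- match.arg(method)
  raw <- intensities(x)
  hasColumn <- "background" %in% colnames(rowData(x)) ||
    "background" %in% assayNames(x)
  if (hasColumn && method == "scalar")
    warning("a background column is present and takes precedence over the ",
            "scalar value")
  if (hasColumn) {
    bg <- if ("background" %in% assayNames(x)) assay(x, "background")
          else matrix(rowData(x)$background, nrow = nrow(x), ncol = ncol(x))
    used <- "column"
  } else if (method == "scalar" || (method == "auto" && !is.null(value))) {
    if (is.null(value)) stop("method 'scalar' requires a background value")
    bg <- matrix(value, nrow = nrow(x), ncol = ncol(x))
    used <- "scalar"
  } else if (method == "rolling") {
    half <- (as.integer(window) - 1L) %/% 2L
    nT <- ncol(raw)
    bg <- t(apply(raw, 1, function(v) {
      vapply(seq_len(nT), function(j) {
        stats::quantile(v[max(1, j - half):min(nT, j + half)],
                        probs = percentile, names = FALSE)
      }, numeric(1))
    }))
    used <- "rolling-percentile"
  } else {
    stop("no background available: supply a background column, a scalar ",
         "value, or method = 'rolling'")
  }
  sub <- pmax(raw - bg, 0)
  if (any(apply(sub, 1, max) <= 0))
    stop("degenerate trace: background is at or above all intensities for ",
         "at least one cell")
  assay(x, "intensity") <- sub
  rowData(x)$background <- NULL
  if ("background" %in% assayNames(x)) assay(x, "background") <- NULL
  metadata(x)$background_method <- used
  x
}

#' Baseline-normalize traces to fold change
#'
#' Computes each cell's baseline `F0` as the mean of its background-subtracted
#' intensity over the baseline window — by default the first
#' `nBaselineFrames` frames of the recording — and adds a `"fold"` assay
#' `intensity / F0` together with `rowData$f0`. By construction the mean fold
#' over the baseline window is exactly 1 for every cell.
#'
#' The alternative anchor `"prestimulus"` takes the `nBaselineFrames` frames
#' immediately preceding the stimulus instead; the two are equal for flat
#' baselines.
#'
#' @param x a background-subtracted [TraceSet-class].
#' @param anchor `"first"` or `"prestimulus"` baseline window.
#' @return the `TraceSet` with a `"fold"` assay and `rowData$f0`.
#' @export
normalizeTraces <- function(x, anchor = c("first", "prestimulus")) {
  anchor <- match.arg(anchor)
  p <- protocol(x)
  tm <- traceTimes(x)
  pre <- which(tm < p@tStimulus)
  if (length(pre) < p@nBaselineFrames)
    stop("fewer than ", p@nBaselineFrames, " pre-stimulus frames available")
  idx <- if (anchor == "first") seq_len(p@nBaselineFrames)
         else utils::tail(pre, p@nBaselineFrames)
  raw <- intensities(x)
  f0 <- rowMeans(raw[, idx, drop = FALSE])
  if (any(f0 <= 0))
    stop("degenerate trace: baseline F0 <= 0 for at least one cell")
  assay(x, "fold") <- raw / f0
  rowData(x)$f0 <- f0
  metadata(x)$baseline_anchor <- anchor
  x
}

#' Extract per-ROI traces from a timelapse image stack
#'
#' Reads a multi-page TIFF stack and a label-mask TIFF and computes, for each
#' label, the mean pixel intensity per frame. Pixels outside all labels
#' provide a scalar background estimate stored in the `background` column.
#'
#' @param stackPath multi-page TIFF, one page per frame.
#' @param maskPath single-page label TIFF (0 = background, 1..k = cells).
#' @param protocol the recording's [StimulusProtocol-class].
#' @param cellData optional data.frame with one row per label supplying
#'   `cell_id, line_id, group, stage, replicate_id`; placeholders otherwise.
#' @return a [TraceSet-class], one row per non-empty label.
#' @export
extractRoiTraces <- function(stackPath, maskPath,
                             protocol = StimulusProtocol(), cellData = NULL) {
  pages <- tiff::readTIFF(stackPath, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- tiff::readTIFF(maskPath, as.is = TRUE)
  if (!all(dim(pages[[1]]) == dim(mask)))
    stop("stack and mask dimensions differ: ",
         paste(dim(pages[[1]]), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  maxLab <- max(mask)
  labels <- integer(0)
  pixels <- list()
  for (lab in seq_len(maxLab)) {
    idx <- which(mask == lab)
    if (length(idx) == 0) {
      warning("label ", lab, " has no pixels; skipped")
      next
    }
    labels <- c(labels, lab)
    pixels[[length(pixels) + 1L]] <- idx
  }
  nT <- length(pages)
  times <- protocolTimes(protocol)
  if (length(times) != nT)
    stop("stack has ", nT, " frames but the protocol grid has ",
         length(times))
  if (length(labels) == 0) {
    warning("mask contains no labels; returning an empty TraceSet")
    cd <- data.frame(cell_id = character(0), line_id = character(0),
                     group = character(0), stage = character(0),
                     replicate_id = character(0), background = numeric(0))
    return(TraceSet(matrix(numeric(0), nrow = 0, ncol = nT), cd, protocol,
                    times = times))
  }
  mat <- matrix(0, nrow = length(labels), ncol = nT)
  for (j in seq_len(nT)) {
    fr <- pages[[j]]
    mat[, j] <- vapply(pixels, function(ix) mean(fr[ix]), numeric(1))
  }
  outside <- which(mask == 0)
  bgEst <- if (length(outside)) mean(pages[[1]][outside]) else NA_real_
  if (is.null(cellData))
    cellData <- data.frame(cell_id = paste0("roi", labels),
                           line_id = "roi", group = "control",
                           stage = "iPSC", replicate_id = "roi")
  cellData$background <- bgEst
  TraceSet(mat, cellData, protocol, times = times)
}
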