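#' Build a TraceSet from an intensity matrix
#'
#' @param intensity numeric matrix, cells x frames, raw fluorescence counts.
#' @param cellData data.frame or DataFrame with one row per cell and columns
#'   `cell_id, line_id, group, stage, replicate_id` (and optionally scalar
#'   `background`).
#' @param times frame times in seconds (defaults to the protocol grid).
#' @param protocol a [StimulusProtocol-class].
#' @return a [TraceSet-class].
#' @export
TraceSet <- function(intensity, cellData, protocol, times = NULL) {
  if (is.null(times)) times <- protocolTimes(protocol)
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != length(times))
    stop("intensity has ", ncol(intensity), " frames but ", length(times),
         " times were given")
  cellData <- S4Vectors::DataFrame(cellData)
  if (nrow(cellData) != nrow(intensity))
    stop("cellData rows must match intensity rows")
  rownames(intensity) <- cellData$cell_id
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = cellData,
    colData = S4Vectors::DataFrame(time_s = times,
                                   row.names = paste0("t", seq_along(times))))
  metadata(se)$protocol <- protocol
  new("TraceSet", se)
}

#' @describeIn TraceSet the stimulation protocol carried in the metadata.
#' @export
setMethod("protocol", "TraceSet", function(x) metadata(x)$protocol)

#' @rdname TraceSet
#' @export
setReplaceMethod("protocol", "TraceSet", function(x, value) {
  stopifnot(is(value, "StimulusProtocol"))
  metadata(x)$protocol <- value
  validObject(x)
  x
})

#' @describeIn TraceSet frame times in seconds.
#' @export
setMethod("traceTimes", "TraceSet", function(x) x$time_s)

#' @describeIn TraceSet the cells x frames intensity matrix.
#' @export
setMethod("intensities", "TraceSet", function(x) assay(x, "intensity"))

#' @describeIn TraceSet the cells x frames fold-change matrix (after
#'   [normalizeTraces()]).
#' @export
setMethod("folds", "TraceSet", function(x) {
  if (!isNormalized(x))
    stop("TraceSet is not normalized; run normalizeTraces() first")
  assay(x, "fold")
})

#' @describeIn TraceSet per-cell baseline F0 values (after normalization).
#' @export
setMethod("baselineF0", "TraceSet", function(x) {
  if (!isNormalized(x))
    stop("TraceSet is not normalized; run normalizeTraces() first")
  stats::setNames(rowData(x)$f0, rowData(x)$cell_id)
})

#' @describeIn TraceSet per-cell metadata as a DataFrame.
#' @export
setMethod("cellData", "TraceSet", function(x) rowData(x))

#' @describeIn TraceSet `TRUE` once a `"fold"` assay is present.
#' @export
setMethod("isNormalized", "TraceSet", function(x) "fold" %in% assayNames(x))

setMethod("show", "TraceSet", function(object) {
  rd <- rowData(object)
  cat(sprintf("TraceSet: %d cells x %d frames%s\n",
              nrow(object), ncol(object),
              if (isNormalized(object)) " (normalized)" else ""))
  cat("  groups: ",
      paste(sprintf("%s=%d", names(table(rd$group)), table(rd$group)),
            collapse = ", "), "\n", sep = "")
  cat("  stages: ", paste(unique(rd$stage), collapse = ", "),
      " | lines: ", paste(unique(rd$line_id), collapse = ", "), "\n", sep = "")
  show(protocol(object))
})

# rbind-combine two TraceSets on the same protocol grid (used to pool an
# ASD and a control cohort before comparison).

#' Combine TraceSets sharing a frame grid
#'
#' @param ... TraceSet objects with identical frame times and protocols.
#' @return a single TraceSet with all cells.
#' @export
bindTraceSets <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, is, logical(1), "TraceSet")))
  t0 <- traceTimes(xs[[1]])
  for (x in xs[-1])
    if (!isTRUE(all.equal(traceTimes(x), t0)))
      stop("TraceSets have different frame grids")
  out <- do.call(rbind, xs)
  metadata(out)$protocol <- protocol(xs[[1]])
  new("TraceSet", out)
}
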