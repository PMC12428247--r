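#' Construct a kinetic shape
#'
#' @param peakFold maximum RMR fold (>= 1).
#' @param timeToPeak seconds from stimulus delivery to the RMR peak.
#' @param plateauFrac fraction of `(peakFold - 1)` retained at the end of the
#'   RMR window (default 0.35).
#' @param egtaDecayTau EGTA-phase decay constant in seconds (default 30).
#' @param ionoPeakFold,ionoTimeToPeak ionomycin pulse parameters; `NA` takes
#'   the cohort-preset means at generation time.
#' @return a [KineticShape-class].
#' @export
KineticShape <- function(peakFold, timeToPeak, plateauFrac = 0.35,
                         egtaDecayTau = 30, ionoPeakFold = NA_real_,
                         ionoTimeToPeak = NA_real_) {
  new("KineticShape", peakFold = peakFold, timeToPeak = timeToPeak,
      plateauFrac = plateauFrac, egtaDecayTau = egtaDecayTau,
      ionoPeakFold = ionoPeakFold, ionoTimeToPeak = ionoTimeToPeak)
}

setMethod("show", "KineticShape", function(object) {
  cat(sprintf(
    "KineticShape: peak %g fold at %g s (plateau %g, EGTA tau %g s), ionomycin %g fold at %g s\n",
    object@peakFold, object@timeToPeak, object@plateauFrac,
    object@egtaDecayTau, object@ionoPeakFold, object@ionoTimeToPeak))
})

# Alpha-pulse increment: rises as g(tau) = (tau/tp) exp(1 - tau/tp) to 1 at
# tau = tp, then relaxes to exactly the plateau fraction p at tau = tauEnd
# (the post-peak decay is the alpha tail rescaled to hit the plateau at the
# window end, so the level carried out of a window is p regardless of tp).
alphaShape <- function(tau, tp, p, tauEnd) {
  g <- (tau / tp) * exp(1 - tau / tp)
  gEnd <- (tauEnd / tp) * exp(1 - tauEnd / tp)
  decay <- p + (1 - p) * (g - gEnd) / (1 - gEnd)
  ifelse(tau <= tp, g, decay)
}

# Snap a time-to-peak to the sampling grid so the drawn amplitude is realized
# exactly at a frame; never snapped below one frame.
snapToGrid <- function(tp, dt) pmax(round(tp / dt), 1) * dt

#' Noise-free fold profile of a kinetic shape
#'
#' Evaluates the deterministic fold-change series on the protocol grid: 1
#' before the stimulus; an alpha pulse peaking at `peakFold` exactly
#' `timeToPeak` seconds after the stimulus, relaxing toward the partial
#' plateau; a second alpha pulse from the ionomycin frame peaking at
#' `ionoPeakFold`; and an exponential return toward 1 after EGTA. Times to
#' peak are snapped to the frame grid so the peaks land on sampled frames.
#'
#' @param shape a [KineticShape-class] with ionomycin fields set.
#' @param protocol a [StimulusProtocol-class].
#' @param times frame times (defaults to the protocol grid).
#' @return numeric vector of fold values, one per frame.
#' @export
foldProfile <- function(shape, protocol, times = protocolTimes(protocol)) {
  dt <- protocol@frameInterval
  tp <- snapToGrid(shape@timeToPeak, dt)
  tp2 <- snapToGrid(shape@ionoTimeToPeak, dt)
  rmrLen <- protocol@tIonomycin - protocol@tStimulus
  ionoLen <- protocol@tEgta - protocol@tIonomycin
  if (tp >= rmrLen)
    stop("timeToPeak ", tp, " s places the peak beyond the RMR window (",
         rmrLen, " s)")
  if (tp2 >= ionoLen)
    stop("ionoTimeToPeak ", tp2,
         " s places the peak beyond the ionomycin window (", ionoLen, " s)")
  A <- shape@peakFold
  p <- shape@plateauFrac
  fold <- rep(1, length(times))

  rmr <- times >= protocol@tStimulus & times < protocol@tIonomycin
  tau <- times[rmr] - protocol@tStimulus
  fold[rmr] <- 1 + (A - 1) * alphaShape(tau, tp, p, rmrLen)

  # receptor response relaxes to its plateau by the ionomycin frame
  base <- 1 + (A - 1) * p
  amp <- max(shape@ionoPeakFold - base, 0)
  iono <- times >= protocol@tIonomycin & times < protocol@tEgta
  tau2 <- times[iono] - protocol@tIonomycin
  fold[iono] <- base + amp * alphaShape(tau2, tp2, p, ionoLen)

  vEgta <- base + amp * p
  egta <- times >= protocol@tEgta
  fold[egta] <- 1 + (vEgta - 1) *
    exp(-(times[egta] - protocol@tEgta) / shape@egtaDecayTau)
  fold
}

#' Generate a single synthetic trace
#'
#' Renders a cell's noise-free fold profile into raw fluorescence counts:
#' `raw = background + f0 * fold * exp(-bleachRate * t) + N(0, noiseSd)`,
#' clipped at 0. Randomness comes from the R session RNG; call `set.seed()`
#' for reproducibility (identical seeds give identical traces).
#'
#' @param shape a [KineticShape-class]; `NA` ionomycin fields take the preset
#'   means.
#' @param preset a [CohortPreset-class] supplying the optics.
#' @param protocol a [StimulusProtocol-class].
#' @param cellId,lineId,replicateId identifiers for the generated cell.
#' @return a one-cell [TraceSet-class].
#' @examples
#' set.seed(1)
#' ts <- generateTrace(KineticShape(3, 30), CohortPreset("ASD", "iPSC", "ATP",
#'                     muPeak = 3, muTtp = 30), StimulusProtocol())
#' @export
generateTrace <- function(shape, preset, protocol = StimulusProtocol(),
                          cellId = "cell1", lineId = paste0(preset@group, "1"),
                          replicateId = "rep1") {
  if (is.na(shape@ionoPeakFold))
    shape@ionoPeakFold <- preset@muIonoPeak
  if (is.na(shape@ionoTimeToPeak))
    shape@ionoTimeToPeak <- preset@muIonoTtp
  times <- protocolTimes(protocol)
  fold <- foldProfile(shape, protocol, times)
  clean <- preset@backgroundLevel +
    preset@f0 * fold * exp(-preset@bleachRate * times)
  raw <- clean
  if (preset@noiseSd > 0)
    raw <- raw + stats::rnorm(length(times), 0, preset@noiseSd)
  raw <- pmax(raw, 0)
  cd <- data.frame(cell_id = cellId, line_id = lineId, group = preset@group,
                   stage = preset@stage, replicate_id = replicateId,
                   background = preset@backgroundLevel)
  TraceSet(matrix(raw, nrow = 1), cd, protocol, times = times)
}

# Inverse-CDF truncated-normal draws (deterministic given the RNG stream).
rtrunc <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mu, lo), hi), n))
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

#' Generate a synthetic cohort of traces
#'
#' Draws `nLines x nReplicates x nCellsPerReplicate` cells for one condition.
#' Each cell is a responder with probability `responderFrac`; its peak fold is
#' drawn from the calibrated responder component (see [calibrateMixture()])
#' or from the non-responder component `Normal(nonresponderMu,
#' nonresponderSd)` truncated to `[1, threshold)`; responder draws are
#' truncated below at 1. Times-to-peak are normal draws truncated to the
#' response window and snapped to the frame grid; ionomycin peaks and times
#' are drawn analogously. The whole cohort is rendered with shared optics and
#' per-frame Gaussian noise.
#'
#' @param preset a [CohortPreset-class].
#' @param protocol a [StimulusProtocol-class].
#' @param seed integer seed; generation is fully reproducible given the seed.
#' @param threshold doubling threshold used for mixture calibration.
#' @return a [TraceSet-class] with one row per generated cell.
#' @examples
#' ts <- generateCohort(studyPresets()[["iPSC.ATP.ASD"]], seed = 1)
#' @export
generateCohort <- function(preset, protocol = NULL, seed = NULL,
                           threshold = 2.0) {
  if (is.null(protocol))
    protocol <- StimulusProtocol(stimulusName = preset@stimulus)
  if (!is.null(seed)) set.seed(seed)
  mix <- calibrateMixture(preset, threshold)
  dt <- protocol@frameInterval
  rmrLen <- protocol@tIonomycin - protocol@tStimulus
  ionoLen <- protocol@tEgta - protocol@tIonomycin
  times <- protocolTimes(protocol)

  nCells <- preset@nLines * preset@nReplicates * preset@nCellsPerReplicate
  lineIdx <- rep(seq_len(preset@nLines),
                 each = preset@nReplicates * preset@nCellsPerReplicate)
  repIdx <- rep(rep(seq_len(preset@nReplicates),
                    each = preset@nCellsPerReplicate), preset@nLines)
  lineId <- paste0(preset@group, lineIdx)
  replicateId <- paste0(lineId, "_r", repIdx)
  cellId <- sprintf("%s_%s_c%03d", preset@stage, replicateId,
                    rep(seq_len(preset@nCellsPerReplicate),
                        preset@nLines * preset@nReplicates))

  isResp <- stats::runif(nCells) < preset@responderFrac
  A <- numeric(nCells)
  if (any(isResp))
    A[isResp] <- rtrunc(sum(isResp), mix$responderMu, preset@sdPeakCell,
                        lo = 1)
  if (any(!isResp))
    A[!isResp] <- rtrunc(sum(!isResp), mix$nonresponderMu,
                         preset@nonresponderSd, lo = 1, hi = threshold)
  tp <- rtrunc(nCells, preset@muTtp, preset@sdTtp, lo = dt, hi = rmrLen - dt)
  A2 <- rtrunc(nCells, preset@muIonoPeak, preset@sdPeakCell, lo = 1)
  tp2 <- rtrunc(nCells, preset@muIonoTtp, 0.3 * preset@muIonoTtp,
                lo = dt, hi = ionoLen - dt)

  mat <- matrix(0, nrow = nCells, ncol = length(times))
  for (i in seq_len(nCells)) {
    sh <- KineticShape(A[i], tp[i], ionoPeakFold = A2[i],
                       ionoTimeToPeak = tp2[i])
    mat[i, ] <- preset@backgroundLevel +
      preset@f0 * foldProfile(sh, protocol, times) *
      exp(-preset@bleachRate * times)
  }
  if (preset@noiseSd > 0)
    mat <- mat + matrix(stats::rnorm(length(mat), 0, preset@noiseSd),
                        nrow = nCells)
  mat <- pmax(mat, 0)

  cd <- data.frame(cell_id = cellId, line_id = lineId, group = preset@group,
                   stage = preset@stage, replicate_id = replicateId,
                   background = preset@backgroundLevel,
                   drawn_peak_fold = A, drawn_ttp = snapToGrid(tp, dt),
                   drawn_iono_fold = A2, drawn_iono_ttp = snapToGrid(tp2, dt))
  ts <- TraceSet(mat, cd, protocol, times = times)
  metadata(ts)$preset <- preset
  metadata(ts)$seed <- seed
  ts
}

#' Render a cohort as a toy timelapse image stack
#'
#' Writes a multi-page 16-bit TIFF with one frame per time point. Each cell is
#' drawn as a filled disc on a regular grid whose pixels all equal the cell's
#' raw intensity at that frame (so an ROI mean reproduces the trace up to
#' integer quantization); pixels outside all discs equal the background
#' level. A companion single-page label-mask TIFF assigns each disc its
#' 1-based cell index.
#'
#' @param x a [TraceSet-class].
#' @param stackPath,maskPath output TIFF paths.
#' @param discRadius disc radius in pixels.
#' @param spacing centre-to-centre spacing in pixels; discs must not overlap.
#' @param backgroundLevel counts assigned outside all discs.
#' @return named character vector of the written paths, invisibly.
#' @export
generateImageStack <- function(x, stackPath, maskPath, discRadius = 3,
                               spacing = 2 * discRadius + 3,
                               backgroundLevel = 50) {
  if (nrow(x) == 0) stop("empty cohort: nothing to render")
  if (spacing < 2 * discRadius + 1)
    stop("layout error: discs of radius ", discRadius,
         " overlap at spacing ", spacing)
  nCells <- nrow(x)
  nx <- ceiling(sqrt(nCells))
  ny <- ceiling(nCells / nx)
  wd <- nx * spacing
  ht <- ny * spacing
  cx <- (((seq_len(nCells) - 1) %% nx) + 0.5) * spacing
  cy <- ((floor((seq_len(nCells) - 1) / nx)) + 0.5) * spacing

  px <- matrix(rep(seq_len(wd) - 0.5, each = ht), nrow = ht)
  py <- matrix(rep(seq_len(ht) - 0.5, times = wd), nrow = ht)
  mask <- matrix(0L, nrow = ht, ncol = wd)
  discs <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    inDisc <- (px - cx[i])^2 + (py - cy[i])^2 <= discRadius^2
    discs[[i]] <- which(inDisc)
    mask[inDisc] <- i
  }

  raw <- intensities(x)
  frames <- lapply(seq_len(ncol(x)), function(j) {
    fr <- matrix(backgroundLevel, nrow = ht, ncol = wd)
    for (i in seq_len(nCells)) fr[discs[[i]]] <- raw[i, j]
    round(pmin(pmax(fr, 0), 65535)) / 65535
  })
  tiff::writeTIFF(frames, stackPath, bits.per.sample = 16,
                  compression = "none")
  tiff::writeTIFF(mask / 65535, maskPath, bits.per.sample = 16,
                  compression = "none")
  invisible(c(stack = stackPath, mask = maskPath))
}
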