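#' Construct a stimulation protocol
#'
#' Defaults encode the standard recording: 500 s at 1 s intervals, receptor
#' stimulus at second 20, 4 uM ionomycin at second 200, EGTA at second 400,
#' baseline taken as the average of the first three frames. These constants
#' are the single source of timing truth for every other module.
#'
#' @param frameInterval sampling interval (s).
#' @param tEnd recording length (s).
#' @param tStimulus receptor-stimulus time (s).
#' @param tIonomycin ionomycin time (s).
#' @param tEgta EGTA time (s).
#' @param nBaselineFrames frames averaged into F0.
#' @param stimulusName `"ATP"`, `"KCl"` or `"DHPG"`.
#' @return a [StimulusProtocol-class] object.
#' @examples
#' p <- StimulusProtocol(stimulusName = "KCl")
#' protocolTimes(p)[1:5]
#' @export
StimulusProtocol <- function(frameInterval = 1.0, tEnd = 500,
                             tStimulus = 20, tIonomycin = 200, tEgta = 400,
                             nBaselineFrames = 3L, stimulusName = "ATP") {
  new("StimulusProtocol",
      frameInterval = as.numeric(frameInterval),
      tEnd = as.numeric(tEnd),
      tStimulus = as.numeric(tStimulus),
      tIonomycin = as.numeric(tIonomycin),
      tEgta = as.numeric(tEgta),
      nBaselineFrames = as.integer(nBaselineFrames),
      stimulusName = stimulusName)
}

#' @describeIn StimulusProtocol the uniform frame-time grid `0, dt, ..., <= tEnd`.
#' @param object,p a `StimulusProtocol`.
#' @export
protocolTimes <- function(p) {
  seq(0, p@tEnd, by = p@frameInterval)
}

# Frame-index windows (half-open at event instants; the event frame belongs
# to the window it opens).
protocolWindows <- function(p, times = protocolTimes(p)) {
  list(
    baseline = which(seq_along(times) <= p@nBaselineFrames),
    rmr      = which(times >= p@tStimulus & times < p@tIonomycin),
    iono     = which(times >= p@tIonomycin & times < p@tEgta),
    egta     = which(times >= p@tEgta)
  )
}

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf(
    "StimulusProtocol: %s | %.0f s at %.3g s/frame | stimulus %g s, ionomycin %g s, EGTA %g s | F0 over first %d frames\n",
    object@stimulusName, object@tEnd, object@frameInterval,
    object@tStimulus, object@tIonomycin, object@tEgta,
    object@nBaselineFrames))
})

#' Analysis configuration constructor
#'
#' @param doublingThreshold responder threshold in fold units (default 2).
#' @param amplitudeSemUnit SEM unit for amplitude/time metrics.
#' @param fractionSemUnit SEM unit for percent doubling.
#' @param testUnit sampling unit of group comparisons.
#' @param baselineAnchor `"first"` or `"prestimulus"` baseline window.
#' @param includeRiseSlope also compute the 10-90% rise slope.
#' @param rngSeed seed recorded in report sidecars.
#' @return an [AnalysisConfig-class] object.
#' @export
AnalysisConfig <- function(doublingThreshold = 2.0,
                           amplitudeSemUnit = "cell",
                           fractionSemUnit = "replicate",
                           testUnit = "cell",
                           baselineAnchor = "first",
                           includeRiseSlope = FALSE,
                           rngSeed = NA_integer_) {
  new("AnalysisConfig",
      doublingThreshold = doublingThreshold,
      amplitudeSemUnit = amplitudeSemUnit,
      fractionSemUnit = fractionSemUnit,
      testUnit = testUnit,
      baselineAnchor = baselineAnchor,
      includeRiseSlope = includeRiseSlope,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(
    "AnalysisConfig: doubling >= %g fold | SEM unit %s (amplitudes) / %s (fractions) | test unit %s | baseline anchor %s\n",
    object@doublingThreshold, object@amplitudeSemUnit,
    object@fractionSemUnit, object@testUnit, object@baselineAnchor))
})

#' Read a protocol or analysis configuration file
#'
#' Configuration files are YAML (or JSON, a YAML subset) mappings with snake
#' case keys `frame_interval, t_end, t_stimulus, t_ionomycin, t_egta,
#' n_baseline_frames, stimulus_name` for protocols and `doubling_threshold,
#' amplitude_sem_unit, fraction_sem_unit, test_unit, baseline_anchor,
#' include_rise_slope, rng_seed` for analysis configs. Missing keys take
#' the defaults.
#'
#' @param path file path.
#' @return a `StimulusProtocol` or `AnalysisConfig`.
#' @export
readProtocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(frameInterval = cfg$frame_interval, tEnd = cfg$t_end,
               tStimulus = cfg$t_stimulus, tIonomycin = cfg$t_ionomycin,
               tEgta = cfg$t_egta, nBaselineFrames = cfg$n_baseline_frames,
               stimulusName = cfg$stimulus_name)
  do.call(StimulusProtocol, args[!vapply(args, is.null, logical(1))])
}

#' @rdname readProtocol
#' @export
readAnalysisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(doublingThreshold = cfg$doubling_threshold,
               amplitudeSemUnit = cfg$amplitude_sem_unit,
               fractionSemUnit = cfg$fraction_sem_unit,
               testUnit = cfg$test_unit,
               baselineAnchor = cfg$baseline_anchor,
               includeRiseSlope = cfg$include_rise_slope,
               rngSeed = cfg$rng_seed)
  do.call(AnalysisConfig, args[!vapply(args, is.null, logical(1))])
}
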