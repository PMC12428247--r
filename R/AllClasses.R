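#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

STAGES  <- c("iPSC", "Diff1wk", "Diff4wk")
GROUPS  <- c("ASD", "control")
STIMULI <- c("ATP", "KCl", "DHPG")
DEG_STAGES <- c("iPSC", "NI", "NSP", "Diff")

#' Stimulation protocol of a calcium-imaging recording
#'
#' Describes the timing of a single-dye evoked-response recording: a uniform
#' sampling grid, a receptor stimulus (ATP, KCl or DHPG), a calcium ionophore
#' (ionomycin) that reveals the maximal dye signal, and the chelator EGTA
#' that terminates the informative windows. All downstream windowing (baseline,
#' receptor-mediated response, ionomycin response, EGTA tail) derives from this
#' object, which is carried in the metadata of every [TraceSet].
#'
#' Windows are half-open: baseline frames are the first `nBaselineFrames`
#' frames, the receptor-mediated response (RMR) window is
#' `[tStimulus, tIonomycin)`, the ionomycin window `[tIonomycin, tEgta)`, and
#' the EGTA tail `[tEgta, tEnd]`. The stimulus frame itself belongs to the RMR
#' window.
#'
#' @slot frameInterval sampling interval in seconds.
#' @slot tEnd recording length in seconds.
#' @slot tStimulus time of receptor-stimulus delivery (s).
#' @slot tIonomycin time of ionomycin addition (s).
#' @slot tEgta time of EGTA addition (s).
#' @slot nBaselineFrames number of frames averaged into the baseline F0.
#' @slot stimulusName one of `"ATP"`, `"KCl"`, `"DHPG"`.
#' @export
setClass("StimulusProtocol", representation(
  frameInterval   = "numeric",
  tEnd            = "numeric",
  tStimulus       = "numeric",
  tIonomycin      = "numeric",
  tEgta           = "numeric",
  nBaselineFrames = "integer",
  stimulusName    = "character"
))

setValidity("StimulusProtocol", function(object) {
  msg <- NULL
  if (object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (!(0 < object@tStimulus && object@tStimulus < object@tIonomycin &&
        object@tIonomycin < object@tEgta && object@tEgta <= object@tEnd))
    msg <- c(msg, "event times must satisfy 0 < tStimulus < tIonomycin < tEgta <= tEnd")
  if (object@nBaselineFrames < 1L)
    msg <- c(msg, "nBaselineFrames must be >= 1")
  if (object@nBaselineFrames * object@frameInterval > object@tStimulus)
    msg <- c(msg, "baseline window must end before the stimulus")
  if (!object@stimulusName %in% STIMULI)
    msg <- c(msg, sprintf("stimulusName must be one of %s",
                          paste(STIMULI, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Generative parameters of one cohort condition
#'
#' A `CohortPreset` encodes the population statistics of one
#' (group, differentiation stage, stimulus) condition as parameters of the
#' synthetic trace generator: the mean and per-cell spread of the maximum
#' receptor-mediated fold response, the mean and spread of the time-to-peak,
#' the fraction of responding cells (cells whose maximum reaches the doubling
#' threshold), the non-responder component, ionomycin-response parameters, and
#' the optics (baseline counts, additive noise, photobleaching, background).
#'
#' When `responderFrac < 1` the population is a two-component mixture and
#' [calibrateMixture()] solves for the responder-component mean that makes the
#' mixture mean equal `muPeak` exactly.
#'
#' @slot group `"ASD"` or `"control"`.
#' @slot stage `"iPSC"`, `"Diff1wk"` or `"Diff4wk"`.
#' @slot stimulus `"ATP"`, `"KCl"` or `"DHPG"`.
#' @slot muPeak population mean of the maximum RMR fold (dimensionless, >= 1).
#' @slot sdPeakCell per-cell SD of the peak fold.
#' @slot muTtp mean time from stimulus to RMR peak (s).
#' @slot sdTtp SD of the time-to-peak (s).
#' @slot responderFrac fraction of cells at or above the doubling threshold.
#' @slot nonresponderMu,nonresponderSd non-responder peak-fold component.
#' @slot muIonoPeak mean ionomycin maximum fold.
#' @slot muIonoTtp mean time from ionomycin to its peak (s).
#' @slot f0 baseline fluorescence (counts).
#' @slot noiseSd additive Gaussian noise SD (counts).
#' @slot bleachRate per-second fractional photobleaching decay.
#' @slot backgroundLevel background offset (counts).
#' @slot nCellsPerReplicate,nReplicates,nLines cohort layout counts.
#' @export
setClass("CohortPreset", representation(
  group              = "character",
  stage              = "character",
  stimulus           = "character",
  muPeak             = "numeric",
  sdPeakCell         = "numeric",
  muTtp              = "numeric",
  sdTtp              = "numeric",
  responderFrac      = "numeric",
  nonresponderMu     = "numeric",
  nonresponderSd     = "numeric",
  muIonoPeak         = "numeric",
  muIonoTtp          = "numeric",
  f0                 = "numeric",
  noiseSd            = "numeric",
  bleachRate         = "numeric",
  backgroundLevel    = "numeric",
  nCellsPerReplicate = "integer",
  nReplicates        = "integer",
  nLines             = "integer"
))

setValidity("CohortPreset", function(object) {
  msg <- NULL
  if (!object@group %in% GROUPS) msg <- c(msg, "unknown group")
  if (!object@stage %in% STAGES) msg <- c(msg, "unknown stage")
  if (!object@stimulus %in% STIMULI) msg <- c(msg, "unknown stimulus")
  if (object@muPeak < 1) msg <- c(msg, "muPeak must be >= 1")
  if (object@responderFrac < 0 || object@responderFrac > 1)
    msg <- c(msg, "responderFrac must be in [0, 1]")
  if (object@muTtp <= 0) msg <- c(msg, "muTtp must be > 0")
  if (object@muIonoTtp <= 0) msg <- c(msg, "muIonoTtp must be > 0")
  if (object@f0 <= 0) msg <- c(msg, "f0 must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(c(object@nCellsPerReplicate, object@nReplicates, object@nLines) < 1L))
    msg <- c(msg, "cohort layout counts must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Noise-free kinetic shape of a single cell's response
#'
#' The deterministic fold-change profile of one cell: an alpha-function pulse
#' `g(tau) = (tau/tp) * exp(1 - tau/tp)` rising from 1 at stimulus delivery to
#' the peak fold `peakFold` at `timeToPeak` seconds, then relaxing toward a
#' partial plateau `1 + plateauFrac * (peakFold - 1)`; a second alpha pulse at
#' ionomycin addition rising to `ionoPeakFold`; and an exponential return
#' toward 1 with time constant `egtaDecayTau` after EGTA.
#'
#' @slot peakFold maximum RMR fold (>= 1).
#' @slot timeToPeak seconds from stimulus to the RMR peak (> 0).
#' @slot plateauFrac fraction of (peakFold - 1) retained at window end.
#' @slot egtaDecayTau EGTA-phase decay time constant (s).
#' @slot ionoPeakFold maximum ionomycin fold; `NA` to take the preset mean.
#' @slot ionoTimeToPeak seconds from ionomycin to its peak; `NA` for preset mean.
#' @export
setClass("KineticShape", representation(
  peakFold       = "numeric",
  timeToPeak     = "numeric",
  plateauFrac    = "numeric",
  egtaDecayTau   = "numeric",
  ionoPeakFold   = "numeric",
  ionoTimeToPeak = "numeric"
))

setValidity("KineticShape", function(object) {
  msg <- NULL
  if (object@peakFold < 1) msg <- c(msg, "peakFold must be >= 1")
  if (object@timeToPeak <= 0) msg <- c(msg, "timeToPeak must be > 0")
  if (object@plateauFrac < 0 || object@plateauFrac > 1)
    msg <- c(msg, "plateauFrac must be in [0, 1]")
  if (object@egtaDecayTau <= 0) msg <- c(msg, "egtaDecayTau must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Analysis configuration
#'
#' Tunables shared by the extraction, kinetics and comparison steps.
#'
#' @slot doublingThreshold fold threshold for responder classification (> 1).
#' @slot amplitudeSemUnit `"cell"` or `"replicate"`: unit of the SEM reported
#'   for amplitude and time metrics.
#' @slot fractionSemUnit unit of the SEM for the percent-doubling metric
#'   (default `"replicate"`).
#' @slot testUnit `"cell"` or `"replicate"`: sampling unit of the
#'   Mann-Whitney comparisons.
#' @slot baselineAnchor `"first"` (first `nBaselineFrames` frames of the
#'   recording) or `"prestimulus"` (the frames immediately preceding the
#'   stimulus). Equal for flat baselines.
#' @slot includeRiseSlope also report a 10-90% rise slope (fold/s).
#' @slot rngSeed integer seed recorded into report sidecars.
#' @export
setClass("AnalysisConfig", representation(
  doublingThreshold = "numeric",
  amplitudeSemUnit  = "character",
  fractionSemUnit   = "character",
  testUnit          = "character",
  baselineAnchor    = "character",
  includeRiseSlope  = "logical",
  rngSeed           = "integer"
))

setValidity("AnalysisConfig", function(object) {
  msg <- NULL
  if (object@doublingThreshold <= 1)
    msg <- c(msg, "doublingThreshold must be > 1")
  for (s in c("amplitudeSemUnit", "fractionSemUnit", "testUnit"))
    if (!slot(object, s) %in% c("cell", "replicate"))
      msg <- c(msg, sprintf("%s must be 'cell' or 'replicate'", s))
  if (!object@baselineAnchor %in% c("first", "prestimulus"))
    msg <- c(msg, "baselineAnchor must be 'first' or 'prestimulus'")
  if (is.null(msg)) TRUE else msg
})

#' Container for per-cell fluorescence traces
#'
#' A `TraceSet` extends [SummarizedExperiment::SummarizedExperiment] with rows
#' as cells and columns as frames. The `"intensity"` assay holds raw (or
#' background-subtracted) fluorescence counts; after [normalizeTraces()] a
#' `"fold"` assay holds the baseline-normalized fold-change series and
#' `rowData(x)$f0` the per-cell baseline. `rowData` carries `cell_id`,
#' `line_id`, `group`, `stage`, `replicate_id` and scalar `background`;
#' `colData$time_s` the frame times; `metadata(x)$protocol` the
#' [StimulusProtocol].
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- NULL
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  need <- c("cell_id", "line_id", "group", "stage", "replicate_id")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (!"time_s" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain time_s")
  else {
    tm <- object$time_s
    if (length(tm) > 1 && any(diff(tm) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
  }
  if (!is(metadata(object)$protocol, "StimulusProtocol"))
    msg <- c(msg, "metadata(x)$protocol must be a StimulusProtocol")
  if ("fold" %in% assayNames(object) && !"f0" %in% colnames(rowData(object)))
    msg <- c(msg, "normalized TraceSet must carry rowData f0")
  if (is.null(msg)) TRUE else msg
})
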