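#' Construct a cohort preset
#'
#' Defaults follow the package's standard generative conditions: per-cell
#' amplitude SD 0.6 fold, time-to-peak SD 30% of its mean, a non-responder
#' component at Normal(1.3, 0.15) fold truncated below the doubling
#' threshold, baseline 1000 counts with 1% additive noise, background 50
#' counts, no photobleaching, and a 2 lines x 3 replicates x 50 cells layout.
#'
#' @param group,stage,stimulus condition labels.
#' @param muPeak population mean maximum RMR fold.
#' @param muTtp mean time-to-peak after the stimulus (s).
#' @param responderFrac fraction of cells reaching the doubling threshold.
#' @param muIonoPeak mean ionomycin maximum fold.
#' @param muIonoTtp mean ionomycin time-to-peak (s).
#' @param sdPeakCell,sdTtp per-cell spreads.
#' @param nonresponderMu,nonresponderSd non-responder peak component.
#' @param f0,noiseSd,bleachRate,backgroundLevel optical parameters (counts,
#'   counts, per second, counts).
#' @param nCellsPerReplicate,nReplicates,nLines cohort layout.
#' @return a [CohortPreset-class].
#' @export
CohortPreset <- function(group, stage, stimulus,
                         muPeak, muTtp, responderFrac = 1.0,
                         muIonoPeak = 3.0, muIonoTtp = 50,
                         sdPeakCell = 0.6, sdTtp = 0.3 * muTtp,
                         nonresponderMu = 1.3, nonresponderSd = 0.15,
                         f0 = 1000, noiseSd = 0.01 * f0,
                         bleachRate = 0, backgroundLevel = 50,
                         nCellsPerReplicate = 50L, nReplicates = 3L,
                         nLines = 2L) {
  new("CohortPreset",
      group = group, stage = stage, stimulus = stimulus,
      muPeak = muPeak, sdPeakCell = sdPeakCell,
      muTtp = muTtp, sdTtp = sdTtp,
      responderFrac = responderFrac,
      nonresponderMu = nonresponderMu, nonresponderSd = nonresponderSd,
      muIonoPeak = muIonoPeak, muIonoTtp = muIonoTtp,
      f0 = f0, noiseSd = noiseSd, bleachRate = bleachRate,
      backgroundLevel = backgroundLevel,
      nCellsPerReplicate = as.integer(nCellsPerReplicate),
      nReplicates = as.integer(nReplicates), nLines = as.integer(nLines))
}

setMethod("show", "CohortPreset", function(object) {
  cat(sprintf(
    "CohortPreset: %s / %s / %s\n  peak %g +/- %g fold (responders %g%%), ttp %g +/- %g s\n  ionomycin %g fold at %g s | layout %d lines x %d reps x %d cells\n",
    object@group, object@stage, object@stimulus,
    object@muPeak, object@sdPeakCell, 100 * object@responderFrac,
    object@muTtp, object@sdTtp, object@muIonoPeak, object@muIonoTtp,
    object@nLines, object@nReplicates, object@nCellsPerReplicate))
})

#' Calibrate the responder/non-responder mixture of a preset
#'
#' A condition that reports both a grand-mean maximum fold and a
#' percent-doubling implies a two-component population: responders (at or
#' above the doubling threshold) and sub-threshold non-responders. With the
#' non-responder component mean fixed (default 1.3 fold), the responder
#' component mean is solved so the mixture mean equals `muPeak` exactly:
#'
#' `responderMu = (muPeak - (1 - f) * nonresponderMu) / f`
#'
#' where `f` is `responderFrac`. The identity
#' `f * responderMu + (1 - f) * nonresponderMu == muPeak` holds to machine
#' precision.
#'
#' @param preset a [CohortPreset-class].
#' @param threshold doubling threshold (fold).
#' @return list with `responderMu` and `nonresponderMu`.
#' @examples
#' p <- CohortPreset("ASD", "Diff1wk", "ATP", muPeak = 1.58, muTtp = 57,
#'                   responderFrac = 0.1363)
#' calibrateMixture(p)
#' @export
calibrateMixture <- function(preset, threshold = 2.0) {
  f <- preset@responderFrac
  nr <- preset@nonresponderMu
  if (nr >= threshold)
    stop("nonresponderMu must lie below the doubling threshold")
  if (f == 0)
    return(list(responderMu = NA_real_, nonresponderMu = nr))
  responderMu <- (preset@muPeak - (1 - f) * nr) / f
  if (responderMu < threshold)
    stop(sprintf(
      paste0("infeasible preset: responder mean %.4f falls below the ",
             "doubling threshold %.2f (mean %.3f and responder fraction ",
             "%.3f are inconsistent at non-responder mean %.2f)"),
      responderMu, threshold, preset@muPeak, f, nr))
  list(responderMu = responderMu, nonresponderMu = nr)
}

presetFromList <- function(rec) {
  args <- list(group = rec$group, stage = rec$stage, stimulus = rec$stimulus,
               muPeak = rec$mu_peak, muTtp = rec$mu_ttp,
               responderFrac = rec$responder_frac,
               muIonoPeak = rec$mu_iono_peak, muIonoTtp = rec$mu_iono_ttp,
               sdPeakCell = rec$sd_peak_cell, sdTtp = rec$sd_ttp,
               nonresponderMu = rec$nonresponder_mu,
               nonresponderSd = rec$nonresponder_sd,
               f0 = rec$f0, noiseSd = rec$noise_sd,
               bleachRate = rec$bleach_rate,
               backgroundLevel = rec$background_level,
               nCellsPerReplicate = rec$n_cells_per_replicate,
               nReplicates = rec$n_replicates, nLines = rec$n_lines)
  do.call(CohortPreset, args[!vapply(args, is.null, logical(1))])
}

#' Load cohort presets from a YAML file
#'
#' The file is a YAML sequence of mappings with snake-case keys matching the
#' [CohortPreset()] arguments (`group, stage, stimulus, mu_peak, mu_ttp,
#' responder_frac, mu_iono_peak, mu_iono_ttp`, ...); unspecified keys take
#' the constructor defaults.
#'
#' @param path YAML file.
#' @return named list of [CohortPreset-class] objects, keyed
#'   `<stage>.<stimulus>.<group>`.
#' @export
readPresets <- function(path) {
  recs <- yaml::read_yaml(path)
  out <- lapply(recs, presetFromList)
  names(out) <- vapply(out, function(p)
    paste(p@stage, p@stimulus, p@group, sep = "."), character(1))
  out
}

#' The published study conditions as presets
#'
#' Returns the shipped preset table encoding each reported
#' (stage, stimulus, group) condition of the iPSC-derived ASD/control
#' calcium-imaging study: iPSC-stage ATP responses, 1-week differentiated
#' neurons under KCl and ATP, and 4-week differentiated neurons under KCl,
#' ATP and DHPG, with grand-mean maxima, times-to-peak, percent-doubling
#' fractions and ionomycin statistics expressed as generative parameters.
#'
#' @return named list of [CohortPreset-class] objects
#'   (see [readPresets()] for the key scheme).
#' @examples
#' names(studyPresets())
#' studyPresets()[["iPSC.ATP.ASD"]]
#' @export
studyPresets <- function() {
  readPresets(system.file("extdata", "presets", "study_conditions.yaml",
                          package = "catrace", mustWork = TRUE))
}
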