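# Shared fixture builders and independent oracles.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A normalized TraceSet whose fold series equal the given matrix/vector
# (baseline frames must be 1 so that F0 recovery is exact).
tsFromFold <- function(fold, protocol = StimulusProtocol(), f0 = 1000) {
  if (is.null(dim(fold))) fold <- matrix(fold, nrow = 1)
  cd <- data.frame(cell_id = paste0("c", seq_len(nrow(fold))),
                   line_id = "ASD1", group = "ASD", stage = "iPSC",
                   replicate_id = "r1")
  ts <- TraceSet(fold * f0, cd, protocol,
                 times = protocolTimes(protocol)[seq_len(ncol(fold))])
  normalizeTraces(ts)
}

# A noise-free preset for pipeline-closure checks: tight spreads keep every
# drawn ionomycin peak above the receptor plateau so all drawn values are
# realizable.
noiselessPreset <- function(muPeak = 4.23, muTtp = 80, muIonoPeak = 3.6,
                            nCells = 20L, ...) {
  CohortPreset("ASD", "iPSC", "ATP", muPeak = muPeak, muTtp = muTtp,
               responderFrac = 1, muIonoPeak = muIonoPeak, muIonoTtp = 50,
               sdPeakCell = 0.1, noiseSd = 0,
               nCellsPerReplicate = nCells, nReplicates = 1L, nLines = 1L,
               ...)
}

extractMetrics <- function(ts, config = AnalysisConfig()) {
  cellMetrics(normalizeTraces(subtractBackground(ts)), config)
}

# Brute-force two-tailed Mann-Whitney p: enumerate every assignment of the
# pooled observations to the first sample and count assignments at least as
# extreme (in |U - n1*n2/2|) as observed.
bruteMannWhitneyP <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  r <- rank(pool)
  mu <- n1 * (n - n1) / 2
  uAll <- apply(utils::combn(n, n1), 2, function(ix)
    sum(r[ix]) - n1 * (n1 + 1) / 2)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# Exact hypergeometric upper tail from binomial coefficients.
exactHyperP <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Synthetic DEG table with exact per-stage significant counts (80% up).
makeDegTable <- function(counts = c(iPSC = 387, NI = 58, NSP = 56, Diff = 495),
                         nonsigPerStage = 50, seed = 99) {
  set.seed(seed)
  rows <- lapply(names(counts), function(s) {
    nSig <- counts[[s]]
    nUp <- round(0.8 * nSig)
    data.frame(
      gene = sprintf("%s_g%04d", s, seq_len(nSig + nonsigPerStage)),
      stage = s,
      log2fc = c(runif(nUp, 0.5, 3), runif(nSig - nUp, -3, -0.5),
                 runif(nonsigPerStage, -1, 1)),
      qvalue = c(runif(nSig, 0, 0.05), runif(nonsigPerStage, 0.2, 1)))
  })
  do.call(rbind, rows)
}
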