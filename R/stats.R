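#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test on two independent samples with midranks for ties. The
#' reported statistic is `U = min(U1, U2)`. The two-tailed p-value is exact
#' (via the null Wilcoxon distribution, doubling the smaller tail) when
#' `n1 + n2 <= 20` and there are no ties, and otherwise uses the normal
#' approximation with tie-corrected variance and continuity correction.
#' With all observations identical across both samples the test is
#' uninformative: `U = n1*n2/2`, `p = 1`, with a warning.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`. Exact mode with ties falls
#'   back to the normal approximation with a warning.
#' @return list with `U`, `U1`, `U2`, `p`, and `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  z <- c(x, y)
  if (length(unique(z)) == 1L) {
    warning("all observations identical across both samples; p = 1")
    return(list(U = n1 * n2 / 2, U1 = n1 * n2 / 2, U2 = n1 * n2 / 2,
                p = 1, method = "degenerate"))
  }
  r <- rank(z)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- any(duplicated(z))
  if (mode == "exact" && ties) {
    warning("ties present; exact p-value unavailable, using normal ",
            "approximation")
    mode <- "normal"
  }
  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = (n1 + n2) <= 20 && !ties)
  if (exact) {
    lo <- stats::pwilcox(U1, n1, n2)
    hi <- stats::pwilcox(U1 - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    n <- n1 + n2
    tt <- table(z)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    mu <- n1 * n2 / 2
    zstat <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    method <- "normal approximation"
  }
  list(U = min(U1, U2), U1 = U1, U2 = U2, p = max(p, .Machine$double.xmin),
       method = method)
}

#' Pool cell lines into group samples
#'
#' Collects all observations of one metric into an ASD sample and a control
#' sample, pooling across lines and replicates. At `unit = "replicate"` each
#' observation is a replicate mean (replicates being line x run
#' combinations) rather than a single cell.
#'
#' @param metrics a [cellMetrics()] data.frame covering both groups.
#' @param metric column to pool (e.g. `"max_rmr_fold"`), or `"pct_doubling"`
#'   for per-replicate responder percentages.
#' @param unit `"cell"` or `"replicate"`.
#' @return list with numeric samples `ASD` and `control`.
#' @export
poolGroups <- function(metrics, metric, unit = c("cell", "replicate")) {
  unit <- match.arg(unit)
  out <- lapply(c(ASD = "ASD", control = "control"), function(g) {
    m <- metrics[metrics$group == g, , drop = FALSE]
    if (nrow(m) == 0) stop("group '", g, "' has no observations")
    v <- if (metric == "pct_doubling") 100 * as.numeric(m$responder)
         else m[[metric]]
    if (unit == "replicate" || metric == "pct_doubling") {
      repId <- interaction(m$line_id, m$replicate_id, drop = TRUE)
      v <- as.numeric(tapply(v, repId, mean))
    }
    v
  })
  out
}

#' Compare conditions between ASD and control groups
#'
#' For every (stage, stimulus) present in the pooled metrics, compares the
#' two groups on each metric with the two-tailed Mann-Whitney U test:
#' `max_rmr_fold`, `time_to_max_rmr`, `max_iono_fold` and `time_to_max_iono`
#' at the configured test unit (cells by default), and `pct_doubling` at
#' replicate level. Group means and SEMs follow [summarizeCells()].
#'
#' @param metrics a [cellMetrics()] data.frame covering both groups (pool
#'   cohorts with `rbind`).
#' @param config an [AnalysisConfig-class].
#' @return data.frame with one row per (stage, stimulus, metric): group
#'   means/SEMs/n, `U`, `p_two_tailed` and `test_unit`.
#' @export
compareConditions <- function(metrics, config = AnalysisConfig()) {
  summ <- summarizeCells(metrics, config)
  keys <- unique(metrics[, c("stage", "stimulus")])
  allMetrics <- c("max_rmr_fold", "time_to_max_rmr", "max_iono_fold",
                  "time_to_max_iono", "pct_doubling")
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- metrics$stage == keys$stage[i] &
      metrics$stimulus == keys$stimulus[i]
    m <- metrics[sel, , drop = FALSE]
    if (!all(c("ASD", "control") %in% m$group))
      stop("both groups must be present for ", keys$stage[i], "/",
           keys$stimulus[i])
    for (metric in allMetrics) {
      unit <- if (metric == "pct_doubling") "replicate" else config@testUnit
      smp <- poolGroups(m, metric, unit)
      tst <- mannWhitneyU(smp$ASD, smp$control)
      gs <- lapply(c("ASD", "control"), function(g)
        summ[summ$group == g & summ$stage == keys$stage[i] &
             summ$stimulus == keys$stimulus[i] & summ$metric == metric, ])
      rows[[length(rows) + 1L]] <- data.frame(
        stage = keys$stage[i], stimulus = keys$stimulus[i], metric = metric,
        mean_ASD = gs[[1]]$mean, sem_ASD = gs[[1]]$sem,
        n_ASD = length(smp$ASD),
        mean_control = gs[[2]]$mean, sem_control = gs[[2]]$sem,
        n_control = length(smp$control),
        U = tst$U, p_two_tailed = tst$p, test_unit = unit)
    }
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjusted comparison p-values
#'
#' Optional multiple-testing correction across the rows of a
#' [compareConditions()] table; off by default because each printed
#' comparison stands alone.
#'
#' @param comparisons a [compareConditions()] data.frame.
#' @return the data.frame with a `p_bh` column appended.
#' @export
adjustComparisons <- function(comparisons) {
  comparisons$p_bh <- stats::p.adjust(comparisons$p_two_tailed, method = "BH")
  comparisons
}
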