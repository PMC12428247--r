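#' Read a differential-expression table
#'
#' CSV with columns `gene, stage, log2fc, qvalue`; stages follow the
#' four-stage differentiation vocabulary iPSC, NI, NSP, Diff.
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
readDegTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "stage", "log2fc", "qvalue")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("DEG table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$qvalue < 0 | df$qvalue > 1))
    stop("qvalue out of [0, 1]")
  if (!all(df$stage %in% DEG_STAGES))
    stop("unknown stage labels: ",
         paste(setdiff(unique(df$stage), DEG_STAGES), collapse = ", "))
  df
}

#' Read a gene set (one symbol per line)
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of unique symbols.
#' @export
readGeneSet <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Count significant DEGs per stage
#'
#' Tallies, for each differentiation stage, the genes significant at
#' `qvalue <= qThreshold`, split by direction of change. Significant genes
#' with `log2fc == 0` are counted in the total but in neither direction,
#' with a warning.
#'
#' @param records DEG data.frame (`gene, stage, log2fc, qvalue`).
#' @param qThreshold significance threshold on the q-value (default 0.05).
#' @return data.frame with one row per stage: `stage, total, up, down`.
#' @export
countStageDegs <- function(records, qThreshold = 0.05) {
  sig <- records[records$qvalue <= qThreshold, , drop = FALSE]
  if (any(sig$log2fc == 0))
    warning(sum(sig$log2fc == 0),
            " significant gene(s) with log2fc = 0 counted in neither ",
            "direction")
  out <- data.frame(stage = DEG_STAGES)
  out$total <- vapply(out$stage, function(s) sum(sig$stage == s), integer(1))
  out$up <- vapply(out$stage, function(s)
    sum(sig$stage == s & sig$log2fc > 0), integer(1))
  out$down <- vapply(out$stage, function(s)
    sum(sig$stage == s & sig$log2fc < 0), integer(1))
  out
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a DEG list and an
#' annotation set within a gene universe: with `N` universe genes, `K` of
#' them annotated, `n` DEGs and `k` annotated DEGs, the enrichment p-value is
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`, evaluated with
#' `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`. DEGs outside the
#' universe are dropped with a warning; the annotation set is intersected
#' with the universe.
#'
#' @param degGenes character vector of significant genes.
#' @param annotation character vector, the annotation gene set.
#' @param universe character vector, the background universe.
#' @return one-row data.frame `k, K, n, N, p_hyper`.
#' @examples
#' u <- paste0("g", 1:20)
#' hypergeomEnrichment(u[1:5], u[1:5], u)  # p = 1 / choose(20, 5)
#' @export
hypergeomEnrichment <- function(degGenes, annotation, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty gene universe")
  degGenes <- unique(degGenes)
  outside <- setdiff(degGenes, universe)
  if (length(outside)) {
    warning(length(outside), " DEG(s) outside the universe dropped")
    degGenes <- intersect(degGenes, universe)
  }
  ann <- intersect(unique(annotation), universe)
  K <- length(ann)
  n <- length(degGenes)
  if (n == 0) stop("no DEGs within the universe")
  k <- length(intersect(degGenes, ann))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, p_hyper = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bhAdjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank stages by calcium-relevant DEG burden
#'
#' Orders stages by annotated-DEG count (descending), breaking ties by
#' smaller enrichment p-value and then by stage name, and returns the top
#' `topK`.
#'
#' @param results data.frame with columns `stage, k, p_hyper` (one row per
#'   stage, e.g. from [screenStages()]).
#' @param topK number of stages to return.
#' @return character vector of selected stage names, best first.
#' @export
selectStages <- function(results, topK = 2L) {
  if (topK > nrow(results)) {
    warning("topK exceeds the number of stages; returning all")
    topK <- nrow(results)
  }
  ord <- order(-results$k, results$p_hyper, results$stage)
  results$stage[ord][seq_len(topK)]
}

#' Stage-selection screen over a DEG table
#'
#' The full screen: per-stage DEG tallies at the q-value threshold,
#' hypergeometric enrichment of each stage's DEGs in a calcium-annotation
#' gene set, BH correction across stages, and a ranking of stages by
#' annotated-DEG count. This reproduces the logic used to pick the
#' differentiation stages carried forward to functional imaging.
#'
#' @param records DEG data.frame (`gene, stage, log2fc, qvalue`).
#' @param annotation calcium-relevant gene set (character vector).
#' @param universe gene universe; defaults to all genes in `records`.
#' @param qThreshold DEG significance threshold (default 0.05).
#' @param topK stages to select.
#' @return list with `counts` ([countStageDegs()] table), `enrichment`
#'   (per-stage `stage, k, K, n, N, p_hyper, q_bh`), and `selected` stages.
#' @export
screenStages <- function(records, annotation,
                         universe = unique(records$gene),
                         qThreshold = 0.05, topK = 2L) {
  counts <- countStageDegs(records, qThreshold)
  enr <- do.call(rbind, lapply(DEG_STAGES, function(s) {
    genes <- unique(records$gene[records$stage == s &
                                   records$qvalue <= qThreshold])
    if (length(genes) == 0)
      return(data.frame(stage = s, k = 0L, K = NA_integer_, n = 0L,
                        N = length(unique(universe)), p_hyper = 1))
    cbind(stage = s, hypergeomEnrichment(genes, annotation, universe))
  }))
  enr$q_bh <- bhAdjust(enr$p_hyper)
  list(counts = counts, enrichment = enr,
       selected = selectStages(enr, topK))
}
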