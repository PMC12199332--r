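## Single-cell loop calling from the loop decoder Theta and consensus
## aggregation across the cell population.

#' Call loops in one cell's contact map
#'
#' Candidate pairs are the nonzero contacts of the (enhanced) map
#' restricted to the 100 kb - 1 Mb separation band; the loop decoder
#' attaches a probability to every candidate and calls are the
#' candidates at or above \code{threshold}. The full candidate
#' probability table is returned alongside so PR analysis loses nothing.
#'
#' @param model a trained \linkS4class{VGAEModel}.
#' @param graph a \linkS4class{ContactGraph}.
#' @param X standardized node features for the graph's chromosome.
#' @param threshold call threshold (default 0.5).
#' @return list with \code{calls} and \code{candidates}, both
#'   data.frame(chrom, cellId, u, v, probability).
#' @export
callLoops <- function(model, graph, X, threshold = 0.5) {
  if (!model@trained) stopf("refusing to call loops with an untrained model")
  emb <- encodeGraph(model, graph, X, mode = "eval")
  e <- graph@edges
  keep <- e$w > 0 & inLoopBand(e$u, e$v, graph@resolution)
  cand <- e[keep, c("u", "v"), drop = FALSE]
  prob <- if (nrow(cand)) decodePairs(model, emb@z, cand, "loop") else
    numeric()
  tab <- data.frame(chrom = rep(chrom(graph), nrow(cand)),
                    cellId = rep(cellId(graph), nrow(cand)),
                    u = cand$u, v = cand$v, probability = prob)
  tab <- tab[order(-tab$probability, tab$u, tab$v), , drop = FALSE]
  rownames(tab) <- NULL
  list(calls = tab[tab$probability >= threshold, , drop = FALSE],
       candidates = tab)
}

#' Call loops across a list of cells
#' @param model trained model. @param graphs list of ContactGraph.
#' @param featuresByChrom named list chrom -> standardized features.
#' @param threshold call threshold.
#' @return list with per-cell \code{calls}/\code{candidates}
#'   data.frames (row-bound).
#' @export
callLoopsAll <- function(model, graphs, featuresByChrom, threshold = 0.5) {
  res <- lapply(graphs, function(g)
    callLoops(model, g, featuresByChrom[[chrom(g)]], threshold))
  list(calls = do.call(rbind, lapply(res, `[[`, "calls")),
       candidates = do.call(rbind, lapply(res, `[[`, "candidates")))
}

#' Consensus loop probabilities across a cell population
#'
#' For every bin pair observed in any cell, the consensus probability is
#' the arithmetic mean over all cells, with cells lacking the candidate
#' contributing 0 (zero-fill; recurrence across cells is rewarded).
#' Set \code{mean = "present"} to average only over cells carrying the
#' candidate.
#'
#' @param candidates data.frame(chrom, cellId, u, v, probability) pooled
#'   over cells (from \code{\link{callLoopsAll}}).
#' @param nCells number of cells in the population (required for
#'   zero-fill; defaults to the number of distinct cellIds).
#' @param mean "all" (zero-fill) or "present".
#' @return data.frame(chrom, u, v, probability) sorted by probability
#'   descending.
#' @export
consensusLoops <- function(candidates, nCells = NULL,
                           mean = c("all", "present")) {
  mean <- match.arg(mean)
  if (is.null(nCells)) nCells <- length(unique(candidates$cellId))
  dt <- data.table::as.data.table(candidates)
  cons <- dt[, list(probability = if (mean == "all")
    sum(probability) / nCells else base::mean(probability)),
    by = c("chrom", "u", "v")]
  data.table::setorder(cons, -probability, chrom, u, v)
  as.data.frame(cons)
}
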