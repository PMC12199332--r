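## Scoring: loop precision/recall/F1 with exact bin-pair matching inside
## the 100 kb - 1 Mb band, PR and ROC curves, and boundary agreement
## between segmentations.

bandFilter <- function(pairs, resolution = 10000L) {
  pairs[inLoopBand(pairs$u, pairs$v, resolution), , drop = FALSE]
}

pairTokens <- function(pairs) {
  paste(pairs$chrom, pmin(pairs$u, pairs$v), pmax(pairs$u, pairs$v))
}

#' Loop precision, recall and F1 against a reference
#'
#' Exact bin-pair matching, no positional slack; both call and reference
#' sets are first restricted to the 100 kb - 1 Mb separation band (calls
#' outside the band are excluded before scoring, not counted as false
#' positives). F1 = 0 when precision + recall = 0.
#'
#' @param calls,reference data.frames with columns chrom, u, v.
#' @param resolution bin size in bp.
#' @return list(precision, recall, f1, tp, fp, fn).
#' @export
loopPrf <- function(calls, reference, resolution = 10000L) {
  reference <- bandFilter(reference, resolution)
  if (nrow(reference) == 0L) stopf("empty reference in band: recall undefined")
  calls <- bandFilter(calls, resolution)
  cs <- unique(pairTokens(calls)); rs <- unique(pairTokens(reference))
  tp <- length(intersect(cs, rs))
  fp <- length(setdiff(cs, rs)); fn <- length(setdiff(rs, cs))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Precision-recall curve and average precision
#'
#' Standard sweep over unique probability thresholds (descending);
#' average precision is the step-wise integral
#' \eqn{\sum_k (R_k - R_{k-1}) P_k}.
#'
#' @param probabilities candidate scores. @param labels 0/1 reference
#'   membership of each candidate.
#' @return list(curve = data.frame(threshold, precision, recall),
#'   averagePrecision).
#' @export
prCurve <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  o <- order(probabilities, decreasing = TRUE)
  y <- labels[o]; p <- probabilities[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  nPos <- sum(y)
  if (nPos == 0L) stopf("no positive labels")
  last <- !duplicated(p, fromLast = TRUE)  # one point per threshold
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / nPos
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(threshold = p[last], precision = prec,
                          recall = rec),
       averagePrecision = ap)
}

#' ROC curve and AUC (trapezoid)
#'
#' @param probabilities candidate scores. @param labels 0/1.
#' @return list(curve = data.frame(threshold, fpr, tpr), auc).
#' @export
rocCurve <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  nPos <- sum(labels); nNeg <- sum(1 - labels)
  if (nPos == 0L || nNeg == 0L)
    stopf("ROC undefined with single-class labels")
  o <- order(probabilities, decreasing = TRUE)
  y <- labels[o]; p <- probabilities[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(p, fromLast = TRUE)
  tpr <- c(0, tp[last] / nPos); fpr <- c(0, fp[last] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, p[last]), fpr = fpr,
                          tpr = tpr),
       auc = auc)
}

#' Boundary agreement between two segmentations
#'
#' A boundary of A matches B when some boundary of B lies within
#' \code{toleranceBins}; matching is greedy one-to-one, nearest pairs
#' first. Precision is over A's boundaries, recall over B's.
#'
#' @param segA,segB \linkS4class{SegmentationResult} on the same
#'   chromosome and bin count.
#' @param toleranceBins match tolerance (default 1).
#' @return list(precision, recall, f1, nMatched).
#' @export
boundaryAgreement <- function(segA, segB, toleranceBins = 1L) {
  stopifnot(segA@nBins == segB@nBins, segA@chrom == segB@chrom)
  a <- boundaryBins(segA); b <- boundaryBins(segB)
  if (!length(a) && !length(b))
    return(list(precision = 1, recall = 1, f1 = 1, nMatched = 0L))
  if (!length(a) || !length(b))
    return(list(precision = 0, recall = 0, f1 = 0, nMatched = 0L))
  dmat <- abs(outer(a, b, "-"))
  pairs <- which(dmat <= toleranceBins, arr.ind = TRUE)
  nMatched <- 0L
  if (nrow(pairs)) {
    pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
    usedA <- logical(length(a)); usedB <- logical(length(b))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE
        nMatched <- nMatched + 1L
      }
    }
  }
  precision <- nMatched / length(a)
  recall <- nMatched / length(b)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       nMatched = nMatched)
}
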