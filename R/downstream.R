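## Cell-level feature encodings at 100 kb, cell-type classification with
## one-vs-rest L1 linear SVMs, and tf-idf marker loop-anchor discovery.

#' Encode latent cell features at 100 kb
#'
#' Per (cell, chromosome): PCA across the latent dims, keep PC1 (one
#' value per bin), orient its sign to correlate positively with per-bin
#' contact coverage, pool by summing every \code{pool} consecutive bins
#' (trailing partial window summed as-is), and concatenate chromosomes.
#'
#' @param embeddings list (cells) of lists (chromosomes) of N x D latent
#'   matrices, or a single-level list for single-chromosome data.
#' @param graphs parallel structure of \linkS4class{ContactGraph} used
#'   for the coverage-based sign convention.
#' @param pool bins per pooled window (default 10 = 100 kb from 10 kb).
#' @return matrix cells x pooled dims.
#' @export
encodeLatentFeatures <- function(embeddings, graphs, pool = 10L) {
  norm1 <- function(x) if (is.list(x)) x else list(x)
  feats <- lapply(seq_along(embeddings), function(i) {
    embs <- norm1(embeddings[[i]]); gs <- norm1(graphs[[i]])
    unlist(lapply(seq_along(embs), function(j) {
      z <- as.matrix(embs[[j]])
      pc1 <- prcomp(z, center = TRUE, rank. = 1L)$x[, 1]
      cov <- binCoverage(gs[[j]])
      if (sum(pc1 * (cov - mean(cov))) < 0) pc1 <- -pc1
      poolSum(pc1, pool)
    }))
  })
  do.call(rbind, feats)
}

binCoverage <- function(graph) {
  e <- graph@edges
  cov <- numeric(graph@nBins)
  if (nrow(e)) {
    add <- rowsum(c(e$w, e$w), c(e$u, e$v) + 1L)
    cov[as.integer(rownames(add))] <- add
  }
  cov
}

poolSum <- function(x, pool) {
  grp <- (seq_along(x) - 1L) %/% pool
  as.vector(rowsum(x, grp))
}

poolMean <- function(x, pool) {
  grp <- (seq_along(x) - 1L) %/% pool
  as.vector(rowsum(x, grp) / as.vector(table(grp)))
}

#' Encode architectural cell features at 100 kb
#'
#' \code{kind = "loop"}: per cell, the number of called loops touching
#' each 100 kb bin (each loop increments both anchors' bins).
#' \code{kind = "tld"}: binary presence of any TLD boundary bin in the
#' 100 kb bin. \code{kind = "compartment"}: mean of the 10 constituent
#' 10 kb compartment scores.
#'
#' @param kind "loop", "tld" or "compartment".
#' @param perCell for "loop": list of data.frame(u, v) loop calls; for
#'   "tld": list of \linkS4class{SegmentationResult}; for "compartment":
#'   list of \linkS4class{CompartmentTrack}.
#' @param nBins chromosome length in 10 kb bins (required for "loop").
#' @param pool bins per window (default 10).
#' @return matrix cells x 100 kb bins.
#' @export
encodeArchitecturalFeatures <- function(kind = c("loop", "tld",
                                                 "compartment"),
                                        perCell, nBins = NULL, pool = 10L) {
  kind <- match.arg(kind)
  rows <- lapply(perCell, function(x) {
    switch(kind,
      loop = {
        stopifnot(!is.null(nBins))
        counts <- tabulate(c(x$u, x$v) + 1L, nbins = nBins)
        poolSum(counts, pool)
      },
      tld = {
        v <- numeric(x@nBins)
        v[boundaryBins(x) + 1L] <- 1
        as.numeric(poolSum(v, pool) > 0)
      },
      compartment = poolMean(compartmentScore(x), pool))
  })
  do.call(rbind, rows)
}

## ---- L1-regularized linear SVM (squared hinge), one binary problem ----
## min_w  ||w||_1 + C * sum_i max(0, 1 - y_i (x_i w + b))^2
## (the standard L1-penalized squared-hinge objective), solved by FISTA
## (proximal gradient with Nesterov momentum); the bias is unpenalized.
l1svmFit <- function(X, y, C = 1, maxIter = 500L, tol = 1e-7) {
  X <- as.matrix(X); y <- ifelse(y > 0, 1, -1)
  n <- nrow(X); p <- ncol(X)
  L <- 2 * C * (norm(X, "2")^2 + n) + 1e-8  # + n for the bias column
  w <- numeric(p); b <- 0
  wv <- w; bv <- b; tk <- 1
  obj <- function(w, b) {
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    sum(abs(w)) + C * sum(m^2)
  }
  prev <- obj(w, b)
  for (it in seq_len(maxIter)) {
    m <- pmax(0, 1 - y * (drop(X %*% wv) + bv))
    gcom <- -2 * C * (y * m)
    gw <- drop(crossprod(X, gcom))
    gb <- sum(gcom)
    wNew <- wv - gw / L
    wNew <- sign(wNew) * pmax(abs(wNew) - 1 / L, 0)  # soft threshold
    bNew <- bv - gb / L
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    wv <- wNew + (tk - 1) / tNew * (wNew - w)
    bv <- bNew + (tk - 1) / tNew * (bNew - b)
    w <- wNew; b <- bNew; tk <- tNew
    if (it %% 20L == 0L) {
      cur <- obj(w, b)
      if (abs(prev - cur) < tol * max(1, abs(prev))) break
      prev <- cur
    }
  }
  list(w = w, b = b)
}

l1svmDecision <- function(fit, X) drop(as.matrix(X) %*% fit$w) + fit$b

#' One-vs-rest L1 linear SVM training
#' @param X feature matrix (cells x features).
#' @param labels factor/character cell types.
#' @param C squared-hinge weight (default 1).
#' @return list of per-class fits (named), each with weights \code{w} and
#'   bias \code{b}.
#' @export
l1svmOneVsRest <- function(X, labels, C = 1) {
  labels <- as.factor(labels)
  fits <- lapply(levels(labels), function(cl)
    l1svmFit(X, ifelse(labels == cl, 1, -1), C = C))
  names(fits) <- levels(labels)
  fits
}

#' Predict cell types from one-vs-rest SVM fits
#' @param fits from \code{\link{l1svmOneVsRest}}. @param X features.
#' @return character predicted labels (argmax decision value).
#' @export
l1svmPredict <- function(fits, X) {
  dec <- do.call(cbind, lapply(fits, function(f) l1svmDecision(f, X)))
  colnames(dec) <- names(fits)
  colnames(dec)[max.col(dec, ties.method = "first")]
}

#' Stratified 2-D embedding + supervised classification of cells
#'
#' PCA (up to 50 components) provides the low-dimensional representation
#' whose first two components serve as the 2-D visualization embedding;
#' classification runs on the original features with one-vs-rest L1
#' linear SVMs, a stratified \code{trainFrac}/1 - trainFrac split, and
#' reports test accuracy, macro-F1 and the confusion matrix.
#'
#' @param X cells x features matrix. @param labels cell types.
#' @param trainFrac training fraction (default 0.75).
#' @param seed split seed. @param C SVM regularization weight.
#' @return list(embedding2d, accuracy, macroF1, confusion, testIdx,
#'   predictions).
#' @export
embedAndClassify <- function(X, labels, trainFrac = 0.75, seed = 1L,
                             C = 1) {
  labels <- as.factor(labels)
  X <- as.matrix(X)
  idxTrain <- withSeed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) < 2L)
        stopf("class %s has < 2 cells; cannot stratify", cl)
      sample(idx, max(1L, round(trainFrac * length(idx))))
    }))
  })
  idxTest <- setdiff(seq_len(nrow(X)), idxTrain)
  if (!all(levels(labels) %in% labels[idxTrain]))
    stopf("a class is absent from the training split")
  rank <- min(50L, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, rank. = rank)
  emb2d <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  fits <- l1svmOneVsRest(X[idxTrain, , drop = FALSE], labels[idxTrain],
                         C = C)
  pred <- l1svmPredict(fits, X[idxTest, , drop = FALSE])
  truth <- as.character(labels[idxTest])
  acc <- mean(pred == truth)
  confusion <- table(truth = factor(truth, levels(labels)),
                     predicted = factor(pred, levels(labels)))
  f1s <- vapply(levels(labels), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(embedding2d = emb2d, accuracy = acc, macroF1 = mean(f1s),
       confusion = confusion, testIdx = idxTest, predictions = pred)
}

#' tf-idf encoding of per-cell loop anchors
#'
#' Anchors are tokens ("chrom:bin"); the term count is the number of
#' called loops using that anchor in that cell. tf is the raw count,
#' idf = ln((1 + n) / (1 + df)) + 1 (smooth), and rows are L2-normalized.
#' Cells with zero loops get a zero row with a warning.
#'
#' @param anchorCounts cells x anchors count matrix (see
#'   \code{\link{anchorCountMatrix}}).
#' @return list(tfidf matrix, idf vector).
#' @export
tfidfEncode <- function(anchorCounts) {
  X <- as.matrix(anchorCounts)
  n <- nrow(X)
  df <- colSums(X > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  W <- sweep(X, 2, idf, "*")
  nrm <- sqrt(rowSums(W^2))
  zero <- nrm == 0
  if (any(zero)) warnf("%d cell(s) with zero loops get zero tf-idf rows",
                       sum(zero))
  nrm[zero] <- 1
  list(tfidf = W / nrm, idf = idf)
}

#' Per-cell loop anchor count matrix
#'
#' @param perCellLoops list of data.frame(chrom, u, v) loop calls.
#' @return integer matrix cells x anchors with "chrom:bin" column names;
#'   each loop contributes +1 to both of its anchors.
#' @export
anchorCountMatrix <- function(perCellLoops) {
  tokens <- lapply(perCellLoops, function(d)
    c(paste0(d$chrom, ":", d$u), paste0(d$chrom, ":", d$v)))
  lev <- sort(unique(unlist(tokens)))
  X <- t(vapply(tokens, function(tk)
    tabulate(factor(tk, levels = lev), nbins = length(lev)),
    integer(length(lev))))
  colnames(X) <- lev
  X
}

#' Discover marker loop anchors per cell type
#'
#' One-vs-rest L1 linear SVMs on tf-idf anchor features rank anchors per
#' type; the top \code{topK} positive-weight anchors per type are pooled
#' (deduplicated union) into the candidate set. For each candidate and
#' type, a Welch t-test compares per-cell raw loop counts (type vs rest),
#' Benjamini-Hochberg adjusted within each type across the pool; the log
#' fold change is log((meanIn + eps) / (meanOut + eps)).
#'
#' @param anchorCounts cells x anchors raw count matrix.
#' @param labels cell types.
#' @param topK SVM features kept per type (default 50).
#' @param C SVM regularization weight.
#' @return data.frame(anchor, cellType, logFoldChange, p, adjustedP)
#'   sorted by adjustedP.
#' @export
discoverMarkerAnchors <- function(anchorCounts, labels, topK = 50L, C = 1) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) >= 2L)
  X <- as.matrix(anchorCounts)
  tfidf <- tfidfEncode(X)$tfidf
  fits <- l1svmOneVsRest(tfidf, labels, C = C)
  pool <- unique(unlist(lapply(fits, function(f) {
    pos <- which(f$w > 0)
    if (length(pos) < topK)
      warnf("fewer than %d positive weights; taking all %d", topK,
            length(pos))
    pos[order(f$w[pos], decreasing = TRUE)][seq_len(min(topK,
                                                        length(pos)))]
  })))
  if (!length(pool)) stopf("no positive-weight anchors found")
  eps <- 1e-9
  rows <- lapply(levels(labels), function(cl) {
    inCl <- labels == cl
    res <- lapply(pool, function(a) {
      xi <- X[inCl, a]; xo <- X[!inCl, a]
      p <- if (var(xi) + var(xo) == 0) 1 else
        tryCatch(t.test(xi, xo, alternative = "greater")$p.value,
                 error = function(e) 1)
      data.frame(anchor = colnames(X)[a], cellType = cl,
                 logFoldChange = log((mean(xi) + eps) / (mean(xo) + eps)),
                 p = p)
    })
    out <- do.call(rbind, res)
    out$adjustedP <- p.adjust(out$p, method = "BH")
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$adjustedP, tab$p, tab$anchor), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
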