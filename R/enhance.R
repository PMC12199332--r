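## KNN contact-map enhancement: embed cells via smoothed diagonal profiles
## + PCA, then average each (poor-quality) cell's maps with its k nearest
## neighbours in the embedding space.

## Moving average of window 3 handling edges by the actual window size.
box3 <- function(v) {
  n <- length(v)
  if (n == 1L) return(v)
  s <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - 1L, 1L); hi <- pmin(seq_len(n) + 1L, n)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

diagProfile <- function(graph, nDiag) {
  m <- as.matrix(contactMatrix(graph))
  m <- log1p(m)
  n <- nrow(m)
  prof <- lapply(seq_len(min(nDiag, n - 1L)), function(d) {
    v <- m[cbind(seq_len(n - d), seq_len(n - d) + d)]
    box3(v)
  })
  unlist(prof)
}

#' Embed cells into a low-dimensional space
#'
#' Per cell, concatenates the lightly smoothed (1-bin box convolution
#' along diagonals) log1p contact profiles of the first \code{nDiag}
#' diagonals of every chromosome, then reduces the cell-by-profile matrix
#' with PCA. Deterministic; \code{dim} is clamped to \code{nCells - 1}.
#'
#' @param cells list of \linkS4class{ContactGraph}; multiple chromosomes
#'   per cell are grouped by \code{cellId}.
#' @param dim target embedding dimensionality (default 32).
#' @param nDiag number of diagonals per chromosome (default 100).
#' @return numeric matrix, cells x dim, rownames = cell ids.
#' @export
embedCells <- function(cells, dim = 32L, nDiag = 100L) {
  ids <- vapply(cells, cellId, character(1))
  uids <- unique(ids)
  if (length(uids) < 2L) stopf("need >= 2 cells to embed")
  profs <- do.call(rbind, lapply(uids, function(id) {
    gs <- cells[ids == id]
    gs <- gs[order(vapply(gs, chrom, character(1)))]
    unlist(lapply(gs, diagProfile, nDiag = nDiag))
  }))
  dim <- min(dim, length(uids) - 1L)
  pc <- prcomp(profs, center = TRUE, scale. = FALSE, rank. = dim)
  emb <- pc$x[, seq_len(dim), drop = FALSE]
  rownames(emb) <- uids
  emb
}

#' KNN enhancement of sparse contact maps
#'
#' For every cell selected for enhancement, each chromosome map is
#' replaced by the element-wise mean of the cell's own map and its
#' \code{k} nearest neighbours' maps (Euclidean distance in the cell
#' embedding; self excluded from the neighbour search but included in the
#' average, divisor \code{k + 1}). Distance ties break by cell id
#' lexicographic order. With \code{qualityQuantile < 1} only cells whose
#' total cis contact mass falls at or below that quantile are enhanced;
#' the rest pass through unchanged.
#'
#' @param cells list of \linkS4class{ContactGraph}.
#' @param embeddings matrix from \code{\link{embedCells}}.
#' @param k number of neighbours (default 3).
#' @param qualityQuantile quantile of per-cell total contact mass below
#'   which cells are enhanced (default 1 = enhance all).
#' @return list of ContactGraph in the same order as \code{cells}.
#' @export
knnEnhance <- function(cells, embeddings, k = 3L, qualityQuantile = 1) {
  ids <- vapply(cells, cellId, character(1))
  uids <- rownames(embeddings)
  if (k >= length(uids)) stopf("k must be < number of cells")
  mass <- vapply(uids, function(id) sum(vapply(cells[ids == id],
                                               totalContacts, numeric(1))),
                 numeric(1))
  enhanceSet <- if (qualityQuantile >= 1) uids else
    uids[mass <= quantile(mass, qualityQuantile)]
  d2 <- as.matrix(dist(embeddings))
  neighborsOf <- function(id) {
    o <- order(d2[id, ], uids)  # ties by lexicographic cell id
    setdiff(uids[o], id)[seq_len(k)]
  }
  out <- cells
  for (i in seq_along(cells)) {
    g <- cells[[i]]
    if (!(g@cellId %in% enhanceSet)) next
    nb <- neighborsOf(g@cellId)
    grp <- cells[ids %in% c(g@cellId, nb)]
    grp <- grp[vapply(grp, chrom, character(1)) == g@chrom]
    allE <- data.table::rbindlist(lapply(grp, function(x) x@edges))
    agg <- allE[, list(w = sum(w) / (k + 1)), by = c("u", "v")]
    data.table::setorder(agg, u, v)
    out[[i]] <- methods::new("ContactGraph", cellId = g@cellId,
                             chrom = g@chrom, resolution = g@resolution,
                             nBins = g@nBins, edges = as.data.frame(agg))
  }
  out
}
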