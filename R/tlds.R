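## TAD-like domain (TLD) segmentation: Ward agglomerative clustering of
## per-bin embeddings with merges restricted to genomically adjacent
## clusters (O(n^2)), CTCF boundary filtering, Wasserstein-based dynamic
## average-size selection, and co-association consensus segmentation.

#' PCA reduction of a bin embedding
#'
#' Deterministic PCA to at most \code{dims} components (identity when the
#' input is already narrow enough), used before constrained clustering
#' and HMM fitting. Each component's sign is fixed by orienting its
#' largest-magnitude loading positive.
#'
#' @param z bins x dims matrix. @param dims target dimensionality.
#' @return bins x min(dims, ncol) matrix.
#' @export
reduceEmbedding <- function(z, dims = 16L) {
  if (ncol(z) <= dims) return(z)
  pc <- prcomp(z, center = TRUE, scale. = FALSE, rank. = dims)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  pc$x %*% diag(flip, ncol(pc$x))
}

#' Model-free per-bin embedding of a contact map
#'
#' PCA of the rows of the lightly smoothed (3-bin moving average along
#' both axes) log1p dense contact matrix. Useful as a fallback bin
#' embedding for segmentation when no trained encoder is available, and
#' for validating the segmentation stack independently of the neural
#' model.
#'
#' @param graph a \linkS4class{ContactGraph}.
#' @param dims embedding dimensionality (default 16).
#' @return numeric matrix, bins x dims.
#' @export
contactEmbedding <- function(graph, dims = 16L) {
  m <- log1p(as.matrix(contactMatrix(graph)))
  sm <- apply(m, 2, box3)
  sm <- t(apply(sm, 1, box3))
  reduceEmbedding(sm, dims)
}

#' Connectivity-constrained Ward segmentation of a bin embedding
#'
#' Agglomerative Ward clustering where only genomically adjacent clusters
#' may merge, so every cluster is a contiguous bin interval and the whole
#' procedure is O(n^2) (n - 1 candidate merges, each evaluated in O(1)
#' via the size-weighted squared centroid distance, which equals the
#' Ward/Lance-Williams merge cost).
#'
#' @param z numeric matrix, bins x dims (PCA-reduced internally when wider
#'   than \code{pcaDims}).
#' @param nClusters target number of segments (1..N).
#' @param pcaDims PCA dimensionality used before clustering (default 16).
#' @param chrom,cellId metadata for the result.
#' @return a \linkS4class{SegmentationResult}.
#' @export
constrainedSegmentation <- function(z, nClusters, pcaDims = 16L,
                                    chrom = "chr1", cellId = "cell") {
  z <- as.matrix(z)
  n <- nrow(z)
  if (nClusters < 1L || nClusters > n)
    stopf("nClusters must be in [1, %d]", n)
  z <- reduceEmbedding(z, pcaDims)
  sizes <- segmentByWard(z, nClusters)
  SegmentationResult(sizes = sizes, nBins = n, chrom = chrom,
                     cellId = cellId)
}

## Core adjacent-merge Ward loop. Returns ordered segment sizes.
segmentByWard <- function(z, nClusters) {
  n <- nrow(z)
  if (nClusters == n) return(rep(1L, n))
  d <- ncol(z)
  cent <- z                       # per-cluster centroid
  csize <- rep(1L, n)
  nxt <- c(seq_len(n - 1L) + 1L, NA_integer_)  # right neighbour index
  prv <- c(NA_integer_, seq_len(n - 1L))
  active <- rep(TRUE, n)
  wardCost <- function(i, j) {
    delta <- cent[i, ] - cent[j, ]
    (csize[i] * csize[j]) / (csize[i] + csize[j]) * sum(delta * delta)
  }
  cost <- rep(Inf, n)  # cost[i] = merge cost of cluster i with nxt[i]
  for (i in seq_len(n - 1L)) cost[i] <- wardCost(i, i + 1L)
  k <- n
  while (k > nClusters) {
    i <- which.min(cost)
    j <- nxt[i]
    newsize <- csize[i] + csize[j]
    cent[i, ] <- (csize[i] * cent[i, ] + csize[j] * cent[j, ]) / newsize
    csize[i] <- newsize
    active[j] <- FALSE
    nxt[i] <- nxt[j]
    if (!is.na(nxt[j])) prv[nxt[j]] <- i
    cost[j] <- Inf
    cost[i] <- if (is.na(nxt[i])) Inf else wardCost(i, nxt[i])
    if (!is.na(prv[i])) cost[prv[i]] <- wardCost(prv[i], i)
    k <- k - 1L
  }
  csize[active]
}

#' Number of clusters for a chromosome from the target average TLD size
#'
#' The cluster count is the chromosome length divided by the average TLD
#' size (default 20 bins = 200 kb at 10 kb resolution).
#'
#' @param chromLengthBp chromosome length in bp.
#' @param avgSizeBins target average TLD size in bins.
#' @param resolution bin size in bp.
#' @export
nClustersForChrom <- function(chromLengthBp, avgSizeBins = 20L,
                              resolution = 10000L) {
  max(1L, as.integer(chromLengthBp %/% (avgSizeBins * resolution)))
}

#' CTCF-based boundary filtering
#'
#' Candidate boundary bins are split into two groups by 1-D KMeans
#' (k = 2, deterministic initialization at the min/max counts) on their
#' CTCF motif counts; the group with the larger mean count is kept and
#' segments are re-derived by dropping rejected boundaries (merging their
#' flanking segments). If all counts are equal no split is possible and
#' every candidate is kept with a warning.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param ctcfCount per-bin integer motif counts.
#' @return filtered \linkS4class{SegmentationResult}.
#' @export
ctcfBoundaryFilter <- function(seg, ctcfCount) {
  b <- boundaryBins(seg)
  if (length(b) < 2L) return(seg)
  x <- ctcfCount[b + 1L]
  if (max(x) == min(x)) {
    warnf("all candidate boundaries have equal CTCF counts; keeping all")
    return(seg)
  }
  km <- kmeans(x, centers = matrix(c(min(x), max(x)), 2L, 1L),
               iter.max = 300L)
  keepCluster <- which.max(km$centers)
  keep <- b[km$cluster == keepCluster]
  SegmentationResult(boundaries = keep, nBins = seg@nBins,
                     chrom = seg@chrom, cellId = seg@cellId)
}

#' First-order Wasserstein distance between two 1-D samples
#'
#' \eqn{W_1 = \int |F_a - F_b|\,dx} over the empirical CDFs; exact.
#'
#' @param a,b numeric samples.
#' @export
wasserstein1 <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  if (length(pts) == 1L) return(0)
  Fa <- ecdf(a)(pts); Fb <- ecdf(b)(pts)
  m <- length(pts)
  sum(abs(Fa[-m] - Fb[-m]) * diff(pts))
}

#' Mean Wasserstein dissimilarity between size distributions
#'
#' \eqn{D = (1/C)\sum_i W_1(\mu_i, \nu_i)} over chromosomes; chromosomes
#' with an empty size list on either side are skipped (C adjusted) with a
#' message.
#'
#' @param generatedSizes,referenceSizes lists of numeric size vectors
#'   (parallel, one per chromosome), sizes in bins.
#' @export
wassersteinDissimilarity <- function(generatedSizes, referenceSizes) {
  stopifnot(length(generatedSizes) == length(referenceSizes))
  keep <- vapply(seq_along(generatedSizes), function(i)
    length(generatedSizes[[i]]) > 0 && length(referenceSizes[[i]]) > 0,
    logical(1))
  if (!any(keep)) stopf("no chromosome with non-empty size lists")
  if (any(!keep))
    message(sprintf("skipping %d chromosome(s) with empty size lists",
                    sum(!keep)))
  mean(vapply(which(keep), function(i)
    wasserstein1(generatedSizes[[i]], referenceSizes[[i]]), numeric(1)))
}

#' Dynamic selection of the average TLD size
#'
#' Segments a sampled subset of chromosome graphs at every candidate
#' average size in \code{candidates} and picks the size minimizing the
#' mean Wasserstein distance between the generated and reference TLD size
#' distributions (ties break to the smaller size).
#'
#' @param embeddings list of per-graph bin-embedding matrices.
#' @param referenceSizes list of reference TAD size vectors (bins), one
#'   per graph (recycle a single reference track across graphs upstream).
#' @param candidates candidate average sizes in bins (default 5:100).
#' @param sampleSize number of graphs sampled (default min(20, all)).
#' @param seed sampling seed. @param pcaDims PCA dims for segmentation.
#' @param resolution bin size in bp.
#' @return list(candidates, dissimilarity, optimum).
#' @export
selectTldSize <- function(embeddings, referenceSizes, candidates = 5:100,
                          sampleSize = NULL, seed = 1L, pcaDims = 16L,
                          resolution = 10000L) {
  stopifnot(length(embeddings) >= 1L,
            length(referenceSizes) == length(embeddings))
  if (is.null(sampleSize)) sampleSize <- min(20L, length(embeddings))
  sel <- withSeed(seed, sample.int(length(embeddings),
                                   min(sampleSize, length(embeddings))))
  embs <- lapply(embeddings[sel], function(z)
    reduceEmbedding(as.matrix(z), pcaDims))
  refs <- referenceSizes[sel]
  D <- vapply(candidates, function(s) {
    gen <- lapply(embs, function(z) {
      ncl <- nClustersForChrom(nrow(z) * resolution, s, resolution)
      as.numeric(segmentByWard(z, min(ncl, nrow(z))))
    })
    wassersteinDissimilarity(gen, refs)
  }, numeric(1))
  list(candidates = candidates, dissimilarity = D,
       optimum = candidates[which.min(D)])
}

#' Filter TLDs to the 100 kb - 1 Mb size window
#'
#' Returns segment sizes (bins) restricted to sizes strictly larger than
#' 100 kb and smaller than 1 Mb, the window downstream aggregate analyses
#' require.
#'
#' @param seg a SegmentationResult. @param resolution bin size in bp.
#' @export
tldSizeFilter <- function(seg, resolution = 10000L) {
  s <- segmentSizes(seg)
  s[s * resolution > 1e5 & s * resolution < 1e6]
}

#' Consensus TLD segmentation across cells
#'
#' Builds the co-association matrix C (fraction of cells in which each
#' pair of bins shares a segment), embeds C spectrally (top
#' \code{spectralDims} eigenvectors of the symmetrically normalized
#' similarity; eigenvalue ties break by index), and applies
#' connectivity-constrained Ward clustering to the spectral embedding.
#'
#' @param segs list of per-cell \linkS4class{SegmentationResult} on one
#'   chromosome.
#' @param nClusters target consensus cluster count.
#' @param spectralDims spectral embedding dimensionality (default 16).
#' @return a consensus \linkS4class{SegmentationResult}.
#' @export
consensusTlds <- function(segs, nClusters, spectralDims = 16L) {
  stopifnot(length(segs) >= 2L)
  C <- coAssociation(segs)
  emb <- spectralEmbed(C, spectralDims)
  seg <- constrainedSegmentation(emb, nClusters, pcaDims = ncol(emb),
                                 chrom = segs[[1]]@chrom,
                                 cellId = "consensus")
  seg
}

## Spectral embedding of a similarity matrix: top-k eigenvectors of
## D^{-1/2} C D^{-1/2}, rows scaled by D^{-1/2} (diffusion-map style
## rescaling keeps within-block rows constant for block-constant C).
spectralEmbed <- function(C, k) {
  deg <- rowSums(C)
  deg[deg <= 0] <- 1
  s <- 1 / sqrt(deg)
  M <- C * (s %o% s)
  eg <- eigen(M, symmetric = TRUE)
  ## drop the (numerically) null space: its eigenvectors are arbitrary
  ## rotations that would add spurious within-block variation
  rank <- sum(eg$values > 1e-8 * max(eg$values))
  k <- min(k, max(rank, 1L))
  eg$vectors[, seq_len(k), drop = FALSE] * s
}

#' Co-association matrix of a set of segmentations
#' @param segs list of SegmentationResult sharing one chromosome.
#' @return n x n matrix with entries in [0, 1], unit diagonal.
#' @export
coAssociation <- function(segs) {
  n <- segs[[1]]@nBins
  C <- matrix(0, n, n)
  for (s in segs) {
    lab <- rep(seq_along(s@segments), IRanges::width(s@segments))
    C <- C + outer(lab, lab, "==")
  }
  C / length(segs)
}
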