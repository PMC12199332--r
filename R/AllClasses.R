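#' ContactGraph: one chromosome of one cell as a weighted graph over bins
#'
#' A single cis contact map, stored sparsely. Bins (10 kb by default) are
#' graph nodes indexed from 0; contacts are undirected weighted edges kept
#' in upper-triangle canonical form (\code{u <= v}).
#'
#' @slot cellId character cell identifier.
#' @slot chrom character chromosome name.
#' @slot resolution integer bin size in bp.
#' @slot nBins integer number of bins N.
#' @slot edges data.frame with integer columns \code{u}, \code{v}
#'   (0-based bin indices, \code{u <= v}) and numeric \code{w}
#'   (non-negative count; fractional after KNN enhancement).
#'
#' @exportClass ContactGraph
setClass("ContactGraph",
  representation(cellId = "character", chrom = "character",
                 resolution = "integer", nBins = "integer",
                 edges = "data.frame"))

setValidity("ContactGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("u", "v", "w") %in% names(e)))
    return("edges must have columns u, v, w")
  if (length(object@nBins) != 1L || object@nBins < 1L)
    msg <- c(msg, "nBins must be a positive scalar")
  if (nrow(e)) {
    if (any(e$u < 0L) || any(e$v >= object@nBins))
      msg <- c(msg, "bin indices out of range [0, nBins)")
    if (any(e$u > e$v))
      msg <- c(msg, "edges must be upper-triangle canonical (u <= v)")
    if (anyDuplicated(pairKey(e$u, e$v, object@nBins)))
      msg <- c(msg, "duplicate (u, v) edge keys")
    if (any(!is.finite(e$w)) || any(e$w < 0))
      msg <- c(msg, "weights must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' NodeFeatureMatrix: sequence-derived per-bin features
#'
#' The N x F node feature matrix of one chromosome: canonical k-mer counts
#' followed by motif-count columns. Rows align 1:1 with ContactGraph bins.
#'
#' @slot chrom character chromosome name.
#' @slot values numeric matrix (N x F) with feature names as colnames.
#'
#' @exportClass NodeFeatureMatrix
setClass("NodeFeatureMatrix",
  representation(chrom = "character", values = "matrix"))

setValidity("NodeFeatureMatrix", function(object) {
  if (any(!is.finite(object@values))) "values must be finite" else TRUE
})

#' LatentEmbedding: per-bin latent Gaussian parameters and sample
#'
#' Output of the variational encoder: per-bin posterior mean \code{mu},
#' log standard deviation \code{logSigma}, and the sample \code{z}
#' (reparameterized during training; equal to \code{mu} at inference).
#'
#' @slot mu,logSigma,z numeric matrices (N x latent dim).
#' @exportClass LatentEmbedding
setClass("LatentEmbedding",
  representation(mu = "matrix", logSigma = "matrix", z = "matrix"))

#' SegmentationResult: ordered contiguous TLD segments of one chromosome
#'
#' @slot chrom character chromosome name.
#' @slot cellId character cell id or "consensus".
#' @slot segments an \link[IRanges]{IRanges} of half-open bin intervals
#'   (stored 1-based closed internally; \code{segmentTable} exposes the
#'   0-based half-open convention), partitioning \code{[0, nBins)}.
#' @slot nBins integer.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(chrom = "character", cellId = "character",
                 segments = "ANY", nBins = "integer"))

setValidity("SegmentationResult", function(object) {
  s <- object@segments
  st <- IRanges::start(s); en <- IRanges::end(s)
  if (st[1] != 1L || en[length(en)] != object@nBins ||
      (length(st) > 1L && any(st[-1] != en[-length(en)] + 1L)))
    "segments must be contiguous and partition [0, nBins)" else TRUE
})

#' CompartmentTrack: signed per-bin compartment posterior
#'
#' Per-bin score in [-1, 1]: the GC-oriented posterior difference
#' gamma(A) - gamma(B); positive means compartment A.
#'
#' @slot chrom character; @slot cellId character ("consensus" allowed).
#' @slot score numeric vector, one entry per bin.
#' @exportClass CompartmentTrack
setClass("CompartmentTrack",
  representation(chrom = "character", cellId = "character",
                 score = "numeric"))

setValidity("CompartmentTrack", function(object) {
  if (any(abs(object@score) > 1 + 1e-9)) "|score| must be <= 1" else TRUE
})

#' CompartmentHMM: two-state diagonal-Gaussian hidden Markov model
#'
#' @slot means 2 x d matrix of state emission means.
#' @slot vars 2 x d matrix of diagonal emission variances (positive).
#' @slot transition 2 x 2 row-stochastic matrix.
#' @slot initial length-2 probability vector.
#' @slot logLik numeric final training log-likelihood.
#' @exportClass CompartmentHMM
setClass("CompartmentHMM",
  representation(means = "matrix", vars = "matrix",
                 transition = "matrix", initial = "numeric",
                 logLik = "numeric"))

setValidity("CompartmentHMM", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@transition) - 1) > 1e-6))
    msg <- c(msg, "transition rows must sum to 1")
  if (any(object@vars <= 0)) msg <- c(msg, "variances must be positive")
  if (length(msg)) msg else TRUE
})

#' VGAEModel: multi-task variational graph autoencoder
#'
#' Holds the GraphSAGE encoder and the twin edge decoders (contact
#' reconstruction Phi, loop classification Theta) as parameter lists,
#' plus the training configuration and per-epoch loss log.
#'
#' @slot params named list of weight matrices / bias vectors.
#' @slot config named list (dims, lr, weightDecay, dropout, patience, ...).
#' @slot trained logical.
#' @slot trainingLog data.frame with per-epoch loss components.
#' @exportClass VGAEModel
setClass("VGAEModel",
  representation(params = "list", config = "list", trained = "logical",
                 trainingLog = "data.frame"))

#' SyntheticTruth: ground-truth architecture of a simulated chromosome
#'
#' @slot nBins integer chromosome length in 10 kb bins.
#' @slot loops data.frame(u, v) planted loop bin pairs, 10-100 bins apart.
#' @slot domains an IRanges partition of the chromosome into domains.
#' @slot compartments character per-bin label in {"A","B"}, blocks >= 10 bins.
#' @slot cellType character; @slot seed integer.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(nBins = "integer", loops = "data.frame",
                 domains = "ANY", compartments = "character",
                 cellType = "character", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  d <- object@loops$v - object@loops$u
  if (nrow(object@loops) && (any(d < 10L) || any(d > 100L)))
    msg <- c(msg, "loop separations must lie in [10, 100] bins")
  st <- IRanges::start(object@domains); en <- IRanges::end(object@domains)
  if (st[1] != 1L || en[length(en)] != object@nBins ||
      (length(st) > 1L && any(st[-1] != en[-length(en)] + 1L)))
    msg <- c(msg, "domains must partition [0, nBins)")
  r <- rle(object@compartments)
  if (any(r$lengths < 10L))
    msg <- c(msg, "compartment blocks must be >= 10 bins")
  if (length(msg)) msg else TRUE
})

#' SyntheticGenome: simulated DNA sequence with planted CTCF motifs
#'
#' @slot sequence a \link[Biostrings]{DNAStringSet} of one chromosome.
#' @slot chrom character chromosome name.
#' @slot ctcfPositions integer bin indices carrying a planted CTCF motif.
#' @slot gcByBin numeric per-bin GC fraction in [0, 1].
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
  representation(sequence = "ANY", chrom = "character",
                 ctcfPositions = "integer", gcByBin = "numeric"))
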