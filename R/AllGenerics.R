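#' @rdname ContactGraph-class
#' @param object,x a ContactGraph (or other scArch object)
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname ContactGraph-class
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))

#' @rdname ContactGraph-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname ContactGraph-class
#' @export
setGeneric("contactEdges", function(x) standardGeneric("contactEdges"))

#' @rdname ContactGraph-class
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' @rdname ContactGraph-class
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))

#' @rdname SegmentationResult-class
#' @param x a SegmentationResult
#' @export
setGeneric("boundaryBins", function(x) standardGeneric("boundaryBins"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname CompartmentTrack-class
#' @param x a CompartmentTrack
#' @export
setGeneric("compartmentScore", function(x) standardGeneric("compartmentScore"))

setMethod("cellId", "ContactGraph", function(x) x@cellId)
setMethod("chrom", "ContactGraph", function(x) x@chrom)
setMethod("nBins", "ContactGraph", function(x) x@nBins)
setMethod("contactEdges", "ContactGraph", function(x) x@edges)
setMethod("totalContacts", "ContactGraph", function(x) sum(x@edges$w))

#' @describeIn ContactGraph-class dense-indexable symmetric sparse matrix
#'   (class \code{dgCMatrix}) of the map; 1-based dims, bin b at row b + 1.
setMethod("contactMatrix", "ContactGraph", function(x) {
  e <- x@edges
  m <- Matrix::sparseMatrix(i = e$u + 1L, j = e$v + 1L, x = e$w,
                            dims = c(x@nBins, x@nBins), symmetric = TRUE)
  methods::as(m, "generalMatrix")
})

setMethod("show", "ContactGraph", function(object) {
  cat(sprintf("ContactGraph cell=%s chrom=%s | %d bins @ %d bp | %d edges, mass %.1f\n",
              object@cellId, object@chrom, object@nBins, object@resolution,
              nrow(object@edges), sum(object@edges$w)))
})

setMethod("chrom", "SegmentationResult", function(x) x@chrom)
setMethod("cellId", "SegmentationResult", function(x) x@cellId)
setMethod("nBins", "SegmentationResult", function(x) x@nBins)

#' @describeIn SegmentationResult-class segment start bins excluding bin 0
#'   (0-based bin indices).
setMethod("boundaryBins", "SegmentationResult", function(x) {
  st <- IRanges::start(x@segments)
  if (length(st) > 1L) st[-1] - 1L else integer()
})

#' @describeIn SegmentationResult-class data.frame of 0-based half-open bin
#'   intervals (columns \code{startBin}, \code{endBin}, exclusive end).
setMethod("segmentTable", "SegmentationResult", function(x) {
  data.frame(chrom = x@chrom,
             startBin = IRanges::start(x@segments) - 1L,
             endBin = IRanges::end(x@segments))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult %s/%s: %d segments over %d bins\n",
              object@cellId, object@chrom, length(object@segments),
              object@nBins))
})

setMethod("chrom", "CompartmentTrack", function(x) x@chrom)
setMethod("cellId", "CompartmentTrack", function(x) x@cellId)
setMethod("compartmentScore", "CompartmentTrack", function(x) x@score)

setMethod("show", "CompartmentTrack", function(object) {
  cat(sprintf("CompartmentTrack %s/%s: %d bins, %.0f%% A (score > 0)\n",
              object@cellId, object@chrom, length(object@score),
              100 * mean(object@score > 0)))
})

setMethod("show", "CompartmentHMM", function(object) {
  cat(sprintf("CompartmentHMM: 2 states x %d dims, logLik %.2f\n",
              ncol(object@means), object@logLik))
})

setMethod("show", "VGAEModel", function(object) {
  cat(sprintf("VGAEModel (%s): F=%d -> 128 -> 64; decoders [96,64,16,1]; %d epochs logged\n",
              if (object@trained) "trained" else "untrained",
              object@config$featureDim, nrow(object@trainingLog)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (%s): %d bins, %d loops, %d domains, %d compartment blocks\n",
              object@cellType, object@nBins, nrow(object@loops),
              length(object@domains), length(rle(object@compartments)$lengths)))
})

setMethod("show", "SyntheticGenome", function(object) {
  cat(sprintf("SyntheticGenome %s: %d bp, %d CTCF bins, mean GC %.3f\n",
              object@chrom, sum(Biostrings::width(object@sequence)),
              length(object@ctcfPositions), mean(object@gcByBin)))
})

#' Construct a ContactGraph from raw edge triples
#'
#' Canonicalizes to the upper triangle and aggregates duplicate pairs.
#'
#' @param u,v integer 0-based bin indices (any order).
#' @param w numeric non-negative counts.
#' @param nBins integer number of bins.
#' @param cellId,chrom,resolution identifiers (resolution in bp).
#' @return a \linkS4class{ContactGraph}.
#' @export
ContactGraph <- function(u, v, w, nBins, cellId = "cell", chrom = "chr1",
                         resolution = 10000L) {
  uu <- pmin(u, v); vv <- pmax(u, v)
  dt <- data.table::data.table(u = as.integer(uu), v = as.integer(vv),
                               w = as.numeric(w))
  dt <- dt[, list(w = sum(w)), by = c("u", "v")]
  data.table::setorder(dt, u, v)
  methods::new("ContactGraph", cellId = cellId, chrom = chrom,
               resolution = as.integer(resolution), nBins = as.integer(nBins),
               edges = as.data.frame(dt))
}

#' Construct a SegmentationResult from segment lengths or boundaries
#'
#' @param sizes integer segment sizes in bins (must sum to nBins), or NULL.
#' @param boundaries 0-based boundary bins (segment starts excluding 0),
#'   used when \code{sizes} is NULL.
#' @param nBins,chrom,cellId metadata.
#' @return a \linkS4class{SegmentationResult}.
#' @export
SegmentationResult <- function(sizes = NULL, boundaries = NULL, nBins,
                               chrom = "chr1", cellId = "cell") {
  if (is.null(sizes)) {
    b <- sort(unique(as.integer(boundaries)))
    starts <- c(0L, b)
    sizes <- diff(c(starts, nBins))
  }
  stopifnot(sum(sizes) == nBins, all(sizes > 0L))
  en <- cumsum(as.integer(sizes))
  st <- c(1L, head(en, -1L) + 1L)
  methods::new("SegmentationResult", chrom = chrom, cellId = cellId,
               segments = IRanges::IRanges(start = st, end = en),
               nBins = as.integer(nBins))
}

#' Segment sizes in bins
#' @param x a SegmentationResult
#' @return integer vector of segment widths (bins).
#' @export
segmentSizes <- function(x) IRanges::width(x@segments)
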