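## On-disk formats. All genomic coordinates are 0-based half-open; bins are
## indexed from 0; bin index = floor(start / resolution). Tabular formats go
## through data.table with explicit column contracts; FASTA via Biostrings.

#' Read a sparse-triplet contact map file into a ContactGraph
#'
#' Expects whitespace/tab-separated lines \code{chrom bin1_start bin2_start
#' count} with 0-based bp starts on 10 kb boundaries. Duplicate and
#' transposed pairs are aggregated into canonical upper-triangle edges.
#' Trans-chromosomal rows (a second chromosome column variant) are not
#' representable in this dialect; rows on chromosomes other than
#' \code{chrom} are dropped with a warning.
#'
#' @param path file path.
#' @param cellId cell identifier (defaults to the file name sans extension).
#' @param chrom chromosome to load (default: first chromosome in the file).
#' @param resolution bin size in bp.
#' @param nBins declared number of bins; inferred from the data when NULL.
#' @return a \linkS4class{ContactGraph}.
#' @export
readContactMap <- function(path, cellId = NULL, chrom = NULL,
                           resolution = 10000L, nBins = NULL) {
  if (is.null(cellId))
    cellId <- sub("\\.[^.]*$", "", basename(path))
  dt <- if (file.size(path) == 0) data.table::data.table() else tryCatch(
    data.table::fread(path, header = FALSE,
                      col.names = c("chrom", "s1", "s2", "count"),
                      colClasses = list(character = 1)),
    error = function(e) stopf("parse error in %s: %s", path,
                              conditionMessage(e)))
  if (nrow(dt) == 0L) {
    if (is.null(nBins)) nBins <- 1L
    return(ContactGraph(integer(), integer(), numeric(), nBins = nBins,
                        cellId = cellId, chrom = chrom %||% "chr?",
                        resolution = resolution))
  }
  if (is.null(chrom)) chrom <- dt$chrom[1]
  drop <- dt$chrom != chrom
  if (any(drop)) {
    warnf("%s: dropping %d rows on other chromosomes (cis maps only)",
          path, sum(drop))
    dt <- dt[!drop]
  }
  bad <- which(dt$count < 0)
  if (length(bad))
    stopf("%s: negative count at line %d", path, bad[1])
  u <- dt$s1 %/% resolution; v <- dt$s2 %/% resolution
  if (is.null(nBins)) nBins <- max(u, v) + 1L
  if (any(u >= nBins | v >= nBins)) {
    bad <- which(u >= nBins | v >= nBins)[1]
    stopf("%s: coordinate beyond chromosome length at line %d", path, bad)
  }
  ContactGraph(u, v, dt$count, nBins = nBins, cellId = cellId,
               chrom = chrom, resolution = resolution)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a set of contact map files
#' @param paths character vector of triplet files (one per cell/chrom).
#' @param resolution bin size in bp.
#' @param nBins declared bin count applied to all files (recommended so
#'   cells share a common N).
#' @param chrom chromosome to load.
#' @return list of \linkS4class{ContactGraph}.
#' @export
readContactMaps <- function(paths, resolution = 10000L, nBins = NULL,
                            chrom = NULL) {
  lapply(paths, readContactMap, resolution = resolution, nBins = nBins,
         chrom = chrom)
}

#' Write a ContactGraph as sparse triplet text
#' @param graph a ContactGraph.
#' @param path output path.
#' @export
writeContactMap <- function(graph, path) {
  e <- graph@edges
  dt <- data.table::data.table(
    chrom = graph@chrom,
    s1 = e$u * graph@resolution,
    s2 = e$v * graph@resolution,
    count = e$w)
  data.table::setorder(dt, s1, s2)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write loop calls as BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score, 0-based
#' half-open bins, probability in the score column, sorted by
#' (chrom, start1, start2).
#'
#' @param calls data.frame with columns \code{chrom}, \code{u}, \code{v}
#'   (bin indices) and \code{probability}.
#' @param path output path.
#' @param resolution bin size in bp.
#' @export
writeLoopsBedpe <- function(calls, path, resolution = 10000L) {
  dt <- data.table::data.table(
    chrom1 = calls$chrom, start1 = calls$u * resolution,
    end1 = (calls$u + 1L) * resolution,
    chrom2 = calls$chrom, start2 = calls$v * resolution,
    end2 = (calls$v + 1L) * resolution,
    name = ".", score = calls$probability)
  data.table::setorder(dt, chrom1, start1, start2)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop file
#' @param path BEDPE path. @param resolution bin size in bp.
#' @return data.frame(chrom, u, v, probability); probability NA when the
#'   score column is ".".
#' @export
readLoopsBedpe <- function(path, resolution = 10000L) {
  dt <- if (file.size(path) == 0) data.table::data.table() else
    data.table::fread(path, header = FALSE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), u = integer(), v = integer(),
                      probability = numeric()))
  names(dt)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  prob <- if (ncol(dt) >= 8) suppressWarnings(as.numeric(dt[[8]])) else
    rep(NA_real_, nrow(dt))
  data.frame(chrom = dt$chrom1,
             u = as.integer(dt$start1 %/% resolution),
             v = as.integer(dt$start2 %/% resolution),
             probability = prob)
}

#' Write a segmentation as BED
#' @param seg a \linkS4class{SegmentationResult}.
#' @param path output path. @param resolution bin size in bp.
#' @export
writeSegmentsBed <- function(seg, path, resolution = 10000L) {
  tab <- segmentTable(seg)
  dt <- data.table::data.table(
    chrom = tab$chrom, start = tab$startBin * resolution,
    end = tab$endBin * resolution,
    name = sprintf("%s_tld%03d", seg@cellId, seq_len(nrow(tab))))
  data.table::setorder(dt, chrom, start)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file of segments/intervals
#' @param path BED path. @param resolution bin size in bp.
#' @return data.frame(chrom, startBin, endBin) with 0-based half-open bins.
#' @export
readSegmentsBed <- function(path, resolution = 10000L) {
  dt <- if (file.size(path) == 0) data.table::data.table() else
    data.table::fread(path, header = FALSE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), startBin = integer(),
                      endBin = integer()))
  data.frame(chrom = dt[[1]],
             startBin = as.integer(dt[[2]] %/% resolution),
             endBin = as.integer(ceiling(dt[[3]] / resolution)))
}

#' Write a per-bin score track as bedGraph
#' @param track a \linkS4class{CompartmentTrack} (or any per-bin numeric
#'   via \code{score}/\code{chrom} arguments).
#' @param path output path. @param resolution bin size in bp.
#' @export
writeTrackBedgraph <- function(track, path, resolution = 10000L) {
  s <- compartmentScore(track)
  dt <- data.table::data.table(
    chrom = chrom(track),
    start = (seq_along(s) - 1L) * resolution,
    end = seq_along(s) * resolution,
    score = s)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph path. @param resolution bin size in bp.
#' @param cellId identifier for the returned track.
#' @return a \linkS4class{CompartmentTrack}.
#' @export
readTrackBedgraph <- function(path, resolution = 10000L,
                              cellId = "consensus") {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  o <- order(dt$start)
  methods::new("CompartmentTrack", chrom = dt$chrom[1], cellId = cellId,
               score = as.numeric(dt$score[o]))
}

#' Write cell labels as a 2-column TSV
#' @param cellIds,labels parallel character vectors. @param path output.
#' @export
writeCellLabels <- function(cellIds, labels, path) {
  data.table::fwrite(data.table::data.table(cell = cellIds, label = labels),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a 2-column cell label TSV
#' @param path input path.
#' @return named character vector (names = cell ids).
#' @export
readCellLabels <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("cell", "label"),
                          colClasses = "character")
  setNames(dt$label, dt$cell)
}

#' Write a synthetic genome (FASTA) and its annotation (BED) files
#'
#' @param genome a \linkS4class{SyntheticGenome}.
#' @param fastaPath,ctcfBedPath output paths (NULL to skip either).
#' @param resolution bin size in bp.
#' @export
writeGenomeFiles <- function(genome, fastaPath = NULL, ctcfBedPath = NULL,
                             resolution = 10000L) {
  if (!is.null(fastaPath))
    Biostrings::writeXStringSet(genome@sequence, fastaPath)
  if (!is.null(ctcfBedPath)) {
    off <- (resolution - nchar(CTCF_CONSENSUS)) %/% 2
    dt <- data.table::data.table(
      chrom = genome@chrom,
      start = genome@ctcfPositions * resolution + off,
      end = genome@ctcfPositions * resolution + off + nchar(CTCF_CONSENSUS))
    data.table::setorder(dt, start)
    data.table::fwrite(dt, ctcfBedPath, sep = "\t", col.names = FALSE)
  }
  invisible(NULL)
}

#' Write truth annotations (domains BED, compartments BED, loops BEDPE)
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param domainsBed,compartmentsBed,loopsBedpe output paths (NULL skips).
#' @param chrom chromosome name. @param resolution bin size in bp.
#' @export
writeTruthFiles <- function(truth, domainsBed = NULL, compartmentsBed = NULL,
                            loopsBedpe = NULL, chrom = "chrS",
                            resolution = 10000L) {
  if (!is.null(domainsBed)) {
    seg <- methods::new("SegmentationResult", chrom = chrom, cellId = "truth",
                        segments = truth@domains, nBins = truth@nBins)
    writeSegmentsBed(seg, domainsBed, resolution)
  }
  if (!is.null(compartmentsBed)) {
    r <- rle(truth@compartments)
    en <- cumsum(r$lengths); st <- c(0L, head(en, -1L))
    dt <- data.table::data.table(chrom = chrom, start = st * resolution,
                                 end = en * resolution, name = r$values)
    data.table::fwrite(dt, compartmentsBed, sep = "\t", col.names = FALSE)
  }
  if (!is.null(loopsBedpe)) {
    calls <- data.frame(chrom = chrom, u = truth@loops$u, v = truth@loops$v,
                        probability = 1)
    writeLoopsBedpe(calls, loopsBedpe, resolution)
  }
  invisible(NULL)
}
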