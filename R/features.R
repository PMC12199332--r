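## Sequence-view node features: canonical k-mer counts and motif counts per
## 10 kb bin, plus the GC and CTCF annotations the TLD/compartment callers
## consume.

binViews <- function(genome, chrom, resolution) {
  seqs <- genome@sequence
  if (!chrom %in% names(seqs))
    stopf("chromosome %s absent from genome", chrom)
  s <- seqs[[chrom]]
  n <- ceiling(length(s) / resolution)
  starts <- (seq_len(n) - 1L) * resolution + 1L
  ends <- pmin(starts + resolution - 1L, length(s))
  Biostrings::Views(s, start = starts, end = ends)
}

## Map every k-mer to its canonical representative (lexicographic min of the
## k-mer and its reverse complement).
canonicalKmerMap <- function(k) {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  list(all = kmers, canonical = canon, levels = sort(unique(canon)))
}

#' Canonical k-mer counts per bin
#'
#' Counts every k-mer in each bin's sequence with a sliding window, merging
#' each k-mer with its reverse complement (canonical collapsing). Windows
#' containing non-ACGT letters (e.g. N) are skipped.
#'
#' @param genome a \linkS4class{SyntheticGenome} (or any object with a
#'   \code{DNAStringSet} in \code{@sequence}).
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param k k-mer size, 1..6 (default 4).
#' @return integer matrix, bins x canonical k-mers.
#' @export
kmerCounts <- function(genome, chrom, resolution = 10000L, k = 4L) {
  stopifnot(k >= 1L, k <= 6L)
  v <- binViews(genome, chrom, resolution)
  raw <- Biostrings::oligonucleotideFrequency(v, width = k)
  map <- canonicalKmerMap(k)
  grp <- factor(map$canonical, levels = map$levels)
  out <- t(rowsum(t(raw), grp))
  storage.mode(out) <- "numeric"
  out
}

#' Motif counts per bin (midpoint rule)
#'
#' Each motif interval is assigned to the bin containing its midpoint
#' (for an interval \code{[s, e)} the midpoint is \code{(s + e - 1) \%/\% 2}),
#' which is unambiguous for motifs spanning a bin border.
#'
#' @param motifs data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open bp), e.g. from a CTCF BED file.
#' @param chrom chromosome name.
#' @param nBins number of bins.
#' @param resolution bin size in bp.
#' @return integer vector of per-bin counts.
#' @export
motifCounts <- function(motifs, chrom, nBins, resolution = 10000L) {
  counts <- integer(nBins)
  if (is.null(motifs) || nrow(motifs) == 0L) return(counts)
  m <- motifs[motifs$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) return(counts)
  mid <- (m$start + m$end - 1L) %/% 2L
  b <- mid %/% resolution
  b <- b[b >= 0L & b < nBins]
  tab <- tabulate(b + 1L, nbins = nBins)
  as.integer(tab)
}

#' Motif coordinate table of a synthetic genome's planted CTCF sites
#' @param genome a \linkS4class{SyntheticGenome}.
#' @param resolution bin size in bp.
#' @return data.frame(chrom, start, end) of planted motif intervals.
#' @export
syntheticMotifTable <- function(genome, resolution = 10000L) {
  off <- (resolution - nchar(CTCF_CONSENSUS)) %/% 2
  data.frame(chrom = genome@chrom,
             start = genome@ctcfPositions * resolution + off,
             end = genome@ctcfPositions * resolution + off +
               nchar(CTCF_CONSENSUS))
}

#' Read a BED motif file
#' @param path BED path (chrom, start, end in the first three columns).
#' @return data.frame(chrom, start, end).
#' @export
readMotifBed <- function(path) {
  dt <- if (file.size(path) == 0) data.table::data.table() else
    data.table::fread(path, header = FALSE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  data.frame(chrom = dt[[1]], start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]))
}

#' Per-bin GC fraction
#'
#' @param genome genome object; @param chrom chromosome;
#' @param resolution bin size in bp.
#' @return numeric vector in [0, 1]; all-N bins get 0 and are flagged in
#'   the \code{"allN"} attribute.
#' @export
gcContent <- function(genome, chrom, resolution = 10000L) {
  v <- binViews(genome, chrom, resolution)
  acgt <- rowSums(Biostrings::letterFrequency(v, c("A", "C", "G", "T")))
  gc <- rowSums(Biostrings::letterFrequency(v, c("G", "C")))
  out <- ifelse(acgt > 0, gc / acgt, 0)
  attr(out, "allN") <- acgt == 0
  out
}

#' Assemble the node feature matrix (k-mers then motifs)
#'
#' @param genome genome object. @param chrom chromosome.
#' @param motifs motif data.frame (see \code{\link{motifCounts}}). When
#'   NULL and the genome is a \linkS4class{SyntheticGenome} carrying
#'   planted motif positions, those are used; otherwise the motif column
#'   is zero.
#' @param resolution bin size in bp. @param k k-mer size.
#' @return a \linkS4class{NodeFeatureMatrix} with k-mer columns followed
#'   by a \code{"CTCF"} motif-count column.
#' @export
buildNodeFeatures <- function(genome, chrom, motifs = NULL,
                              resolution = 10000L, k = 4L) {
  km <- kmerCounts(genome, chrom, resolution, k)
  if (is.null(motifs) && methods::is(genome, "SyntheticGenome") &&
      length(genome@ctcfPositions))
    motifs <- syntheticMotifTable(genome, resolution)
  ct <- motifCounts(motifs, chrom, nrow(km), resolution)
  values <- cbind(km, CTCF = ct)
  methods::new("NodeFeatureMatrix", chrom = chrom, values = values)
}

#' Standardize feature columns
#'
#' Per-column zero mean / unit variance (sample variance); constant
#' columns become all-zero. When \code{center}/\code{scale} vectors are
#' supplied (fitted on a training genome) they are reused, so inference on
#' another genome never leaks its own statistics.
#'
#' @param X numeric matrix or \linkS4class{NodeFeatureMatrix}.
#' @param center,scale optional fitted statistics to reuse.
#' @return matrix with attributes \code{"center"} and \code{"scale"}.
#' @export
normalizeFeatures <- function(X, center = NULL, scale = NULL) {
  if (methods::is(X, "NodeFeatureMatrix")) X <- X@values
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[scale < 1e-12] <- 1
  }
  out <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  consts <- apply(out, 2, function(col) max(col) - min(col) < 1e-12)
  out[, consts] <- 0
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}
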