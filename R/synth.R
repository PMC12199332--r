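## Synthetic single-cell Hi-C simulator: distance-decay contact intensity
## with planted loops, domains and compartments, plus a synthetic genome
## whose GC content and CTCF motif placement make the downstream callers'
## assumptions hold (GC-orientable compartments, CTCF-enriched boundaries
## and loop anchors).

## Fixed 19-mer used as the planted CTCF consensus motif.
CTCF_CONSENSUS <- "CCACCAGGGGGCGCTAGTG"

#' Generate a ground-truth chromosome architecture
#'
#' Draws a domain partition, alternating A/B compartment blocks and a set
#' of loop bin pairs for one simulated chromosome of \code{nBins} 10 kb
#' bins. Domain sizes are drawn around \code{meanDomainSize} bins;
#' compartment blocks around \code{meanCompartmentBlock} bins (never below
#' 10); loops are uniform pairs with separation 10-100 bins.
#'
#' @param nBins integer chromosome length in bins.
#' @param nLoops integer number of planted loops.
#' @param meanDomainSize mean domain size in bins (default 20 = 200 kb).
#' @param meanCompartmentBlock mean compartment block size in bins.
#' @param cellType label carried by cells simulated from this truth.
#' @param seed integer RNG seed.
#' @param loops optional data.frame(u, v) to use instead of random loops.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
simulateTruth <- function(nBins, nLoops = 50L, meanDomainSize = 20L,
                          meanCompartmentBlock = 30L, cellType = "type1",
                          seed = 1L, loops = NULL) {
  withSeed(seed, {
    ## draw a partition whose realized mean size equals the target: fix
    ## the domain count, draw relative sizes, rescale to sum to nBins
    lo <- max(5L, round(meanDomainSize / 2)); hi <- round(meanDomainSize * 1.5)
    nDom <- max(1L, as.integer(round(nBins / meanDomainSize)))
    raw <- runif(nDom, lo, hi)
    bounds <- round(cumsum(raw) * nBins / sum(raw))
    sizes <- as.integer(diff(c(0, bounds)))
    while (any(sizes < max(2L, lo %/% 2)) && length(sizes) > 1L) {
      j <- which.min(sizes)
      k <- if (j == 1L) 2L else j - 1L
      sizes[k] <- sizes[k] + sizes[j]
      sizes <- sizes[-j]
    }
    blocks <- integer()
    while (sum(blocks) < nBins) {
      b <- max(10L, round(rnorm(1, meanCompartmentBlock,
                                meanCompartmentBlock / 4)))
      blocks <- c(blocks, min(b, nBins - sum(blocks)))
    }
    if (tail(blocks, 1) < 10L && length(blocks) > 1L) {
      blocks[length(blocks) - 1L] <- blocks[length(blocks) - 1L] +
        tail(blocks, 1)
      blocks <- head(blocks, -1L)
    }
    comp <- rep(rep(c("A", "B"), length.out = length(blocks)), blocks)
    if (is.null(loops)) {
      loops <- uniqueLoopPairs(nBins, nLoops)
    } else {
      loops <- data.frame(u = as.integer(pmin(loops$u, loops$v)),
                          v = as.integer(pmax(loops$u, loops$v)))
    }
    en <- cumsum(sizes); st <- c(1L, head(en, -1L) + 1L)
    methods::new("SyntheticTruth", nBins = as.integer(nBins), loops = loops,
                 domains = IRanges::IRanges(start = st, end = en),
                 compartments = comp, cellType = cellType,
                 seed = as.integer(seed))
  })
}

## Draw n distinct loop pairs with separations uniform in [10, 100] bins.
uniqueLoopPairs <- function(nBins, n) {
  got <- data.frame(u = integer(), v = integer())
  while (nrow(got) < n) {
    d <- sample(10:100, n, replace = TRUE)
    d <- d[d < nBins]
    u <- vapply(d, function(dd) sample.int(nBins - dd, 1L) - 1L, integer(1))
    got <- unique(rbind(got, data.frame(u = u, v = u + d)))
  }
  got <- got[order(got$u, got$v), , drop = FALSE][seq_len(n), , drop = FALSE]
  rownames(got) <- NULL
  got
}

#' Per-bin compartment labels of a truth
#' @param truth a SyntheticTruth
#' @return character vector ("A"/"B") of length nBins.
#' @export
compartmentLabels <- function(truth) truth@compartments

#' Domain boundary bins of a truth (segment starts excluding bin 0)
#' @param truth a SyntheticTruth
#' @export
truthBoundaries <- function(truth) {
  st <- IRanges::start(truth@domains)
  if (length(st) > 1L) st[-1] - 1L else integer()
}

#' Expected (bulk) contact intensity of a simulated chromosome
#'
#' Builds the dense non-negative intensity matrix
#' \deqn{I_{ij} = |i-j|^{a} \cdot g_d^{[same\ domain]} \cdot
#'       g_c^{[same\ compartment]} \cdot g_l^{[near\ loop]}}
#' with power-law distance decay exponent \code{a < 0}, multiplicative
#' boosts for pairs in the same domain, pairs sharing a compartment label,
#' and pairs within 1 bin of a planted loop. Symmetric, zero diagonal.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param decayExponent power-law exponent (default -1).
#' @param domainBoost,loopBoost,compartmentBoost multiplicative
#'   enrichments (all >= 1).
#' @return dense N x N matrix.
#' @export
simulateBulkIntensity <- function(truth, decayExponent = -1,
                                  domainBoost = 3, loopBoost = 20,
                                  compartmentBoost = 1.5) {
  if (!all(is.finite(c(decayExponent, domainBoost, loopBoost,
                       compartmentBoost))))
    stopf("non-finite decay/boost parameter")
  if (decayExponent >= 0) stopf("decayExponent must be < 0")
  if (min(domainBoost, loopBoost, compartmentBoost) < 1)
    stopf("boosts must be >= 1")
  n <- truth@nBins
  idx <- seq_len(n) - 1L
  dist <- abs(outer(idx, idx, "-"))
  intensity <- ifelse(dist == 0, 0, dist^decayExponent)
  domId <- rep(seq_along(truth@domains), IRanges::width(truth@domains))
  sameDom <- outer(domId, domId, "==")
  intensity <- intensity * ifelse(sameDom, domainBoost, 1)
  comp <- truth@compartments
  sameComp <- outer(comp, comp, "==")
  intensity <- intensity * ifelse(sameComp, compartmentBoost, 1)
  if (nrow(truth@loops)) {
    boost <- matrix(1, n, n)
    for (r in seq_len(nrow(truth@loops))) {
      ui <- truth@loops$u[r]; vi <- truth@loops$v[r]
      ii <- intersect(ui + (-1:1), idx); jj <- intersect(vi + (-1:1), idx)
      boost[ii + 1L, jj + 1L] <- loopBoost
      boost[jj + 1L, ii + 1L] <- loopBoost
    }
    intensity <- intensity * boost
  }
  diag(intensity) <- 0
  intensity
}

#' Downsample a bulk intensity into one sparse single-cell map
#'
#' Draws \code{contactsPerCell} bin pairs from a multinomial with
#' probabilities proportional to the upper-triangle intensity, emulating
#' the sparsity of single-cell Hi-C.
#'
#' @param intensity dense symmetric non-negative matrix.
#' @param contactsPerCell integer >= 1 total contact count.
#' @param seed RNG seed.
#' @param cellId,chrom identifiers.
#' @return a \linkS4class{ContactGraph} whose total mass equals
#'   \code{contactsPerCell}.
#' @export
downsampleToCell <- function(intensity, contactsPerCell, seed = 1L,
                             cellId = "cell", chrom = "chrS") {
  if (contactsPerCell < 1L) stopf("contactsPerCell must be >= 1")
  n <- nrow(intensity)
  ut <- upper.tri(intensity)
  p <- intensity[ut]
  if (sum(p) <= 0) stopf("all-zero intensity matrix")
  counts <- withSeed(seed,
    as.vector(stats::rmultinom(1, size = contactsPerCell, prob = p)))
  rows <- row(intensity)[ut]; cols <- col(intensity)[ut]
  nz <- counts > 0L
  ContactGraph(u = rows[nz] - 1L, v = cols[nz] - 1L, w = counts[nz],
               nBins = n, cellId = cellId, chrom = chrom)
}

#' Simulate a synthetic genome matched to a truth
#'
#' One chromosome of \code{nBins * resolution} bp. A-compartment bins are
#' drawn from a GC-rich (55\%) nucleotide pool and B bins from a GC-poor
#' (40\%) pool, so GC orientation of compartment states is identifiable.
#' A fixed 19-mer CTCF consensus is planted at the centre of every domain
#' boundary bin, every loop-anchor bin, and a 5\% random background of
#' other bins.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return a \linkS4class{SyntheticGenome}.
#' @export
simulateGenome <- function(truth, resolution = 10000L, chrom = "chrS",
                           seed = 1L) {
  n <- truth@nBins
  withSeed(seed, {
    probsA <- c(A = 0.225, C = 0.275, G = 0.275, T = 0.225)  # 55% GC
    probsB <- c(A = 0.300, C = 0.200, G = 0.200, T = 0.300)  # 40% GC
    seqs <- vapply(seq_len(n), function(b) {
      p <- if (truth@compartments[b] == "A") probsA else probsB
      paste(sample(names(p), resolution, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    bnd <- truthBoundaries(truth)
    anchors <- unique(c(truth@loops$u, truth@loops$v))
    bg <- sample.int(n, size = max(1L, round(0.05 * n))) - 1L
    ctcfBins <- sort(unique(c(bnd, anchors, bg)))
    motif <- CTCF_CONSENSUS
    off <- (resolution - nchar(motif)) %/% 2
    for (b in ctcfBins) {
      s <- seqs[b + 1L]
      substr(s, off + 1L, off + nchar(motif)) <- motif
      seqs[b + 1L] <- s
    }
    dna <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
    names(dna) <- chrom
    gc <- vapply(seqs, function(s) {
      f <- Biostrings::letterFrequency(Biostrings::DNAString(s), "GC")
      as.numeric(f) / nchar(s)
    }, numeric(1), USE.NAMES = FALSE)
    methods::new("SyntheticGenome", sequence = dna, chrom = chrom,
                 ctcfPositions = as.integer(ctcfBins), gcByBin = gc)
  })
}

#' Simulate a labelled multi-cell single-cell Hi-C dataset
#'
#' Generates \code{nCells} sparse contact maps split evenly across the
#' cell types described by \code{truths} (one
#' \linkS4class{SyntheticTruth} per type, typically sharing domains and
#' compartments but differing in planted loops), together with one
#' synthetic genome built from the first truth.
#'
#' @param nCells total number of cells.
#' @param truths list of SyntheticTruth, one per cell type.
#' @param contactsPerCell contacts drawn per cell (default 3000 per
#'   1000-bin chromosome).
#' @param seed master RNG seed.
#' @param chrom chromosome name.
#' @param decayExponent,domainBoost,loopBoost,compartmentBoost passed to
#'   \code{\link{simulateBulkIntensity}}.
#' @return list with elements \code{cells} (list of ContactGraph),
#'   \code{genome} (SyntheticGenome), \code{truths}, \code{cellTypes}
#'   (character vector parallel to cells).
#' @export
simulateDataset <- function(nCells, truths, contactsPerCell = 3000L,
                            seed = 1L, chrom = "chrS", decayExponent = -1,
                            domainBoost = 3, loopBoost = 20,
                            compartmentBoost = 1.5) {
  nTypes <- length(truths)
  if (nTypes > nCells) stopf("more cell types than cells")
  typeNames <- vapply(truths, function(t) t@cellType, character(1))
  intensities <- lapply(truths, simulateBulkIntensity,
                        decayExponent = decayExponent,
                        domainBoost = domainBoost, loopBoost = loopBoost,
                        compartmentBoost = compartmentBoost)
  typeOf <- rep(seq_len(nTypes), length.out = nCells)
  cells <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    cells[[i]] <- downsampleToCell(
      intensities[[typeOf[i]]], contactsPerCell,
      seed = deriveSeed(seed, i),
      cellId = sprintf("cell%03d", i), chrom = chrom)
  }
  genome <- simulateGenome(truths[[1]], chrom = chrom,
                           seed = deriveSeed(seed, 0L))
  list(cells = cells, genome = genome, truths = truths,
       cellTypes = typeNames[typeOf])
}

#' Simulate noisy per-cell loop call lists from truths
#'
#' Each cell detects each loop of its type's truth independently with
#' probability \code{detectProb} and additionally calls
#' \code{nBackground} false loops at uniform band separations, emulating
#' imperfect single-cell loop calling for downstream feature-encoding
#' and marker-discovery analyses.
#'
#' @param truths list of \linkS4class{SyntheticTruth} (one per type).
#' @param cellTypes character vector of type names, one entry per cell
#'   (matching \code{truth@cellType}).
#' @param detectProb per-loop detection probability (default 0.6).
#' @param nBackground false loops per cell (default 20).
#' @param seed RNG seed. @param chrom chromosome name.
#' @return list of data.frame(chrom, u, v), one per cell.
#' @export
simulateLoopCalls <- function(truths, cellTypes, detectProb = 0.6,
                              nBackground = 20L, seed = 1L,
                              chrom = "chrS") {
  typeNames <- vapply(truths, function(t) t@cellType, character(1))
  withSeed(seed, {
    lapply(cellTypes, function(ct) {
      tr <- truths[[match(ct, typeNames)]]
      keep <- runif(nrow(tr@loops)) < detectProb
      bg <- uniqueLoopPairs(tr@nBins, nBackground)
      calls <- rbind(tr@loops[keep, , drop = FALSE], bg)
      calls <- unique(calls)
      data.frame(chrom = chrom, u = calls$u, v = calls$v)
    })
  })
}

#' Build a family of truths sharing domains/compartments, differing in loops
#'
#' All types share the base truth's domain partition and compartment
#' blocks plus a common loop set; each type additionally carries
#' \code{nExclusive} type-exclusive loops. The exclusive loops of a type
#' are anchored at \code{markerAnchors} hub bins (loop-anchor re-use, as
#' at CTCF/cohesin hubs), distinct across types, so each type has a
#' planted marker-anchor signal whose per-cell loop count exceeds one.
#'
#' @param nBins chromosome length in bins.
#' @param nTypes number of cell types.
#' @param nShared shared loops; @param nExclusive per-type exclusive loops.
#' @param markerAnchors hub anchors per type carrying the exclusive loops.
#' @param seed RNG seed. @param ... passed to \code{\link{simulateTruth}}.
#' @return list of \linkS4class{SyntheticTruth}; the per-type hub bins are
#'   attached as the \code{"markerAnchors"} attribute (list of integer
#'   vectors).
#' @export
simulateTruthFamily <- function(nBins, nTypes, nShared = 30L,
                                nExclusive = 10L, markerAnchors = 5L,
                                seed = 1L, ...) {
  base <- simulateTruth(nBins, nLoops = nShared, seed = seed, ...)
  shared <- base@loops
  hubs <- withSeed(deriveSeed(seed, 101L), {
    ## hubs need room for partners on both sides where possible
    pool <- setdiff(seq(0L, nBins - 1L), c(shared$u, shared$v))
    sample(pool, nTypes * markerAnchors)
  })
  hubList <- split(hubs, rep(seq_len(nTypes), each = markerAnchors))
  truths <- lapply(seq_len(nTypes), function(t) {
    excl <- withSeed(deriveSeed(seed, 200L + t), {
      hb <- hubList[[t]]
      used <- paste(shared$u, shared$v)
      out <- data.frame(u = integer(), v = integer())
      i <- 0L
      while (nrow(out) < nExclusive) {
        i <- i + 1L
        h <- hb[(i - 1L) %% length(hb) + 1L]
        d <- sample(10:100, 1L)
        p <- if (runif(1) < 0.5 && h - d >= 0L) h - d else
          if (h + d < nBins) h + d else h - d
        if (p < 0L || p >= nBins) next
        uu <- min(h, p); vv <- max(h, p)
        key <- paste(uu, vv)
        if (key %in% used) next
        used <- c(used, key)
        out <- rbind(out, data.frame(u = uu, v = vv))
      }
      out
    })
    lt <- rbind(shared, excl)
    tr <- base
    tr@loops <- lt[order(lt$u, lt$v), , drop = FALSE]
    rownames(tr@loops) <- NULL
    tr@cellType <- sprintf("type%d", t)
    methods::validObject(tr)
    tr
  })
  attr(truths, "markerAnchors") <- hubList
  truths
}
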