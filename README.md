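# scArch

Multi-scale chromatin architecture calling from single-cell Hi-C
(scHi-C) data, in R.

scHi-C yields one sparse contact map per cell — a few thousand contacts
per chromosome — far below what bulk loop, TAD or compartment callers
need. scArch represents each chromosome of each cell as a graph (10 kb
bins as nodes, contacts as edges, sequence-derived k-mer + CTCF-motif
node features) and trains a **multi-task variational graph autoencoder**:
a three-layer GraphSAGE encoder produces a latent Gaussian per bin
(μ_u, log σ_u ∈ R^64; z_u = μ_u + σ_u ⊙ ε in training, z_u = μ_u at
inference), and two dense edge decoders on [z_u, z_v] reconstruct
contacts (Φ) and classify chromatin loops (Θ). The loss is
BCE(recon) + BCE(loop) + KL, with proximity-aware (distance-matched)
negative sampling, Adam (lr 2·10⁻⁵, weight decay 10⁻³), dropout 0.2 and
early stopping on held-out chromosomes.

From the same per-bin embeddings the package derives:

* **TAD-like domains (TLDs)** — agglomerative Ward clustering
  restricted to genomically adjacent merges (O(n²); every cluster is a
  contiguous interval), CTCF-based boundary filtering (1-D 2-means on
  motif counts, keep the high-count group), and dynamic average-size
  selection by minimizing the mean first-order Wasserstein distance
  `D = (1/C) Σ_i W₁(μ_i, ν_i)` between generated and reference TAD size
  distributions over candidate sizes 5–100 bins;
* **A/B compartments** — a 2-state diagonal-Gaussian HMM over the
  embedding sequence, with the state of higher GC content oriented as A;
  the per-bin score is γ(A) − γ(B) ∈ [−1, 1];
* **consensus calls** — mean loop probability with zero-fill across
  cells; co-association + spectral embedding + constrained clustering
  for consensus TLDs; mean GC-oriented posterior for compartments;
* **cell-identity analyses** — four 100 kb feature encodings (latent
  PC1, loop anchors, TLD boundaries, compartment scores) with
  one-vs-rest L1 linear SVM classification, and tf-idf marker
  loop-anchor discovery with Welch t-tests and Benjamini–Hochberg
  correction.

A fully labelled synthetic scHi-C simulator (power-law distance decay,
planted loops/domains/compartments, multinomial downsampling to
single-cell sparsity, and a synthetic genome with planted CTCF motifs
and compartment-coupled GC content) makes the entire framework testable
without external data.

## Tests

```r
testthat::test_dir("tests/testthat", package = "scArch",
                   load_package = "installed")
```

## A worked example

Simulate a 300-bin chromosome with 40 planted loops and ten sparse
cells (1,500 contacts each), call per-cell TLDs from a model-free
contact embedding, build the consensus segmentation, and score it
against the planted truth:

```r
library(scArch)

truth  <- simulateTruth(300, nLoops = 40, meanDomainSize = 20, seed = 1)
ds     <- simulateDataset(10, list(truth), contactsPerCell = 1500, seed = 1)
genome <- ds$genome

embs <- lapply(ds$cells, contactEmbedding)
ncl  <- nClustersForChrom(300 * 10000, avgSizeBins = 20)   # 15 clusters
ctcf <- motifCounts(syntheticMotifTable(genome), "chrS", 300)
segs <- lapply(seq_along(embs), function(i)
  ctcfBoundaryFilter(
    constrainedSegmentation(embs[[i]], ncl, chrom = "chrS",
                            cellId = sprintf("cell%03d", i)), ctcf))
cons <- consensusTlds(segs, nClusters = ncl)
boundaryAgreement(cons,
  SegmentationResult(boundaries = truthBoundaries(truth),
                     nBins = 300, chrom = "chrS"))
#> $precision
#> [1] 0.8571429
#> $recall
#> [1] 0.8571429
#> $f1
#> [1] 0.8571429
#> $nMatched
#> [1] 12
```

Twelve of the fourteen planted domain boundaries are recovered within
±1 bin from ten cells of only 1,500 contacts each — consensus
precision, recall and F1 all 0.857. The compartment caller consumes
per-bin embeddings and the genome's GC track; on embeddings carrying a
compartment-coupled two-state signal it recovers the planted A/B sign
for over 90% of bins (the acceptance script recomputes this number).
Training the VGAE and calling loops follows the same pattern with
`trainVGAE()`, `callLoopsAll()` and `consensusLoops()`; see the methods
vignette (`vignettes/scArch-methods.Rmd`) and the CLI
(`inst/cli/scarch.R`) for the end-to-end workflow.

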