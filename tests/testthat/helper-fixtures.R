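# Small shared fixtures, built once per test run.

smallTruth <- function(nBins = 200L, nLoops = 20L, seed = 3L, ...)
  simulateTruth(nBins, nLoops = nLoops, seed = seed, ...)

# A tiny genome whose first bins spell known sequences, for exact k-mer
# count assertions (2 bins of 8 bp at resolution 8).
tinyGenome <- function(seqstr, chrom = "chrZ") {
  dna <- Biostrings::DNAStringSet(seqstr)
  names(dna) <- chrom
  methods::new("SyntheticGenome", sequence = dna, chrom = chrom,
               ctcfPositions = integer(), gcByBin = numeric())
}
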